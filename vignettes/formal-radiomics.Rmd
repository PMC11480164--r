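---
title: "Classifying radiomic feature series by model checking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying radiomic feature series by model checking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmrad)
```

## The problem and the model

Mild acute pancreatitis (MAP) can be radiologically subtle: the pathognomonic
CT signs (peripancreatic fluid, gland edema) may be minimal or absent at the
CTSI-0 end of the mild spectrum, and reader accuracy drops accordingly.
Radiomics turns the segmented gland into a per-slice vector of quantitative
texture/shape/intensity features; the question is how to classify those
series with small cohorts, no training set, and a decision process a
radiologist can audit.

`fmrad` answers with formal verification. The pipeline is:

1. **Ordinal discretization.** For each feature of a fixed 22-feature panel
   (families FIRST, GLCM, GLDM, GLSZM, SHAPE, GLRLM), the cohort range
   `[min, max]` is split into five equal-width intervals named *very_low,
   low, basal, high, very_high*. Five equivalent intervals keep the state
   vocabulary small enough for human-readable rules while still separating
   a shifted class from baseline.
2. **Patient models.** A patient with $S$ slices becomes a linear labeled
   transition system with $S \times F + 1$ states ($F$ = panel size): slices
   in ascending order, features within a slice in fixed panel order, each
   transition labeled by its discretized action, e.g. `mean__very_high`.
   Models serialize to CCS process-algebra text (prefix `.`, `nil`, `;`).
   The encoding is a *chain* on purpose: the diagnostic semantics used here
   is the presence or absence of actions along the series, which is
   order-invariant and needs no parallel composition or nondeterminism.
3. **The Property.** Domain experts designate a few exemplar patients with
   a typical, high-expression picture (CTSI grade 3). For a feature class
   $C$ the synthesized sub-property is
   $$\bigwedge_{f \in C} \; \bigvee_{\ell \in L(f)} \mathrm{presence}(f\_\_\ell),$$
   where $L(f)$ collects the modal level of $f$ over each exemplar's series.
   Sub-properties for different classes are joined by OR. `presence(a)` is
   the least-fixpoint formula $\mu X.(\langle a\rangle tt \lor
   \langle-\rangle X)$ of the modal mu-calculus.
4. **Model checking.** A fixpoint checker evaluates the rule on each
   patient's model; satisfaction ⇒ MAP. Positive calls carry a witness (the
   shortest action prefix establishing the rule), so the decision is
   retraceable step by step.
5. **Evaluation.** Confusion matrices with MAP as the positive class;
   accuracy, precision, sensitivity, specificity; optional combination with
   radiologist calls.

There is no training/test split in the statistical sense: the rule is
written (synthesized) from exemplars, and every *other* patient is a test
case. Exemplars are always excluded from scoring.

## The logic fragment and its checker

The formula language is the modal mu-calculus restricted to syntactically
monotone formulas: `tt`, `ff`, variables, `and`/`or`/`not`, `<a>`/`[a]`
modalities with a wildcard `-`, and `min`/`max` fixpoints; `presence(a)`
and `absence(a)` are first-class macros. Negation is only admitted on
closed subformulas — that guarantees monotone fixpoint bodies without a
polarity analysis, and the parser rejects violations naming the variable
(`min X . not X` is an error).

Fixpoints are computed by Kleene iteration from the empty (least) or full
(greatest) state set. On a lattice of subsets of an $n$-state chain every
fixpoint stabilizes within $n+1$ body evaluations; the checker asserts this
bound. No symbolic (BDD) or on-the-fly machinery is used: patient models
have at most a few hundred states, and the plain algorithm is the one a
reader can verify by hand.

The test suite cross-checks the checker against an independent oracle that
exploits the chain shape differently: it walks the unique maximal trace
backwards and solves each fixpoint state by state (the value at state $i$
can only depend on states $\ge i$ in an acyclic chain). Implementation and
oracle agree on 200 random chain/formula pairs per run, and
`presence(a)` coincides with alphabet membership exhaustively.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_levels` | 5 | ordinal levels | five equivalent intervals; small enough for readable rules |
| interval convention | `[e_i, e_{i+1})`, top closed | — | standard equal-width binning; the cohort maximum must land in the top level |
| out-of-range values | clamp + warning | — | a frozen scheme applied to new patients must not crash a prospective run |
| degenerate features | map to `basal` | — | a constant feature carries no information and must not drive presence atoms |
| modal-level ties | toward the higher ordinal | — | exemplars are chosen for high disease expression; ambiguity resolves toward severity |
| exemplar summarization | modal level | — | the mode is the most robust one-number summary of an ordinal series |
| rule shape | AND over features of OR over exemplar levels, presence atoms only | — | one canonical synthesized form; `absence` remains available for hand-written rules |
| positive class | MAP | — | the rule detects disease; healthy is the control group |
| metric rounding | half-up, 2 dp (or whole %) | — | matches how diagnostic tables print |

Discretization is fit *transductively* — over all retained patients,
exemplars included — because the method models the whole cohort rather than
fitting a training set. `fit_discretization` can equally be run on a
reference cohort and the frozen scheme applied to new patients (hence the
clamping rule).

## What the synthetic generator emulates

The generator reproduces the statistical skeleton of the motivating study:

* 40 healthy + 40 MAP patients; slice (ROI) counts per patient drawn from
  truncated normals with mean 19.7 on 6–27 (healthy) and 22.7 on 19–31
  (MAP) — the published ranges are read as 95% intervals, so
  sd = width/3.92, and the decimal-comma figures "19, 7"/"22, 7" are read
  as 19.7/22.7;
* MAP severity grades CTSI 0–3, uniform by default (the study reports four
  grades but not their counts);
* class signal as a mean shift of `delta` (default 3) pooled standard
  deviations on the discriminative features (all FIRST and SHAPE features
  by default), scaled by severity through $m(\mathrm{ctsi}) =
  (1+\mathrm{ctsi})/4$ — so CTSI-3 patients sit at the full shift and
  CTSI-0 patients at a quarter of it;
* optional incomplete extractions (a blanked feature for selected
  patients), reproducing the 80 → 76 exclusion pathway.

Feature *baselines* are nuisance parameters: per-feature means are drawn
once per cohort from a log-normal prior (median 50, log-sd 1.5) with
within-slice noise at 20% of the mean. Only the class structure in
sd units matters downstream — the discretization is per-feature and the
shift is expressed in sd units, so the pipeline is invariant to the
baseline scale. The generator does **not** emulate inter-feature
correlation, slice-to-slice autocorrelation, inter-operator segmentation
variability, or realistic marginal distributions of specific radiomic
features. A green end-to-end test therefore establishes that the machinery
recovers a known class structure of the stated size — not that the method
attains any particular accuracy on real CT data.

## Numerical and design choices

* **Equal-width edges** are `seq(min, max, length.out = 6)`; equality of
  widths is exact up to floating-point and tested against an independent
  recomputation at 1e-9 relative tolerance.
* **Boundary values** go to the upper bin (half-open convention); the
  maximum goes to `very_high` (closed top).
* **Missing values** (`NA`, `NaN`, empty cells, infinities) are carried as
  `NA` through reading and resolved by the exclusion filter — a patient is
  excluded iff any panel feature is missing on any slice. Coverage is
  judged against the panel features present in the table at all, so an
  upstream extractor with a narrower panel is noted rather than fatal.
* **Exemplar tokens.** A rule spec like `FIRST:CSV20,CSV35 OR
  SHAPE:CSV20,CSV29` means: FIRST-class sub-property from exemplars CSV20
  and CSV35, OR the SHAPE-class sub-property from CSV20 and CSV29 — three
  distinct exemplars in total. The synthesized formula and the per-feature
  level sets are recorded as provenance.
* **Combination with readers.** `or_positive` and `and_positive` are
  deployable vote policies; `oracle_union` is *idealized adjudication* —
  correct whenever either source is correct — and is labeled as such in all
  outputs because it is a counterfactual upper bound, not a classifier.
  Its accuracy provably dominates both sources, which the suite asserts on
  random prediction pairs.
* **Published-table arithmetic.** Diagnostic tables occasionally print a
  metric inconsistent with their own confusion matrix (here: a model-alone
  specificity printed 0.84 where the matrix gives 32/39 = 0.82, and a
  combined specificity printed 0.95 where the matrix gives 39/39 = 1.00).
  `flag_printed_inconsistencies()` surfaces these; nothing is reconciled.
* **Config format** is JSON (no YAML parser is available in the supported
  dependency set).
* **Auto-exemplar policy.** When a pipeline config does not name a rule
  spec, exemplars default to the first `n` (3) CTSI-3 MAP patients in
  sorted-id order and every configured class (FIRST, SHAPE) uses all of
  them. This is the transparent default for simulations; real analyses
  should name exemplars explicitly.

## Known limitations

* The rule language synthesizes presence atoms only; absence atoms and raw
  modal/fixpoint formulas are available for hand-written properties but no
  search over them is attempted.
* `rank_rules` scores a *given* candidate list; it does not enumerate the
  full exemplar-subset lattice (combinatorial and, with held-out scoring
  per candidate, easy to overfit at these cohort sizes).
* The checker is written for linear chains. `evaluate_formula` only
  accepts `patient_lts` objects; branching LTSs would need a generalized
  successor map (the semantics as written extends, the data structure does
  not).
* Witness extraction covers presence-style formulas (and/or over presence
  atoms); other satisfied formulas return no witness rather than a
  potentially misleading one.
* Information-gain feature ranking is a transparent stand-in for the
  original study's black-box feature selection, not a reproduction of it.

## A complete run

```{r pipeline, eval = FALSE}
report <- run_pipeline(list(seed = 3, synthesis = list(delta = 3)))
print(report)
# Pipeline run: 80 patients in, 80 retained, 77 scored (3 exemplars held out)
# Rule: FIRST:CSV12,CSV14,CSV16 OR SHAPE:CSV12,CSV14,CSV16
# accuracy 0.9610, precision 1.0000, sensitivity 0.9189, specificity 1.0000
```

Per-patient positive calls carry their witness prefix (`report$predictions$witness`),
the serialized CCS models land in `<out>/ccs/`, and `report.json` embeds the
confusion matrices from which every reported metric recomputes exactly.
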