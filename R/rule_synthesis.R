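#' Modal (most frequent) level of a slice series
#'
#' Summarizes an exemplar patient's slice series for one feature by its most
#' frequent ordinal level. Ties break toward the higher ordinal: exemplars
#' are chosen for high disease expression, so ambiguity resolves toward
#' severity.
#'
#' @param levels integer vector of ordinals (non-empty).
#' @return the modal ordinal (integer).
#' @examples
#' modal_level(c(3L, 3L, 2L))  # high
#' modal_level(c(3L, 2L))      # tie -> high
#' @export
modal_level <- function(levels) {
  if (!length(levels)) stop("empty level list")
  levels <- as.integer(levels)
  tab <- table(levels)
  winners <- as.integer(names(tab)[tab == max(tab)])
  max(winners)
}

#' Parse a rule specification string
#'
#' Syntax: disjuncts joined by `OR`, each `CLASS:id1,id2,...` (a feature
#' class name and its exemplar patient ids), e.g.
#' `"FIRST:CSV20,CSV35 OR SHAPE:CSV20,CSV29"`.
#'
#' @param text specification string.
#' @return a `rule_spec`: list of `list(class, exemplars)` disjuncts.
#' @export
parse_rule_spec <- function(text) {
  parts <- strsplit(text, "\\s+OR\\s+")[[1]]
  disj <- lapply(parts, function(p) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("rule spec disjunct must be CLASS:id1,id2 - got ", p)
    list(class = trimws(kv[1]),
         exemplars = trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]]))
  })
  structure(disj, class = "rule_spec")
}

#' All exemplar ids named by a rule spec
#' @param spec a `rule_spec`.
#' @return sorted character vector of distinct patient ids.
#' @export
spec_exemplars <- function(spec) {
  sort(unique(unlist(lapply(spec, `[[`, "exemplars"))))
}

#' Format a rule spec back to its string form
#' @param spec a `rule_spec`.
#' @return specification string.
#' @export
format_rule_spec <- function(spec) {
  paste(vapply(spec, function(d)
    paste0(d$class, ":", paste(d$exemplars, collapse = ",")), ""),
    collapse = " OR ")
}

#' Synthesize one feature class's sub-property from exemplars
#'
#' For each feature `f` of the class, collects the characteristic level set
#' `L(f)` = the modal levels of `f` over each exemplar's slice series, and
#' returns the conjunction over features of the disjunction over levels of
#' presence atoms:
#' \deqn{\bigwedge_{f} \bigvee_{\ell \in L(f)} presence(f\_\_\ell)}
#' By construction every exemplar satisfies its own sub-property (its modal
#' level occurs in its series), and enlarging the exemplar set can only
#' enlarge `L(f)`, making satisfaction monotone non-decreasing.
#'
#' @param class_name one of the panel's class names.
#' @param exemplar_ids patient ids present and complete in `dm`.
#' @param dm discretized matrix.
#' @param panel feature panel.
#' @return list with `formula` (AST) and `levels` (named list, per feature
#'   the ordinal level set used).
#' @export
synthesize_class_property <- function(class_name, exemplar_ids, dm,
                                      panel = canonical_panel()) {
  validate_panel(panel)
  if (!class_name %in% names(panel)) stop("unknown class: ", class_name)
  feats <- panel[[class_name]]
  missing <- setdiff(exemplar_ids, unique(dm$patient_id))
  if (length(missing))
    stop("exemplar(s) absent from cohort: ", paste(missing, collapse = ", "))
  nms <- level_names()
  lvsets <- lapply(feats, function(f) {
    per_ex <- vapply(exemplar_ids, function(e) {
      lv <- dm[dm$patient_id == e & dm$feature == f]$level
      if (!length(lv)) stop("exemplar ", e, " missing feature ", f)
      modal_level(lv)
    }, integer(1))
    sort(unique(per_ex))
  })
  names(lvsets) <- feats
  conj <- lapply(feats, function(f)
    f_fold(lapply(lvsets[[f]],
                  function(l) f_presence(action_name(f, nms[l + 1L]))),
           f_or))
  list(formula = f_fold(conj, f_and), levels = lvsets)
}

#' Synthesize a diagnostic rule from a rule specification
#'
#' Builds each disjunct with [synthesize_class_property()] and joins them
#' with OR; records full provenance (spec, per-feature level sets) so the
#' formula can be reconstructed deterministically.
#'
#' @param spec a `rule_spec` or its string form.
#' @param dm discretized matrix (covering all exemplars).
#' @param panel feature panel.
#' @param name rule name; default the spec string.
#' @return an object of class `diagnostic_rule`: list with `name`,
#'   `formula`, `text` (concrete syntax) and `provenance`.
#' @export
synthesize_rule <- function(spec, dm, panel = canonical_panel(), name = NULL) {
  if (is.character(spec)) spec <- parse_rule_spec(spec)
  if (!inherits(spec, "rule_spec") || !length(spec))
    stop("invalid rule spec")
  parts <- lapply(spec, function(d)
    synthesize_class_property(d$class, d$exemplars, dm, panel))
  formula <- f_fold(lapply(parts, `[[`, "formula"), f_or)
  check_monotone(formula)
  prov <- lapply(seq_along(spec), function(i)
    list(class = spec[[i]]$class, exemplars = spec[[i]]$exemplars,
         levels = parts[[i]]$levels))
  structure(list(name = name %||% format_rule_spec(spec),
                 formula = formula,
                 text = format_formula(formula),
                 provenance = list(spec = format_rule_spec(spec),
                                   disjuncts = prov)),
            class = "diagnostic_rule")
}

#' @export
print.diagnostic_rule <- function(x, ...) {
  cat("Diagnostic rule:", x$name, "\n")
  cat("  ", x$text, "\n")
  invisible(x)
}

#' Rank candidate rule specifications by held-out accuracy
#'
#' Scores each candidate on the cohort excluding its own exemplars (the
#' exemplars trivially satisfy their rule and would inflate accuracy), then
#' sorts by descending accuracy; ties break toward fewer exemplars, then
#' lexicographic spec text.
#'
#' @param candidate_specs list of `rule_spec` (or spec strings).
#' @param dm discretized matrix.
#' @param models named list of `patient_lts` for the cohort
#'   ([build_cohort_models()]).
#' @param labels label table.
#' @param panel feature panel.
#' @param metric `"accuracy"` (default) or `"sensitivity"`.
#' @return `data.table` with columns `spec`, `score`, `n_scored`, ordered
#'   best first.
#' @export
rank_rules <- function(candidate_specs, dm, models, labels,
                       panel = canonical_panel(), metric = "accuracy") {
  if (!length(candidate_specs)) stop("empty candidate list")
  metric <- match.arg(metric, c("accuracy", "sensitivity"))
  labels <- validate_labels(labels)
  rows <- lapply(candidate_specs, function(s) {
    if (is.character(s)) s <- parse_rule_spec(s)
    rule <- synthesize_rule(s, dm, panel)
    ex <- spec_exemplars(s)
    keep <- setdiff(names(models), ex)
    pred <- classify_cohort(models[keep], rule)
    cm <- confusion_matrix(pred, labels)
    m <- compute_metrics(cm)
    data.table::data.table(spec = format_rule_spec(s),
                           score = m[[metric]],
                           n_exemplars = length(ex),
                           n_scored = cm$tp + cm$fp + cm$fn + cm$tn)
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, -score, n_exemplars, spec)
  out[, n_exemplars := NULL]
  out[]
}
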