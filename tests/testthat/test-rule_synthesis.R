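test_that("modal level takes the mode, ties toward severity", {
  expect_equal(modal_level(c(3L, 3L, 2L)), 3L)      # majority
  expect_equal(modal_level(c(3L, 2L)), 3L)          # tie -> higher
  expect_equal(modal_level(c(0L, 0L, 1L, 1L, 4L)), 1L)
  expect_error(modal_level(integer()), "empty")
})

test_that("modal level matches a brute-force frequency oracle", {
  set.seed(77)
  for (i in 1:1000) {
    lv <- sample(0:4, sample(1:12, 1), replace = TRUE)
    expect_identical(modal_level(lv), oracle_modal(lv))
  }
})

test_that("rule spec strings parse and print back", {
  spec <- parse_rule_spec("FIRST:CSV20,CSV35 OR SHAPE:CSV20,CSV29")
  expect_length(spec, 2L)
  expect_equal(spec[[1]]$class, "FIRST")
  expect_equal(spec[[2]]$exemplars, c("CSV20", "CSV29"))
  expect_equal(spec_exemplars(spec), c("CSV20", "CSV29", "CSV35"))
  expect_equal(format_rule_spec(spec), "FIRST:CSV20,CSV35 OR SHAPE:CSV20,CSV29")
  expect_error(parse_rule_spec("FIRST"), "CLASS:id1")
})

test_that("class property is conjunction over features of level disjunctions", {
  # hand-computable toy: 3 patients, constant values per patient so the
  # modal level per feature is forced
  fm <- tiny_cohort_fm(n_pat = 3L, n_slices = 4L, shifts = c(0, 6, 12))
  sch <- fit_discretization(fm)
  dm <- discretize_matrix(fm, sch)
  prop <- synthesize_class_property("SHAPE", c("P02", "P03"), dm)
  # 3 SHAPE features, conjoined
  expect_equal(prop$formula$op, "and")
  expect_named(prop$levels, canonical_panel()$SHAPE)
  # levels recorded are exactly the per-exemplar modal levels
  for (f in names(prop$levels)) {
    per_ex <- vapply(c("P02", "P03"), function(e)
      oracle_modal(dm[dm$patient_id == e & dm$feature == f]$level),
      integer(1))
    expect_equal(prop$levels[[f]], sort(unique(unname(per_ex))))
  }
  expect_error(synthesize_class_property("NOPE", "P01", dm), "unknown class")
  expect_error(synthesize_class_property("FIRST", "ghost", dm), "absent")
})

test_that("single exemplar, forced level -> single presence atom per feature", {
  fm <- tiny_cohort_fm(n_pat = 2L, n_slices = 3L)
  fm[patient_id == "P02" & feature %in% canonical_panel()$SHAPE,
     value := 1e6]  # P02 slices pinned at the cohort maximum
  sch <- fit_discretization(fm)
  dm <- discretize_matrix(fm, sch)
  prop <- synthesize_class_property("SHAPE", "P02", dm)
  expect_true(all(vapply(prop$levels, identical, TRUE, 4L)))
  atoms <- prop$formula
  txt <- format_formula(atoms)
  expect_match(txt, "presence\\(surfacearea__very_high\\)")
  expect_false(grepl(" or ", txt))  # one level per feature, no disjunction
})

test_that("every exemplar satisfies its own synthesized sub-property", {
  fx <- study_fixture()
  flt <- filter_incomplete_patients(fx$features)
  sch <- fit_discretization(flt$matrix)
  dm <- discretize_matrix(flt$matrix, sch)
  exemplars <- head(sort(fx$labels[status == "MAP" & ctsi == 3L &
                                     !patient_id %in% c("CSV1", "CSV2", "CSV3"),
                                   patient_id]), 4L)
  for (cl in c("FIRST", "SHAPE", "GLCM")) {
    prop <- synthesize_class_property(cl, exemplars, dm)
    for (e in exemplars) {
      m <- build_patient_model(dm, e)
      expect_true(evaluate_formula(m, prop$formula)$satisfied,
                  label = sprintf("exemplar %s vs class %s", e, cl))
    }
  }
})

test_that("rule synthesis composes disjuncts and records provenance", {
  fm <- tiny_cohort_fm(n_pat = 3L, n_slices = 3L, shifts = c(0, 4, 8))
  dm <- discretize_matrix(fm, fit_discretization(fm))
  rule <- synthesize_rule("FIRST:P02,P03 OR SHAPE:P02", dm)
  expect_s3_class(rule, "diagnostic_rule")
  expect_equal(rule$formula$op, "or")
  expect_equal(rule$provenance$spec, "FIRST:P02,P03 OR SHAPE:P02")
  expect_silent(check_monotone(rule$formula))
  # deterministic given identical inputs
  rule2 <- synthesize_rule("FIRST:P02,P03 OR SHAPE:P02", dm)
  expect_identical(rule, rule2)
  # single disjunct: no top-level or
  rule3 <- synthesize_rule("FIRST:P02", dm)
  expect_equal(rule3$formula$op, "and")
})

test_that("widening the exemplar set is monotone for satisfaction", {
  fm <- tiny_cohort_fm(n_pat = 6L, n_slices = 4L,
                       shifts = c(0, 1, 2, 3, 4, 5))
  dm <- discretize_matrix(fm, fit_discretization(fm))
  models <- build_cohort_models(dm)
  sat_set <- function(ex) {
    rule <- synthesize_rule(
      structure(list(list(class = "FIRST", exemplars = ex)),
                class = "rule_spec"), dm)
    names(Filter(function(m) evaluate_formula(m, rule$formula)$satisfied,
                 models))
  }
  narrow <- sat_set(c("P05"))
  wide <- sat_set(c("P05", "P02", "P06"))
  expect_true(all(narrow %in% wide))
})

test_that("rank_rules prefers the signal-bearing feature class", {
  # signal only on FIRST features
  cfg <- cohort_config(n_healthy = 12L, n_map = 12L, delta = 3,
                       discriminative = canonical_panel()$FIRST, seed = 5L)
  co <- generate_cohort(cfg)
  dm <- discretize_matrix(co$features, fit_discretization(co$features))
  models <- build_cohort_models(dm)
  ex <- co$labels[status == "MAP"][order(-ctsi, patient_id)]$patient_id[1:2]
  specs <- list(sprintf("FIRST:%s", paste(ex, collapse = ",")),
                sprintf("GLRLM:%s", paste(ex, collapse = ",")))
  ranked <- rank_rules(specs, dm, models, co$labels)
  expect_match(ranked$spec[1], "^FIRST")
  expect_gt(ranked$score[1], ranked$score[2])
  # per-candidate exemplar exclusion: scored n = cohort minus own exemplars
  expect_equal(unique(ranked$n_scored), 24L - 2L)
  expect_error(rank_rules(list(), dm, models, co$labels), "empty")
})
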