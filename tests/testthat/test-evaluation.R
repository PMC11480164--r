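test_that("confusion matrix counts toy cohorts correctly", {
  labels <- tiny_labels(c("a", "b", "c", "d", "e"),
                        c("MAP", "MAP", "MAP", "healthy", "healthy"))
  pred <- prediction_table(labels$patient_id, labels$status, "model")
  cm <- confusion_matrix(pred, labels)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 3L, fp = 0L, fn = 0L, tn = 2L))

  all_map <- prediction_table(c("a", "b", "d", "e"), rep("MAP", 4), "model")
  cm2 <- confusion_matrix(all_map, labels)
  expect_equal(unlist(cm2[c("tp", "fp", "fn", "tn")]),
               c(tp = 2L, fp = 2L, fn = 0L, tn = 0L))

  expect_error(confusion_matrix(prediction_table("zz", "MAP", "model"),
                                labels), "without label")
})

test_that("confusion matrix matches a brute-force tally on random cohorts", {
  set.seed(41)
  for (i in 1:10) {
    n <- 50L
    ids <- sprintf("p%02d", 1:n)
    labels <- tiny_labels(ids, sample(c("healthy", "MAP"), n, replace = TRUE))
    pred <- prediction_table(sample(ids), sample(c("healthy", "MAP"), n,
                                                 replace = TRUE), "model")
    cm <- confusion_matrix(pred, labels)
    expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
                 oracle_confusion(pred, labels))
  }
})

test_that("exclusion set is honored and n is conserved", {
  labels <- tiny_labels(sprintf("p%d", 1:6), rep(c("MAP", "healthy"), 3))
  pred <- prediction_table(labels$patient_id, rep("MAP", 6), "model")
  cm <- confusion_matrix(pred, labels, exclude = c("p1", "p2"))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 4L)
})

test_that("metrics reproduce the published model-alone table", {
  m <- compute_metrics(new_confusion_matrix(25, 7, 6, 32))
  expect_equal(m$accuracy, 57 / 70)
  expect_equal(round_half_up(m$accuracy), 0.81)
  expect_equal(round_half_up(m$precision), 0.78)
  expect_equal(round_half_up(m$sensitivity), 0.81)
  expect_equal(round_half_up(m$accuracy, percent = TRUE), 81)
  expect_equal(round_half_up(m$precision, percent = TRUE), 78)
  expect_equal(round_half_up(m$sensitivity, percent = TRUE), 81)
})

test_that("metrics reproduce the published combined table", {
  m <- compute_metrics(new_confusion_matrix(29, 0, 2, 39))
  expect_equal(round_half_up(m$accuracy), 0.97)
  expect_equal(m$precision, 1.00)
  expect_equal(round_half_up(m$sensitivity), 0.94)
})

test_that("undefined denominators yield NA, never an error", {
  m <- compute_metrics(new_confusion_matrix(0, 0, 0, 10))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 1.0)
  expect_error(compute_metrics(new_confusion_matrix(0, 0, 0, 0)), "all-zero")
  expect_error(new_confusion_matrix(-1, 0, 0, 1), "non-negative")
})

test_that("published specificities that do not recompute are flagged", {
  st <- study_tables()
  flags <- flag_printed_inconsistencies(st$model_cm, st$printed_model)
  expect_true(all(flags[flags$metric != "specificity"]$consistent))
  spc <- flags[flags$metric == "specificity"]
  expect_false(spc$consistent)
  expect_equal(spc$recomputed, 0.82)  # 32/39, printed as 0.84

  flags2 <- flag_printed_inconsistencies(st$combined_cm, st$printed_combined)
  spc2 <- flags2[flags2$metric == "specificity"]
  expect_false(spc2$consistent)
  expect_equal(spc2$recomputed, 1.00)  # 39/39, printed as 0.95
})

test_that("combination policies behave on hand-built cases", {
  labels <- tiny_labels(c("m1", "m2", "h1"), c("MAP", "MAP", "healthy"))
  model <- prediction_table(c("m1", "m2", "h1"),
                            c("healthy", "healthy", "healthy"), "model")
  reader <- prediction_table(c("m1", "m2", "h1"),
                             c("MAP", "healthy", "MAP"), "radiologist")
  # MAP missed by model, caught by reader -> TP under oracle_union
  comb <- combine_predictions(model, reader, labels, "oracle_union")
  expect_equal(comb[comb$patient_id == "m1"]$call, "MAP")
  # healthy over-called by reader, correct by model -> TN
  expect_equal(comb[comb$patient_id == "h1"]$call, "healthy")
  # both wrong on a MAP patient -> stays wrong under any policy
  expect_equal(comb[comb$patient_id == "m2"]$call, "healthy")
  orp <- combine_predictions(model, reader, labels, "or_positive")
  expect_equal(orp$call[orp$patient_id == "h1"], "MAP")
  andp <- combine_predictions(model, reader, labels, "and_positive")
  expect_true(all(andp$call == "healthy"))
  expect_error(combine_predictions(model, reader, NULL, "oracle_union"),
               "requires labels")
})

test_that("oracle_union accuracy dominates both sources", {
  set.seed(21)
  for (i in 1:100) {
    n <- 30L
    ids <- sprintf("p%02d", 1:n)
    labels <- tiny_labels(ids, sample(c("healthy", "MAP"), n, replace = TRUE))
    rand_pred <- function(src)
      prediction_table(ids, sample(c("healthy", "MAP"), n, replace = TRUE),
                       src)
    model <- rand_pred("model"); reader <- rand_pred("radiologist")
    acc <- function(p) compute_metrics(confusion_matrix(p, labels))$accuracy
    comb <- combine_predictions(model, reader, labels, "oracle_union")
    expect_gte(acc(comb), max(acc(model), acc(reader)))
  }
})

test_that("narrative reconstruction reproduces the combined matrix", {
  st <- reconstruct_study_predictions()
  # the model's own matrix is the published one
  cm_model <- confusion_matrix(st$model, st$labels)
  expect_equal(unlist(cm_model[c("tp", "fp", "fn", "tn")]),
               c(tp = 25L, fp = 7L, fn = 6L, tn = 32L))
  # reader misses exactly 6 MAP (all CTSI 0-1), over-calls exactly 2 healthy
  cm_reader <- confusion_matrix(st$reader, st$labels)
  expect_equal(cm_reader$fn, 6L)
  expect_equal(cm_reader$fp, 2L)
  missed <- merge(st$reader[call == "healthy"], st$labels,
                  by = "patient_id")[status == "MAP"]
  expect_true(all(missed$ctsi <= 1L))
  # exactly 2 of the reader's misses are shared with the model
  shared <- intersect(st$model[call == "healthy"]$patient_id,
                      missed$patient_id)
  expect_length(shared, 2L)
  # model FP disjoint from reader FP
  expect_length(intersect(
    st$model[call == "MAP"]$patient_id[
      st$model[call == "MAP"]$patient_id %in%
        st$labels[status == "healthy"]$patient_id],
    st$reader[call == "MAP"]$patient_id[
      st$reader[call == "MAP"]$patient_id %in%
        st$labels[status == "healthy"]$patient_id]), 0L)
  comb <- combine_predictions(st$model, st$reader, st$labels, "oracle_union")
  cm <- confusion_matrix(comb, st$labels)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 29L, fp = 0L, fn = 2L, tn = 39L))
})

test_that("classification is permutation-invariant and witnesses explain", {
  fm <- tiny_cohort_fm(n_pat = 3L, n_slices = 3L, shifts = c(0, 0, 6))
  dm <- discretize_matrix(fm, fit_discretization(fm))
  models <- build_cohort_models(dm)
  rule <- synthesize_rule("FIRST:P03", dm)
  p1 <- classify_cohort(models, rule)
  p2 <- classify_cohort(rev(models), rule)
  expect_identical(p1, p2)
  expect_equal(p1[patient_id == "P03"]$call, "MAP")
  expect_false(is.na(p1[patient_id == "P03"]$witness))
  expect_error(classify_cohort(c(models, models[1]), rule), "duplicate")
})
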