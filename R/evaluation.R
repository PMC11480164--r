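#' Classify a cohort with a diagnostic rule
#'
#' A patient is called `MAP` iff the model checker finds the rule's formula
#' satisfied at their model's initial state; otherwise `healthy`.
#' Deterministic and invariant to the order of the model list.
#'
#' @param models named list of `patient_lts`.
#' @param rule a `diagnostic_rule` (or a formula AST / source text).
#' @param source tag for the prediction source; default `"model"`.
#' @return a prediction table: `data.table` with `patient_id`, `call`,
#'   `source`, and `witness` (dot-joined action prefix for positive calls
#'   where available).
#' @export
classify_cohort <- function(models, rule, source = "model") {
  ids <- vapply(models, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in model list")
  formula <- if (inherits(rule, "diagnostic_rule")) rule$formula else rule
  if (is.character(formula)) formula <- parse_formula(formula)
  res <- lapply(models, evaluate_formula, formula = formula)
  out <- data.table::data.table(
    patient_id = unname(ids),
    call = ifelse(vapply(res, `[[`, NA, "satisfied"), "MAP", "healthy"),
    source = source,
    witness = vapply(res, function(r)
      if (is.null(r$witness)) NA_character_
      else paste(r$witness, collapse = "."), ""))
  data.table::setorder(out, patient_id)
  out[]
}

#' Build a prediction table from explicit calls
#'
#' @param patient_id character vector of ids.
#' @param call vector of `"healthy"`/`"MAP"` calls.
#' @param source prediction source tag (`model`, `radiologist`, `combined`).
#' @return prediction `data.table`.
#' @export
prediction_table <- function(patient_id, call, source) {
  stopifnot(length(patient_id) == length(call),
            all(call %in% c("healthy", "MAP")))
  if (anyDuplicated(patient_id)) stop("duplicate patient ids")
  data.table::data.table(patient_id = as.character(patient_id),
                         call = call, source = source,
                         witness = NA_character_)
}

#' Confusion matrix of predictions against labels
#'
#' MAP is the positive class throughout.
#'
#' @param pred prediction table ([classify_cohort()]).
#' @param labels label table with `patient_id`, `status`.
#' @param exclude patient ids to leave out (e.g. rule exemplars).
#' @return an object of class `confusion_matrix`: list with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(pred, labels, exclude = character()) {
  labels <- validate_labels(labels)
  pred <- pred[!pred$patient_id %in% exclude]
  unlabeled <- setdiff(pred$patient_id, labels$patient_id)
  if (length(unlabeled))
    stop("predicted patient(s) without label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "))
  m <- merge(pred, labels[, c("patient_id", "status")], by = "patient_id")
  new_confusion_matrix(
    tp = sum(m$call == "MAP" & m$status == "MAP"),
    fp = sum(m$call == "MAP" & m$status == "healthy"),
    fn = sum(m$call == "healthy" & m$status == "MAP"),
    tn = sum(m$call == "healthy" & m$status == "healthy"))
}

#' Construct a confusion matrix from counts
#' @param tp,fp,fn,tn non-negative integer counts (MAP = positive).
#' @return a `confusion_matrix`.
#' @export
new_confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP %d  FP %d\nFN %d  TN %d   (n = %d, positive = MAP)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' accuracy = (TP+TN)/n, precision = TP/(TP+FP), sensitivity (recall) =
#' TP/(TP+FN), specificity = TN/(TN+FP). A zero denominator yields `NA`
#' (explicit undefined marker), never an error.
#'
#' @param cm a `confusion_matrix` with at least one count.
#' @return list of class `diagnostic_metrics` with the four raw values.
#' @examples
#' compute_metrics(new_confusion_matrix(25, 7, 6, 32))
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0L) stop("all-zero confusion matrix")
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(accuracy = (cm$tp + cm$tn) / n,
                 precision = ratio(cm$tp, cm$tp + cm$fp),
                 sensitivity = ratio(cm$tp, cm$tp + cm$fn),
                 specificity = ratio(cm$tn, cm$tn + cm$fp)),
            class = "diagnostic_metrics")
}

#' Round a metric the way the study tables print it
#'
#' Half-up rounding (0.975 -> 0.98), to 2 decimals by default or to a whole
#' percentage with `percent = TRUE`.
#'
#' @param x numeric metric in `[0, 1]`.
#' @param digits decimal places.
#' @param percent round to whole percent instead.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L, percent = FALSE) {
  if (percent) floor(100 * x + 0.5)
  else floor(x * 10^digits + 0.5) / 10^digits
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (k in names(x))
    cat(sprintf("%-12s %s\n", k,
                if (is.na(x[[k]])) "undefined"
                else sprintf("%.4f (%.2f)", x[[k]], round_half_up(x[[k]]))))
  invisible(x)
}

#' Combine model and radiologist predictions
#'
#' Policies:
#' * `or_positive` — MAP if either source calls MAP (maximizes sensitivity);
#' * `and_positive` — MAP only if both call MAP;
#' * `oracle_union` — idealized adjudication: the combined call is correct
#'   whenever at least one source is correct, and the shared wrong call when
#'   both err. This is a counterfactual upper bound ("what supervision could
#'   have recovered"), not a deployable classifier, and requires labels.
#'
#' @param model,reader prediction tables over the same patient set.
#' @param labels label table (required for `oracle_union`).
#' @param policy combination policy.
#' @return prediction table with `source = "combined"`.
#' @export
combine_predictions <- function(model, reader, labels = NULL,
                                policy = c("oracle_union", "or_positive",
                                           "and_positive")) {
  policy <- match.arg(policy)
  if (!setequal(model$patient_id, reader$patient_id))
    stop("model and reader predictions must cover the same patients")
  m <- merge(model[, c("patient_id", "call")],
             reader[, c("patient_id", "call")],
             by = "patient_id", suffixes = c("_model", "_reader"))
  call <- switch(policy,
    or_positive = ifelse(m$call_model == "MAP" | m$call_reader == "MAP",
                         "MAP", "healthy"),
    and_positive = ifelse(m$call_model == "MAP" & m$call_reader == "MAP",
                          "MAP", "healthy"),
    oracle_union = {
      if (is.null(labels)) stop("policy oracle_union requires labels")
      labels <- validate_labels(labels)
      mm <- merge(m, labels[, c("patient_id", "status")], by = "patient_id")
      ifelse(mm$call_model == mm$status | mm$call_reader == mm$status,
             mm$status,
             mm$call_model)  # both wrong: the shared wrong call
    })
  prediction_table(m$patient_id, call, "combined")
}

#' Flag printed metrics that disagree with their own confusion matrix
#'
#' Recomputes each metric from the matrix and reports any whose printed
#' value differs after half-up rounding to 2 decimals. Published tables
#' occasionally carry such internal inconsistencies; they are surfaced, not
#' reconciled.
#'
#' @param cm a `confusion_matrix`.
#' @param printed named numeric vector of printed values (subset of
#'   `accuracy`, `precision`, `sensitivity`, `specificity`).
#' @return `data.table` with `metric`, `printed`, `recomputed`, `consistent`.
#' @export
flag_printed_inconsistencies <- function(cm, printed) {
  m <- compute_metrics(cm)
  rows <- lapply(names(printed), function(k) {
    rec <- round_half_up(m[[k]])
    data.table::data.table(metric = k, printed = unname(printed[k]),
                           recomputed = rec,
                           consistent = isTRUE(all.equal(unname(printed[k]), rec)))
  })
  data.table::rbindlist(rows)
}
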