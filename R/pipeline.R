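#' Run the full classification pipeline
#'
#' Orchestrates read (or synthesize) -> exclusion filter -> discretization
#' fit -> patient model construction -> rule synthesis (exemplars excluded
#' from scoring) -> model checking -> evaluation, with optional combination
#' against radiologist calls.
#'
#' `config` is a named list (or path to a JSON file) with entries:
#' \describe{
#'   \item{seed}{integer; seeds synthesis.}
#'   \item{synthesis}{optional list of [cohort_config()] overrides, plus an
#'     optional `incomplete = list(n_healthy, n_map, feature)` block that
#'     blanks one feature for the first so-many patients of each class
#'     before filtering.}
#'   \item{features, labels}{paths to CSV tables (used when `synthesis` is
#'     absent).}
#'   \item{rule_spec}{explicit rule specification string, e.g.
#'     `"FIRST:CSV20,CSV35 OR SHAPE:CSV20,CSV29"`.}
#'   \item{exemplars}{alternative to `rule_spec`: list with `n` (number of
#'     exemplar patients, taken as the first `n` CTSI-3 MAP ids in sorted
#'     order) and `classes` (feature classes, each becoming a disjunct over
#'     all chosen exemplars).}
#'   \item{combine}{optional policy for [combine_predictions()] against the
#'     labels' `radiologist_call` column.}
#'   \item{out}{optional output directory for artifacts.}
#' }
#'
#' @param config named list or JSON file path.
#' @return a `run_report` list: config echo, exclusion report,
#'   discretization scheme, rule (text + provenance), per-patient calls with
#'   witnesses, confusion matrices and metrics per source, and seed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  panel <- canonical_panel()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- acquire cohort ---
  if (!is.null(config$synthesis)) {
    syn <- config$synthesis
    inc <- syn$incomplete
    syn$incomplete <- NULL
    if (!is.null(config$seed)) syn$seed <- config$seed
    cfg <- stage("synthesize", do.call(cohort_config, syn))
    cohort <- stage("synthesize", generate_cohort(cfg))
    fm <- cohort$features; labels <- cohort$labels
    if (!is.null(inc)) {
      ids <- c(utils::head(labels[labels$status == "healthy"]$patient_id,
                           inc$n_healthy %||% 0L),
               utils::head(labels[labels$status == "MAP"]$patient_id,
                           inc$n_map %||% 0L))
      fm <- stage("synthesize",
                  inject_missing(fm, ids, inc$feature %||% "Mean"))
    }
  } else {
    if (is.null(config$features) || is.null(config$labels))
      stop("config must provide either a synthesis block or features+labels paths")
    fm <- stage("read", read_feature_table(config$features, panel))
    labels <- stage("read", read_labels(config$labels))
  }

  # --- filter, discretize, model ---
  flt <- stage("filter", filter_incomplete_patients(fm, panel))
  labels <- labels[labels$patient_id %in% attr(flt$report, "retained_ids")]
  scheme <- stage("discretize", fit_discretization(flt$matrix, panel))
  dm <- stage("discretize", discretize_matrix(flt$matrix, scheme))
  models <- stage("build-models", build_cohort_models(dm, panel))

  # --- rule ---
  spec <- if (!is.null(config$rule_spec)) parse_rule_spec(config$rule_spec)
  else {
    ex_cfg <- config$exemplars %||% list(n = 3L, classes = c("FIRST", "SHAPE"))
    pool <- sort(labels[labels$status == "MAP" & !is.na(labels$ctsi) &
                          labels$ctsi == 3L]$patient_id)
    n_ex <- min(ex_cfg$n %||% 3L, length(pool))
    if (n_ex == 0L) stop("pipeline stage 'synthesize-rule' failed: no CTSI-3 patients to use as exemplars")
    ex <- pool[seq_len(n_ex)]
    structure(lapply(ex_cfg$classes %||% c("FIRST", "SHAPE"), function(cl)
      list(class = cl, exemplars = ex)), class = "rule_spec")
  }
  rule <- stage("synthesize-rule", synthesize_rule(spec, dm, panel))
  exemplars <- spec_exemplars(spec)

  # --- classify + evaluate (exemplars never scored) ---
  scored <- setdiff(names(models), exemplars)
  pred <- stage("classify", classify_cohort(models[scored], rule))
  cm <- stage("evaluate", confusion_matrix(pred, labels))
  metrics <- compute_metrics(cm)
  report <- list(config = config,
                 seed = config$seed %||% NA_integer_,
                 n_input = length(unique(fm$patient_id)),
                 n_retained = length(attr(flt$report, "retained_ids")),
                 n_scored = nrow(pred),
                 exclusions = flt$report,
                 scheme = scheme,
                 rule = list(name = rule$name, text = rule$text,
                             provenance = rule$provenance),
                 exemplars = exemplars,
                 predictions = pred,
                 confusion = list(model = cm),
                 metrics = list(model = metrics))

  # --- optional combination with radiologist calls ---
  if (!is.null(config$combine)) {
    if (!"radiologist_call" %in% names(labels))
      stop("pipeline stage 'combine' failed: labels lack radiologist_call")
    reader <- prediction_table(
      labels$patient_id[labels$patient_id %in% pred$patient_id],
      labels$radiologist_call[labels$patient_id %in% pred$patient_id],
      "radiologist")
    comb <- stage("combine",
                  combine_predictions(pred, reader, labels, config$combine))
    report$confusion$radiologist <- confusion_matrix(reader, labels)
    report$confusion$combined <- confusion_matrix(comb, labels)
    report$metrics$radiologist <- compute_metrics(report$confusion$radiologist)
    report$metrics$combined <- compute_metrics(report$confusion$combined)
    report$combined_policy <- config$combine
    if (identical(config$combine, "oracle_union"))
      report$combined_note <-
        "idealized adjudication (counterfactual upper bound), not a deployable classifier"
  }
  class(report) <- "run_report"
  if (!is.null(config$out)) write_run_report(report, config$out, models)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run: %d patients in, %d retained, %d scored (%d exemplars held out)\n",
              x$n_input, x$n_retained, x$n_scored, length(x$exemplars)))
  cat("Rule:", x$rule$name, "\n")
  cat("Model confusion: "); print(x$confusion$model)
  cat("Model metrics:\n"); print(x$metrics$model)
  if (!is.null(x$metrics$combined)) {
    cat(sprintf("Combined (%s) metrics:\n", x$combined_policy))
    print(x$metrics$combined)
  }
  invisible(x)
}

#' Write run-report artifacts to a directory
#'
#' CCS models as `.ccs` text, discretization scheme / rule provenance /
#' predictions / report as JSON, confusion matrices and metrics as CSV.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if absent).
#' @param models optional named list of `patient_lts` to serialize.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir, models = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(models)) {
    ccs_dir <- file.path(dir, "ccs")
    dir.create(ccs_dir, showWarnings = FALSE)
    for (m in models)
      writeLines(serialize_ccs(m),
                 file.path(ccs_dir, paste0(pid_token(m$patient_id), ".ccs")))
  }
  data.table::fwrite(report$predictions, file.path(dir, "predictions.csv"))
  rows <- data.table::rbindlist(lapply(names(report$confusion), function(s) {
    cm <- report$confusion[[s]]; m <- report$metrics[[s]]
    data.table::data.table(source = s, tp = cm$tp, fp = cm$fp, fn = cm$fn,
                           tn = cm$tn, accuracy = m$accuracy,
                           precision = m$precision,
                           sensitivity = m$sensitivity,
                           specificity = m$specificity)
  }))
  data.table::fwrite(rows, file.path(dir, "metrics.csv"))
  scheme_df <- as.data.frame(report$scheme)
  jsonlite::write_json(
    list(seed = report$seed,
         n_input = report$n_input, n_retained = report$n_retained,
         n_scored = report$n_scored,
         exclusions = as.data.frame(report$exclusions),
         scheme = scheme_df,
         rule = report$rule,
         exemplars = report$exemplars,
         confusion = lapply(report$confusion, unclass),
         metrics = lapply(report$metrics, unclass),
         combined_policy = report$combined_policy,
         combined_note = report$combined_note),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
  invisible(dir)
}

#' Rank panel features by information gain
#'
#' A transparent stand-in for black-box feature selection: for each feature,
#' the mutual information (in bits) between class label and discretized
#' level, computed over slices with patients weighted equally (each
#' patient's slices sum to weight 1, so long series do not dominate).
#'
#' @param dm discretized matrix.
#' @param labels label table covering at least two classes among `dm`'s
#'   patients.
#' @return `data.table` with `feature`, `gain`, descending, ties broken
#'   lexicographically.
#' @export
rank_features <- function(dm, labels) {
  labels <- validate_labels(labels)
  d <- merge(dm, labels[, c("patient_id", "status")], by = "patient_id")
  if (data.table::uniqueN(d$status) < 2L)
    stop("need at least two classes to rank features")
  d[, w := 1 / .N, by = .(patient_id, feature)]
  entropy <- function(w) {
    p <- w / sum(w); p <- p[p > 0]
    -sum(p * log2(p))
  }
  h_class <- entropy(d[, sum(w), by = status]$V1)
  gains <- d[, {
    h_cond <- sum(vapply(split(.SD, .SD$level), function(g)
      sum(g$w) * entropy(tapply(g$w, g$status, sum)), 0)) / sum(w)
    .(gain = h_class - h_cond)
  }, by = feature, .SDcols = c("level", "status", "w")]
  data.table::setorder(gains, -gain, feature)
  gains[]
}
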