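#' @import data.table
NULL

#' Construct a feature matrix
#'
#' The feature matrix is the pipeline's sole upstream input: one row per
#' (patient, slice, feature) with a real-valued, unitless radiomic value.
#' Values may be `NA` (incomplete extraction); completeness is enforced later
#' by [filter_incomplete_patients()], not at construction.
#'
#' @param df data.frame with columns `patient_id`, `slice_index`, `feature`,
#'   `value` (long form).
#' @return a `data.table` with those four columns, keyed and validated.
#' @export
feature_matrix <- function(df) {
  dt <- data.table::as.data.table(df)
  need <- c("patient_id", "slice_index", "feature", "value")
  if (!all(need %in% names(dt)))
    stop("feature matrix needs columns: ", paste(need, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, `:=`(patient_id = as.character(patient_id),
            slice_index = as.integer(slice_index),
            feature = as.character(feature),
            value = as.numeric(value))]
  validate_feature_matrix(dt)
}

#' Validate feature-matrix invariants
#'
#' `(patient_id, slice_index, feature)` must be unique; slice indices must be
#' non-negative; values must be `NA` or finite (infinite values are coerced
#' to `NA` so they flow into the exclusion pathway rather than corrupting
#' discretization).
#'
#' @param fm a feature matrix ([feature_matrix()]).
#' @return the validated matrix (possibly with infinities recoded to `NA`).
#' @export
validate_feature_matrix <- function(fm) {
  stopifnot(data.table::is.data.table(fm))
  if (nrow(fm) == 0L) stop("empty feature matrix")
  if (anyNA(fm$slice_index) || any(fm$slice_index < 0L))
    stop("slice_index must be a non-negative integer")
  if (anyDuplicated(fm, by = c("patient_id", "slice_index", "feature")))
    stop("duplicate (patient_id, slice_index, feature) rows")
  bad <- !is.na(fm$value) & !is.finite(fm$value)
  if (any(bad)) fm[bad, value := NA_real_]
  data.table::setkey(fm, patient_id, slice_index, feature)
  fm[]
}

#' Read a cohort feature table from delimited text
#'
#' Accepts either layout, auto-detected from the header:
#' * wide: `patient_id,slice_index,<feature>,<feature>,...`
#' * long (tidy): `patient_id,slice_index,feature_name,value`
#'
#' Feature columns are matched against the panel case-insensitively after
#' stripping punctuation ("Joint entropy" matches "JointEntropy"); columns
#' not in the panel are ignored with a message. Empty cells, `NA` and `NaN`
#' are recorded as missing values — they drive patient exclusion downstream
#' rather than erroring at read time. Non-numeric text in a feature column is
#' a format error naming the column.
#'
#' @param source path to a CSV file (or anything `data.table::fread` accepts).
#' @param panel the feature panel; default [canonical_panel()].
#' @return a feature matrix in long form restricted to panel features.
#' @export
read_feature_table <- function(source, panel = canonical_panel()) {
  validate_panel(panel)
  dt <- data.table::fread(source, colClasses = list(character = 1L),
                          na.strings = c("", "NA", "NaN", "nan"))
  if (ncol(dt) < 3L) stop("format error: expected header with patient id, slice index and features")
  lk <- panel_lookup(panel)
  nn <- normalize_feature_name(names(dt))

  id_col <- which(nn %in% c("patientid", "patient", "id"))[1]
  sl_col <- which(nn %in% c("sliceindex", "slice"))[1]
  if (is.na(id_col) || is.na(sl_col))
    stop("format error: header must name patient_id and slice_index columns")

  long <- all(c("featurename", "value") %in% nn) ||
    all(c("feature", "value") %in% nn)
  if (long) {
    f_col <- which(nn %in% c("featurename", "feature"))[1]
    v_col <- which(nn == "value")[1]
    out <- dt[, c(id_col, sl_col, f_col, v_col), with = FALSE]
    data.table::setnames(out, c("patient_id", "slice_index", "feature", "value"))
    keys <- normalize_feature_name(out$feature)
    known <- keys %in% names(lk)
    if (any(!known)) {
      message("ignoring ", length(unique(out$feature[!known])),
              " non-panel feature(s): ",
              paste(utils::head(unique(out$feature[!known]), 5), collapse = ", "))
      out <- out[known]
      keys <- keys[known]
    }
    out[, feature := unname(lk[keys])]
    if (!is.numeric(out$value) && !all(is.na(out$value))) {
      sus <- suppressWarnings(as.numeric(out$value))
      bad <- which(!is.na(out$value) & is.na(sus))
      if (length(bad))
        stop("format error: non-numeric value in rows ",
             paste(utils::head(bad, 3), collapse = ", "))
      out[, value := sus]
    }
  } else {
    feat_cols <- setdiff(seq_along(dt), c(id_col, sl_col))
    keys <- nn[feat_cols]
    known <- keys %in% names(lk)
    if (any(!known))
      message("ignoring ", sum(!known), " non-panel column(s): ",
              paste(utils::head(names(dt)[feat_cols[!known]], 5), collapse = ", "))
    feat_cols <- feat_cols[known]
    if (!length(feat_cols)) stop("format error: no panel feature columns found")
    for (j in feat_cols) {
      col <- dt[[j]]
      if (is.character(col)) {
        sus <- suppressWarnings(as.numeric(col))
        bad <- which(!is.na(col) & is.na(sus))
        if (length(bad))
          stop(sprintf("format error: non-numeric value in column '%s', row %d",
                       names(dt)[j], bad[1]))
        data.table::set(dt, j = j, value = sus)
      }
    }
    if (anyDuplicated(dt, by = c(id_col, sl_col)))
      stop("format error: duplicate (patient, slice) row")
    id_vars <- names(dt)[c(id_col, sl_col)]
    out <- data.table::melt(
      dt[, c(id_col, sl_col, feat_cols), with = FALSE],
      id.vars = id_vars, variable.name = "feature", value.name = "value",
      variable.factor = FALSE)
    data.table::setnames(out, id_vars, c("patient_id", "slice_index"))
    out[, feature := unname(lk[normalize_feature_name(feature)])]
  }
  feature_matrix(out)
}

#' Read a cohort label table
#'
#' CSV with header `patient_id,status[,ctsi][,radiologist_call]`; `status`
#' and `radiologist_call` take values `healthy` or `MAP`, `ctsi` is an
#' integer severity grade 0-3 (meaningful for MAP patients only).
#'
#' @param source path to a CSV file.
#' @return a `data.table` with columns `patient_id`, `status`, and optional
#'   `ctsi`, `radiologist_call`.
#' @export
read_labels <- function(source) {
  dt <- data.table::fread(source, colClasses = list(character = 1L))
  validate_labels(dt)
}

#' Validate a label table
#' @param labels data.frame with `patient_id`, `status`, optional `ctsi` and
#'   `radiologist_call`.
#' @return validated `data.table`.
#' @export
validate_labels <- function(labels) {
  dt <- data.table::as.data.table(labels)
  if (!all(c("patient_id", "status") %in% names(dt)))
    stop("labels need columns patient_id, status")
  dt[, patient_id := as.character(patient_id)]
  if (!all(dt$status %in% c("healthy", "MAP")))
    stop("status must be 'healthy' or 'MAP'")
  if (anyDuplicated(dt$patient_id)) stop("duplicate patient_id in labels")
  if ("ctsi" %in% names(dt)) {
    dt[, ctsi := as.integer(ctsi)]
    ok <- is.na(dt$ctsi) | (dt$ctsi >= 0L & dt$ctsi <= 3L)
    if (!all(ok)) stop("ctsi must be in 0..3")
  }
  if ("radiologist_call" %in% names(dt)) {
    ok <- is.na(dt$radiologist_call) |
      dt$radiologist_call %in% c("healthy", "MAP")
    if (!all(ok)) stop("radiologist_call must be 'healthy' or 'MAP'")
  }
  dt[]
}

#' Exclude patients with incomplete feature panels
#'
#' A patient is excluded iff any panel feature is missing or non-finite on
#' any of that patient's slices — the incomplete-extraction pathway: feature
#' files that fail to cover the panel make a patient unusable, since the
#' formal model requires one action per (slice, feature). Coverage is judged
#' against the panel features that occur in the table at all; a feature
#' column absent for the whole cohort means the upstream extractor used a
#' narrower panel and is noted, not held against every patient.
#'
#' The filter is idempotent and permutation-invariant, and conserves
#' patients: retained plus excluded ids partition the input.
#'
#' @param fm a feature matrix.
#' @param panel the feature panel.
#' @return a list with `matrix` (retained rows, complete panel coverage) and
#'   `report`, an exclusion report: `data.table` of `patient_id` and
#'   comma-joined `missing` feature names, plus attribute `retained_ids`.
#' @export
filter_incomplete_patients <- function(fm, panel = canonical_panel()) {
  fm <- validate_feature_matrix(fm)
  validate_panel(panel)
  feats <- intersect(panel_features(panel), unique(fm$feature))
  absent <- setdiff(panel_features(panel), feats)
  if (length(absent))
    message("panel feature(s) absent from the whole table: ",
            paste(absent, collapse = ", "))
  if (!length(feats)) stop("no panel features present in matrix")
  # complete = every (slice, feature) cell present and finite
  slice_n <- fm[, .(n_slices = data.table::uniqueN(slice_index)), by = patient_id]
  cover <- fm[!is.na(value) & feature %in% feats,
              .(n_ok = .N), by = .(patient_id, feature)]
  grid <- data.table::CJ(patient_id = slice_n$patient_id, feature = feats)
  cover <- merge(grid, cover, by = c("patient_id", "feature"), all.x = TRUE)
  cover[is.na(n_ok), n_ok := 0L]
  cover <- merge(cover, slice_n, by = "patient_id")
  bad <- cover[n_ok < n_slices]
  excl <- bad[, .(missing = paste(sort(feature), collapse = ",")),
              by = patient_id][order(patient_id)]
  retained <- setdiff(unique(fm$patient_id), excl$patient_id)
  if (!length(retained))
    warning("all patients excluded: no complete panel coverage")
  out <- fm[patient_id %in% retained & feature %in% feats]
  report <- structure(excl, retained_ids = sort(retained))
  list(matrix = out, report = report)
}

#' Write an exclusion report as JSON
#'
#' @param report the `report` element of [filter_incomplete_patients()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  lst <- lapply(seq_len(nrow(report)), function(i)
    list(patient_id = report$patient_id[i],
         missing = strsplit(report$missing[i], ",", fixed = TRUE)[[1]]))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a feature matrix as tidy CSV
#'
#' Long form `patient_id,slice_index,feature_name,value`; missing values are
#' written as empty cells and survive a read round-trip.
#'
#' @param fm a feature matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  out <- data.table::copy(fm)
  data.table::setnames(out, "feature", "feature_name")
  data.table::fwrite(out, path, na = "")
  invisible(path)
}
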