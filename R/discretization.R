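#' Ordinal level names
#'
#' Five ordered levels used to discretize every feature: ordinals 0-4 named
#' `very_low`, `low`, `basal`, `high`, `very_high`. For a non-default number
#' of levels the names are `l0`, `l1`, ...
#'
#' @param n_levels number of levels.
#' @return character vector of level names, ordered by ordinal.
#' @export
level_names <- function(n_levels = 5L) {
  if (n_levels == 5L) c("very_low", "low", "basal", "high", "very_high")
  else paste0("l", seq_len(n_levels) - 1L)
}

#' Fit an equal-width discretization scheme
#'
#' For each panel feature, partitions the observed cohort range
#' `[min, max]` into `n_levels` intervals of equal width; the interval edges
#' become the scheme. Fitting is transductive by default — the whole retained
#' cohort, exemplars included, defines the edges; there is no train/test
#' split at this stage. A scheme fitted on one cohort can be frozen and
#' applied to new patients (out-of-range values clamp, see
#' [assign_level()]).
#'
#' Constant features (cohort min equals max) carry no information; they are
#' flagged `degenerate` and every value maps to the middle level `basal`.
#'
#' @param fm a complete (post-filter) feature matrix.
#' @param panel the feature panel.
#' @param n_levels number of levels, default 5.
#' @return an object of class `discretization_scheme`: a `data.table` with
#'   one row per feature, columns `feature`, `e0`..`e<n>`, `degenerate`.
#' @export
fit_discretization <- function(fm, panel = canonical_panel(), n_levels = 5L) {
  if (!is.numeric(n_levels) || n_levels < 2L) stop("n_levels must be >= 2")
  n_levels <- as.integer(n_levels)
  fm <- validate_feature_matrix(fm)
  validate_panel(panel)
  feats <- panel_features(panel)
  absent <- setdiff(feats, unique(fm$feature))
  if (length(absent))
    stop("features absent from matrix: ", paste(absent, collapse = ", "))
  if (anyNA(fm[feature %in% feats, value]))
    stop("matrix has missing panel values; run filter_incomplete_patients first")
  rng <- fm[feature %in% feats,
            .(lo = min(value), hi = max(value)), by = feature]
  edges <- t(mapply(function(lo, hi) seq(lo, hi, length.out = n_levels + 1L),
                    rng$lo, rng$hi))
  colnames(edges) <- paste0("e", 0:n_levels)
  sch <- data.table::data.table(feature = rng$feature, edges,
                                degenerate = rng$lo == rng$hi)
  # canonical panel order
  sch <- sch[match(feats, feature)]
  structure(sch, class = c("discretization_scheme", class(sch)),
            n_levels = n_levels)
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat("Discretization scheme:", nrow(x), "features,",
      attr(x, "n_levels"), "equal-width levels",
      if (any(x$degenerate)) sprintf("(%d degenerate)", sum(x$degenerate)) else "",
      "\n")
  invisible(x)
}

#' Assign ordinal levels to values of one feature
#'
#' Intervals are half-open `[e_i, e_{i+1})` except the last, which is closed
#' at the top so the cohort maximum maps to the highest level. Values outside
#' the fitted range (possible when a frozen scheme is applied to new
#' patients) clamp to the extreme levels with a warning. Degenerate features
#' map every value to `basal`.
#'
#' @param value numeric vector of finite values.
#' @param feature feature name (one of the scheme's features).
#' @param scheme a fitted `discretization_scheme`.
#' @return integer vector of ordinals `0..n_levels-1`, with the level name
#'   as a `names` attribute.
#' @export
assign_level <- function(value, feature, scheme) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  row <- which(scheme$feature == feature)
  if (!length(row)) stop("unknown feature: ", feature)
  if (anyNA(value) || !all(is.finite(value)))
    stop("non-finite value for feature ", feature)
  n <- attr(scheme, "n_levels")
  nms <- level_names(n)
  if (scheme$degenerate[row]) {
    ord <- rep.int(as.integer(n %/% 2), length(value))
    return(stats::setNames(ord, nms[ord + 1L]))
  }
  edges <- as.numeric(scheme[row, paste0("e", 0:n), with = FALSE])
  below <- value < edges[1]; above <- value > edges[n + 1L]
  if (any(below) || any(above))
    warning(sprintf("%d value(s) outside fitted range of '%s'; clamped",
                    sum(below) + sum(above), feature))
  ord <- findInterval(value, edges, rightmost.closed = TRUE)
  ord <- pmin(pmax(ord, 1L), n) - 1L
  stats::setNames(as.integer(ord), nms[ord + 1L])
}

#' Discretize a whole feature matrix
#'
#' Maps every value to its ordinal level under the scheme and attaches the
#' action label used by the formal model: the normalized feature name joined
#' to the level name by a double underscore, e.g. `mean__very_high`.
#'
#' @param fm a complete feature matrix covering all scheme features.
#' @param scheme a fitted `discretization_scheme`.
#' @return a `data.table` with columns `patient_id`, `slice_index`,
#'   `feature`, `level` (ordinal), `level_name`, `action`.
#' @export
discretize_matrix <- function(fm, scheme) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  fm <- validate_feature_matrix(fm)
  fm <- fm[feature %in% scheme$feature]
  if (nrow(fm) == 0L) stop("no scheme features present in matrix")
  n <- attr(scheme, "n_levels")
  nms <- level_names(n)
  out <- fm[, {
    lv <- assign_level(value, .BY$feature, scheme)
    .(patient_id = patient_id, slice_index = slice_index,
      level = unname(lv))
  }, by = feature]
  out[, level_name := nms[level + 1L]]
  out[, action := action_name(feature, level_name)]
  data.table::setcolorder(out, c("patient_id", "slice_index", "feature",
                                 "level", "level_name", "action"))
  data.table::setkey(out, patient_id, slice_index, feature)
  out[]
}

#' Canonical action name for a (feature, level) pair
#'
#' @param feature feature name(s).
#' @param level_name level name(s).
#' @return lowercase action label(s), alphanumerics and underscores only.
#' @export
action_name <- function(feature, level_name) {
  paste0(normalize_feature_name(feature), "__", level_name)
}
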