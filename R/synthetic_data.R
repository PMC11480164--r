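#' Synthetic cohort configuration
#'
#' Defaults encode the emulated study design: 40 healthy and 40 mild-acute-
#' pancreatitis (MAP) patients; per-patient slice counts drawn from
#' truncated normals with mean 19.7 on range 6-27 (healthy) and 22.7 on
#' range 19-31 (MAP), the ranges read as 95% intervals (sd = width/3.92);
#' class signal as a mean shift of `delta` pooled standard deviations on the
#' discriminative features (all FIRST and SHAPE features by default), scaled
#' by CT severity grade through the multiplier `m(ctsi) = (1 + ctsi) / 4`;
#' CTSI grades 0-3 assigned uniformly among MAP patients.
#'
#' Per-feature baselines are nuisance parameters (no feature distributions
#' are being emulated, only class structure): baseline means are drawn once
#' per cohort from a log-normal prior and within-slice noise is 20% of the
#' baseline, so the signal is scale-free in sd units.
#'
#' @param n_healthy,n_map group sizes.
#' @param slice_mean_healthy,slice_range_healthy,slice_mean_map,slice_range_map
#'   slice-count distribution parameters per class.
#' @param discriminative feature names carrying class signal.
#' @param delta effect size in pooled-sd units (0 = null cohort).
#' @param ctsi_probs mixing proportions over grades 0-3 (sums to 1).
#' @param baseline_meanlog,baseline_sdlog log-normal prior for baselines.
#' @param noise_cv within-slice noise as a fraction of baseline mean.
#' @param seed integer RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 40L, n_map = 40L,
                          slice_mean_healthy = 19.7,
                          slice_range_healthy = c(6, 27),
                          slice_mean_map = 22.7,
                          slice_range_map = c(19, 31),
                          discriminative = NULL,
                          delta = 3,
                          ctsi_probs = rep(0.25, 4),
                          baseline_meanlog = log(50),
                          baseline_sdlog = 1.5,
                          noise_cv = 0.2,
                          seed = 1L) {
  panel <- canonical_panel()
  if (is.null(discriminative))
    discriminative <- c(panel$FIRST, panel$SHAPE)
  cfg <- list(n_healthy = as.integer(n_healthy), n_map = as.integer(n_map),
              slice_mean_healthy = slice_mean_healthy,
              slice_range_healthy = slice_range_healthy,
              slice_mean_map = slice_mean_map,
              slice_range_map = slice_range_map,
              discriminative = discriminative, delta = delta,
              ctsi_probs = ctsi_probs,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              noise_cv = noise_cv, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_healthy >= 0L, cfg$n_map >= 0L)
  rng_ok <- function(m, r) r[1] <= m && m <= r[2]
  if (!rng_ok(cfg$slice_mean_healthy, cfg$slice_range_healthy) ||
      !rng_ok(cfg$slice_mean_map, cfg$slice_range_map))
    stop("slice ranges must contain their means")
  if (abs(sum(cfg$ctsi_probs) - 1) > 1e-8 || length(cfg$ctsi_probs) != 4L)
    stop("ctsi_probs must be 4 proportions summing to 1")
  if (cfg$delta > 0 && !length(cfg$discriminative))
    stop("empty discriminative set with delta > 0")
  unknown <- setdiff(cfg$discriminative, panel_features(canonical_panel()))
  if (length(unknown))
    stop("discriminative features not in panel: ",
         paste(unknown, collapse = ", "))
  invisible(cfg)
}

# Truncated-normal draw by rejection; ranges here retain >90% mass so a few
# rounds suffice.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a seeded synthetic cohort
#'
#' Produces a complete feature matrix and label table with the configured
#' class structure: healthy slice values are `Normal(mu_f, sigma_f)` per
#' feature; MAP slice values on discriminative features are shifted by
#' `delta * sigma_f * (1 + ctsi) / 4`; non-discriminative features are
#' identically distributed in both classes. MAP patients are named
#' `CSV<k>`, healthy patients `H<k>`. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#' @return list with `features` (feature matrix) and `labels`
#'   (`patient_id`, `status`, `ctsi`).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  validate_cohort_config(cfg)
  set.seed(cfg$seed)
  panel <- canonical_panel()
  feats <- panel_features(panel)
  nf <- length(feats)
  mu <- stats::rlnorm(nf, cfg$baseline_meanlog, cfg$baseline_sdlog)
  sigma <- cfg$noise_cv * mu
  sd_from_range <- function(r) (r[2] - r[1]) / (2 * stats::qnorm(0.975))

  ids <- c(sprintf("H%02d", seq_len(cfg$n_healthy)),
           sprintf("CSV%d", seq_len(cfg$n_map)))
  status <- rep(c("healthy", "MAP"), c(cfg$n_healthy, cfg$n_map))
  n_slices <- round(c(
    rtruncnorm(cfg$n_healthy, cfg$slice_mean_healthy,
               sd_from_range(cfg$slice_range_healthy),
               cfg$slice_range_healthy[1], cfg$slice_range_healthy[2]),
    rtruncnorm(cfg$n_map, cfg$slice_mean_map,
               sd_from_range(cfg$slice_range_map),
               cfg$slice_range_map[1], cfg$slice_range_map[2])))
  ctsi <- ifelse(status == "MAP",
                 sample(0:3, length(ids), replace = TRUE,
                        prob = cfg$ctsi_probs), NA_integer_)

  shift_mask <- feats %in% cfg$discriminative
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ns <- n_slices[i]
    shift <- if (status[i] == "MAP")
      cfg$delta * sigma * shift_mask * (1 + ctsi[i]) / 4
    else rep(0, nf)
    vals <- stats::rnorm(ns * nf,
                         mean = rep(mu + shift, each = ns),
                         sd = rep(sigma, each = ns))
    rows[[i]] <- data.table::data.table(
      patient_id = ids[i],
      slice_index = rep(seq_len(ns), times = nf),
      feature = rep(feats, each = ns),
      value = vals)
  }
  fm <- feature_matrix(data.table::rbindlist(rows))
  labels <- data.table::data.table(patient_id = ids, status = status,
                                   ctsi = as.integer(ctsi))
  list(features = fm, labels = validate_labels(labels))
}

#' Inject missing values into a feature matrix
#'
#' Blanks one feature for the named patients, reproducing the
#' incomplete-extraction pathway that the exclusion filter handles.
#'
#' @param fm a feature matrix.
#' @param patient_ids ids to affect (may be empty: identity).
#' @param feature the feature to blank.
#' @return a modified copy of `fm`.
#' @export
inject_missing <- function(fm, patient_ids, feature) {
  fm <- data.table::copy(validate_feature_matrix(fm))
  if (!length(patient_ids)) return(fm)
  if (!feature %in% unique(fm$feature)) stop("unknown feature: ", feature)
  missing_ids <- setdiff(patient_ids, unique(fm$patient_id))
  if (length(missing_ids))
    stop("unknown patient id(s): ", paste(missing_ids, collapse = ", "))
  feat <- feature
  ids <- patient_ids
  fm[patient_id %in% ids & feature == feat, value := NA_real_]
  fm[]
}
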