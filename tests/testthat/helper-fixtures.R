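# Small deterministic fixtures, built in code at test time.

# Wide-format CSV with 2 patients x 2 slices x 3 panel features.
write_tiny_wide_csv <- function(path, extra_col = FALSE, na_cell = FALSE) {
  df <- data.frame(
    patient_id = rep(c("A", "B"), each = 2),
    slice_index = rep(1:2, 2),
    Mean = c(1, 2, 3, 4),
    JointEntropy = c(5, 6, 7, 8),
    SurfaceArea = c(9, 10, 11, 12))
  if (extra_col) df$Energy <- 13:16
  if (na_cell) df$Mean[2] <- NA
  write.csv(df, path, row.names = FALSE, na = "NA")
  path
}

# Minimal complete cohort: `n_pat` patients, `n_slices` slices, full panel,
# seeded standard-normal values (with optional per-patient mean shifts).
tiny_cohort_fm <- function(n_pat = 4L, n_slices = 3L, shifts = NULL,
                           seed = 42L) {
  set.seed(seed)
  feats <- panel_features(canonical_panel())
  if (is.null(shifts)) shifts <- rep(0, n_pat)
  rows <- lapply(seq_len(n_pat), function(i) {
    data.frame(patient_id = sprintf("P%02d", i),
               slice_index = rep(seq_len(n_slices), length(feats)),
               feature = rep(feats, each = n_slices),
               value = rnorm(n_slices * length(feats), mean = shifts[i]))
  })
  feature_matrix(do.call(rbind, rows))
}

tiny_labels <- function(ids, status, ctsi = NULL) {
  df <- data.table::data.table(patient_id = ids, status = status)
  if (!is.null(ctsi)) df$ctsi <- as.integer(ctsi)
  validate_labels(df)
}

# Default synthetic study cohort with the incomplete-extraction pathway:
# 80 patients, one healthy and three MAP with a blanked feature.
study_fixture <- function(seed = 11L, delta = 3) {
  co <- generate_cohort(cohort_config(seed = seed, delta = delta))
  fm <- inject_missing(co$features, c("H01", "CSV1", "CSV2", "CSV3"), "Mean")
  list(features = fm, labels = co$labels)
}
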