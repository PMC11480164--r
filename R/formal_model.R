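#' Build a patient's labeled transition system
#'
#' Encodes one patient's discretized slice series as a linear labeled
#' transition system (LTS): states `0..N` with a single transition
#' `(s, a, s+1)` per state `s < N`. Slices are visited in ascending
#' `slice_index`; within a slice, features are emitted in canonical panel
#' order, class by class. Each transition's action is the discretized
#' (feature, level) label, so `N = n_slices * n_features`.
#'
#' The chain encoding is deliberate: classification depends only on the
#' presence or absence of actions along the series, which a sequential
#' composition captures; parallel process-algebra operators would introduce
#' nondeterminism with no diagnostic role.
#'
#' @param dm a discretized matrix ([discretize_matrix()]).
#' @param patient_id the patient to encode.
#' @param panel the feature panel (fixes within-slice order).
#' @return an object of class `patient_lts`: list with `patient_id`,
#'   `actions` (character vector, transition `i` links state `i-1` to `i`)
#'   and `n_states`.
#' @export
build_patient_model <- function(dm, patient_id, panel = canonical_panel()) {
  validate_panel(panel)
  pid <- as.character(patient_id)
  sub <- dm[dm$patient_id == pid]
  if (nrow(sub) == 0L) stop("patient absent from discretized matrix: ", pid)
  feats <- panel_features(panel)
  sub <- sub[sub$feature %in% feats]
  sub[, .ford := match(feature, feats)]
  data.table::setorder(sub, slice_index, .ford)
  n_slices <- data.table::uniqueN(sub$slice_index)
  if (n_slices == 0L) stop("patient has zero slices: ", pid)
  if (nrow(sub) != n_slices * length(feats))
    stop("incomplete (slice, feature) grid for patient ", pid)
  lts <- structure(list(patient_id = pid, actions = sub$action,
                        n_states = nrow(sub) + 1L),
                   class = "patient_lts")
  validate_lts(lts)
}

#' Validate the linear-chain invariants of an LTS
#'
#' @param lts a `patient_lts`.
#' @return the LTS, invisibly-validated; errors if invalid.
#' @export
validate_lts <- function(lts) {
  if (!inherits(lts, "patient_lts")) stop("not a patient_lts")
  if (length(lts$actions) < 1L) stop("LTS must have at least one transition")
  if (lts$n_states != length(lts$actions) + 1L)
    stop("chain property violated: n_states must equal n_transitions + 1")
  if (!all(grepl("^[a-z0-9_]+$", lts$actions)))
    stop("action names must be lowercase alphanumerics and underscores")
  lts
}

#' @export
print.patient_lts <- function(x, ...) {
  cat(sprintf("Patient LTS '%s': %d states, %d transitions, alphabet %d\n",
              x$patient_id, x$n_states, length(x$actions),
              length(action_alphabet(x))))
  invisible(x)
}

#' Action alphabet of an LTS
#'
#' @param lts a `patient_lts`.
#' @return sorted character vector of the distinct transition labels.
#' @export
action_alphabet <- function(lts) {
  validate_lts(lts)
  sort(unique(lts$actions))
}

# Process identifier token: patient id reduced to alphanumerics/underscore.
pid_token <- function(pid) gsub("[^[:alnum:]_]", "_", pid)

#' Serialize an LTS in CCS syntax
#'
#' One defining equation per state, in the minimal CCS dialect used here
#' (action prefix `.`, `nil`, `;` terminators; no restriction, relabeling or
#' parallel composition):
#' \preformatted{P<pid>_0 = mean__high.P<pid>_1;
#' P<pid>_1 = nil;}
#' The text round-trips through [parse_ccs()] to an identical LTS.
#'
#' @param lts a `patient_lts`.
#' @return a single string of CCS equations.
#' @export
serialize_ccs <- function(lts) {
  validate_lts(lts)
  tok <- pid_token(lts$patient_id)
  n <- length(lts$actions)
  eqs <- sprintf("P%s_%d = %s.P%s_%d;", tok, 0:(n - 1L), lts$actions,
                 tok, 1:n)
  paste0(paste(c(eqs, sprintf("P%s_%d = nil;", tok, n)), collapse = "\n"),
         "\n")
}

#' Parse CCS text back into an LTS
#'
#' Inverse of [serialize_ccs()] for the linear-chain dialect.
#'
#' @param text CCS equations as a single string.
#' @param patient_id id to attach; default recovered from the process names.
#' @return a `patient_lts`.
#' @export
parse_ccs <- function(text, patient_id = NULL) {
  lines <- grep(";", strsplit(text, "\n", fixed = TRUE)[[1]],
                fixed = TRUE, value = TRUE)
  m <- regmatches(lines,
    regexec("^P(.+)_([0-9]+) = (?:([a-z0-9_]+)\\.P(.+)_([0-9]+)|nil);$",
            trimws(lines)))
  if (any(lengths(m) == 0L)) stop("CCS parse error near: ",
                                  lines[which(lengths(m) == 0L)[1]])
  tab <- do.call(rbind, m)
  tok <- unique(tab[, 2])
  if (length(tok) != 1L) stop("CCS parse error: multiple process families")
  src <- as.integer(tab[, 3])
  ord <- order(src)
  acts <- tab[ord, 4]
  acts <- acts[nzchar(acts)]
  if (!length(acts)) stop("CCS parse error: no transitions")
  structure(list(patient_id = patient_id %||% tok, actions = acts,
                 n_states = length(acts) + 1L),
            class = "patient_lts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build LTS models for every patient in a discretized matrix
#'
#' @param dm a discretized matrix.
#' @param panel the feature panel.
#' @return named list of `patient_lts`, one per patient, sorted by id.
#' @export
build_cohort_models <- function(dm, panel = canonical_panel()) {
  ids <- sort(unique(dm$patient_id))
  stats::setNames(lapply(ids, build_patient_model, dm = dm, panel = panel),
                  ids)
}
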