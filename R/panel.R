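#' Normalize a feature name
#'
#' Feature names arrive in two spellings: prose ("Joint entropy") from
#' published feature tables and camel case ("JointEntropy") from extractors
#' such as PyRadiomics. Matching is therefore case-insensitive after
#' stripping spaces and punctuation, so both spellings map to the same key.
#'
#' @param x character vector of feature names.
#' @return character vector of normalized keys (lowercase alphanumerics).
#' @examples
#' normalize_feature_name(c("Joint entropy", "JointEntropy"))
#' @export
normalize_feature_name <- function(x) {
  stopifnot(is.character(x))
  tolower(gsub("[^[:alnum:]]+", "", x))
}

# The 22-feature diagnostic panel, six radiomic feature families.
# GrayLevelNonUniformity exists in both the GLSZM and GLRLM catalogues of
# standard extractors; here it belongs to GLRLM.
.panel_classes <- list(
  FIRST = c("10Percentile", "Mean", "Median", "Skewness", "Uniformity"),
  GLCM  = c("Imc2", "JointEntropy", "SumEntropy", "MaximumProbability"),
  GLDM  = c("DependenceEntropy", "LowGrayLevelEmphasis",
            "DependenceNonUniformity"),
  GLSZM = c("ZoneEntropy", "SmallAreaHighGrayLevelEmphasis",
            "SizeZoneNonUniformity"),
  SHAPE = c("Maximum2DDiameterRow", "MinorAxisLength", "SurfaceArea"),
  GLRLM = c("GrayLevelNonUniformity", "LowGrayLevelRunEmphasis",
            "RunEntropy", "ShortRunLowGrayLevelEmphasis")
)

#' The canonical diagnostic feature panel
#'
#' Returns the fixed 22-feature panel used throughout the pipeline: six
#' radiomic feature families (FIRST = first-order intensity statistics,
#' GLCM/GLDM/GLSZM/GLRLM = gray-level texture matrices, SHAPE = geometric
#' descriptors), each holding an ordered list of feature names. Panel order
#' is deterministic; downstream model construction emits features in this
#' order, class by class.
#'
#' @return An object of class `feature_panel`: a named list of character
#'   vectors, one per feature class.
#' @examples
#' p <- canonical_panel()
#' names(p)
#' panel_features(p)
#' @export
canonical_panel <- function() {
  structure(.panel_classes, class = "feature_panel")
}

#' All feature names of a panel, in canonical order
#'
#' @param panel a `feature_panel`.
#' @return character vector of feature names, class by class.
#' @export
panel_features <- function(panel) {
  stopifnot(inherits(panel, "feature_panel"))
  unlist(panel, use.names = FALSE)
}

#' Validate a feature panel
#'
#' Checks the structural invariants: exactly six named classes, no duplicate
#' feature names across classes (after normalization), non-empty classes.
#'
#' @param panel a `feature_panel`.
#' @return the panel, invisibly; errors if invalid.
#' @export
validate_panel <- function(panel) {
  if (!inherits(panel, "feature_panel") || !is.list(panel))
    stop("not a feature_panel")
  if (length(panel) != 6L || is.null(names(panel)))
    stop("panel must have exactly 6 named classes")
  feats <- panel_features(panel)
  if (any(lengths(panel) == 0L)) stop("panel classes must be non-empty")
  keys <- normalize_feature_name(feats)
  if (anyDuplicated(keys)) stop("duplicate feature names across panel")
  invisible(panel)
}

#' @export
print.feature_panel <- function(x, ...) {
  cat("Feature panel:", length(panel_features(x)), "features in",
      length(x), "classes\n")
  for (cl in names(x))
    cat(sprintf("  %-6s %s\n", cl, paste(x[[cl]], collapse = ", ")))
  invisible(x)
}

# Map arbitrary column spellings onto panel features; returns a named
# character vector canonical_name[normalized_key].
panel_lookup <- function(panel) {
  feats <- panel_features(panel)
  stats::setNames(feats, normalize_feature_name(feats))
}
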