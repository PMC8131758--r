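#' Class labels of the six-class micronucleus assay taxonomy
#'
#' The scoring taxonomy distinguishes mononucleated (`MONO`), binucleated
#' (`BN`) and polynucleated (`POLY`, 3--4 main nuclei) cells, the
#' micronucleated variants of the first two (`MONO_MN`, `BN_MN`) and cells
#' with irregular morphology (`IRREG`: overlapping nuclei, nuclei of unequal
#' size or staining intensity, or irregular nuclear shape) which must be
#' excluded from assay scoring. Classifier predictions may additionally be
#' `"UNKNOWN"` when no class fits well; `UNKNOWN` is never a ground-truth
#' label.
#'
#' @return Character vector of the six trainable class labels.
#' @export
mn_classes <- function() {
  c("MONO", "MONO_MN", "BN", "BN_MN", "POLY", "IRREG")
}

#' Truth label implied by a cell's geometry
#'
#' For regular morphology the label is a pure function of the number of main
#' nuclei and the presence of micronuclei; any irregular morphology maps to
#' `IRREG` regardless of nucleus or micronucleus counts.
#'
#' @param n_nuclei Number of main nuclei (1--4).
#' @param n_mn Number of micronuclei (>= 0).
#' @param irregular_mode One of `"none"`, `"overlapping_nuclei"`,
#'   `"size_mismatch"`, `"intensity_mismatch"`, `"shape_irregular"`.
#' @return A single class label string.
#' @export
label_from_geometry <- function(n_nuclei, n_mn, irregular_mode = "none") {
  stopifnot(length(n_nuclei) == 1, length(n_mn) == 1)
  if (!irregular_mode %in% c("none", irregular_modes()))
    stop("unknown irregular_mode: ", irregular_mode)
  if (n_nuclei < 1 || n_nuclei > 4) stop("n_nuclei must be in 1..4")
  if (n_mn < 0) stop("n_mn must be >= 0")
  if (irregular_mode != "none") return("IRREG")
  if (n_nuclei == 1) return(if (n_mn > 0) "MONO_MN" else "MONO")
  if (n_nuclei == 2) return(if (n_mn > 0) "BN_MN" else "BN")
  "POLY"
}

irregular_modes <- function() {
  c("overlapping_nuclei", "size_mismatch", "intensity_mismatch",
    "shape_irregular")
}

assert_class_label <- function(label, allow_unknown = FALSE) {
  ok <- mn_classes()
  if (allow_unknown) ok <- c(ok, "UNKNOWN")
  bad <- setdiff(unique(label), ok)
  if (length(bad))
    stop("invalid class label(s): ", paste(bad, collapse = ", "))
  invisible(label)
}
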