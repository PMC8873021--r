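#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' StudyDesign: treatment groups, donors and blank runs of a screen
#'
#' The paired design of an enviromimetic organoid screen: every donor is
#' treated with every compound, the first group label is the vehicle control,
#' and a number of blank (carrier-only) LC/MS runs accompany the samples.
#'
#' @slot groups Ordered character vector of group labels; the first element is
#'   the vehicle control. Labels must be unique and at least two are required.
#' @slot donors Character vector of donor labels (identical across groups);
#'   at least two.
#' @slot blanks Integer count of blank runs.
#' @slot seed Integer master RNG seed for synthetic generation.
#' @export
setClass("StudyDesign",
  slots = c(groups = "character", donors = "character",
            blanks = "integer", seed = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@groups) < 2L)
    msg <- c(msg, "at least 2 groups (control + >=1 treatment) required")
  if (anyDuplicated(object@groups))
    msg <- c(msg, "group labels must be unique (control present exactly once)")
  if (length(unique(object@donors)) < 2L)
    msg <- c(msg, "at least 2 donors required")
  if (length(object@blanks) != 1L || is.na(object@blanks) || object@blanks < 0L)
    msg <- c(msg, "'blanks' must be a single non-negative count")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a StudyDesign
#'
#' @param groups Ordered group labels, vehicle control first.
#' @param donors Donor labels shared by all groups, or a single count n
#'   expanded to \code{D1..Dn}.
#' @param blanks Number of blank runs.
#' @param seed Master RNG seed.
#' @return A \linkS4class{StudyDesign}.
#' @examples
#' StudyDesign(c("vehicle", "WIN", "IL17a"), donors = 4)
#' @export
StudyDesign <- function(groups, donors = 4, blanks = 3, seed = 1) {
  if (is.numeric(donors) && length(donors) == 1L)
    donors <- paste0("D", seq_len(donors))
  new("StudyDesign", groups = as.character(groups),
      donors = as.character(donors), blanks = as.integer(blanks),
      seed = as.integer(seed))
}

#' ExtractionConfig: windows for targeted peak-height extraction
#'
#' Defaults follow standard practice for a targeted high-resolution assay:
#' a +/- 5 ppm m/z tolerance, a +/- 7.5 s apex retention-time tolerance around
#' a study-wide consensus apex, itself located within a +/- 0.5 min search
#' window of the library retention time.
#'
#' @slot ppmTol m/z tolerance in parts-per-million (half-width).
#' @slot apexTol Apex retention-time tolerance in seconds (half-width).
#' @slot searchWindow Initial retention-time search window in seconds
#'   (half-width) for consensus-apex localization.
#' @slot minScans Minimum number of in-window scans for a peak.
#' @export
setClass("ExtractionConfig",
  slots = c(ppmTol = "numeric", apexTol = "numeric",
            searchWindow = "numeric", minScans = "integer"))

setValidity("ExtractionConfig", function(object) {
  msg <- character()
  for (s in c("ppmTol", "apexTol", "searchWindow"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  if (!length(msg) && object@apexTol > object@searchWindow)
    msg <- c(msg, "'apexTol' must not exceed 'searchWindow'")
  if (length(object@minScans) != 1L || object@minScans < 1L)
    msg <- c(msg, "'minScans' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ExtractionConfig-class
#' @param ppm_tol,apex_tol,search_window,min_scans See slot documentation.
#' @return An \linkS4class{ExtractionConfig}.
#' @export
ExtractionConfig <- function(ppm_tol = 5, apex_tol = 7.5, search_window = 30,
                             min_scans = 1) {
  new("ExtractionConfig", ppmTol = ppm_tol, apexTol = apex_tol,
      searchWindow = search_window, minScans = as.integer(min_scans))
}

#' MsRun: one centroided MS1 LC/MS run
#'
#' A flat centroid table (retention time, polarity, m/z, intensity) standing
#' for the RT-ordered scans of one sample or blank run. Scans are the unique
#' (rt, polarity) combinations; centroids are m/z-sorted within each scan.
#'
#' @slot sampleId Unique run identifier.
#' @slot role \code{"sample"} or \code{"blank"}.
#' @slot group,donor Group and donor labels (\code{NA} for blanks).
#' @slot peaks data.frame with columns \code{rt} (seconds, non-decreasing),
#'   \code{polarity} (\code{"pos"}/\code{"neg"}), \code{mz}, \code{intensity}.
#' @export
setClass("MsRun",
  slots = c(sampleId = "character", role = "character",
            group = "character", donor = "character", peaks = "data.frame"))

setValidity("MsRun", function(object) {
  msg <- character()
  if (!object@role %in% c("sample", "blank"))
    msg <- c(msg, "'role' must be 'sample' or 'blank'")
  p <- object@peaks
  need <- c("rt", "polarity", "mz", "intensity")
  if (!all(need %in% names(p))) {
    msg <- c(msg, sprintf("'peaks' needs columns %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(p)) {
    if (is.unsorted(p$rt)) msg <- c(msg, "'peaks$rt' must be non-decreasing")
    if (any(p$intensity < 0)) msg <- c(msg, "intensities must be >= 0")
    if (!all(p$polarity %in% c("pos", "neg")))
      msg <- c(msg, "polarity must be 'pos' or 'neg'")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MsRun-class
#' @param sample_id,role,group,donor,peaks See slot documentation.
#' @return An \linkS4class{MsRun}.
#' @export
MsRun <- function(sample_id, role = "sample", group = NA_character_,
                  donor = NA_character_, peaks) {
  peaks <- peaks[order(peaks$rt, peaks$polarity, peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  new("MsRun", sampleId = sample_id, role = role,
      group = as.character(group), donor = as.character(donor), peaks = peaks)
}

#' MetaboSet: analyte x run intensity matrix
#'
#' A \linkS4class{SummarizedExperiment} holding targeted peak heights
#' (assay \code{"height"}), the metabolite library as \code{rowData}, and the
#' sample sheet (sample_id, group, donor, role) as \code{colData}. Detection
#' and imputation add assays \code{"detected"} and \code{"imputed"} plus the
#' per-analyte thresholds in \code{metadata(x)$thresholds}.
#'
#' @export
setClass("MetaboSet", contains = "SummarizedExperiment")

setValidity("MetaboSet", function(object) {
  msg <- character()
  if (!"height" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'height' is required")
  need <- c("sample_id", "group", "donor", "role")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, sprintf("colData needs columns %s",
                          paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ProteomeSet: protein x sample intensity matrix
#'
#' A \linkS4class{SummarizedExperiment} with linear-scale intensities in assay
#' \code{"intensity"} (\code{NA} = missing cell) and group/donor labels in
#' \code{colData}. Normalization adds assay \code{"norm"} (log2, quantile
#' normalized).
#'
#' @export
setClass("ProteomeSet", contains = "SummarizedExperiment")

setValidity("ProteomeSet", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (!all(c("group", "donor") %in%
           colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData needs columns 'group' and 'donor'")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (any(a[!is.na(a)] <= 0))
    msg <- c(msg, "intensities must be > 0 where present")
  if (length(msg)) msg else TRUE
})

#' DetectionThresholds: per-analyte blank-based detection limits
#'
#' @slot threshold Named numeric vector, one threshold per analyte, each equal
#'   to \code{max(sn_multiple * blank_statistic, floor)}.
#' @slot snMultiple Signal-to-noise multiple applied to the blank statistic.
#' @slot floor Absolute detection floor in arbitrary intensity units.
#' @export
setClass("DetectionThresholds",
  slots = c(threshold = "numeric", snMultiple = "numeric", floor = "numeric"))

setValidity("DetectionThresholds", function(object) {
  if (any(object@threshold < object@floor))
    "every threshold must be >= the floor" else TRUE
})

#' CellCycleFit: fractions and diagnostics of a DNA-content deconvolution
#'
#' @slot fractions Named numeric: \code{sub_g1}, \code{g1}, \code{s},
#'   \code{g2m}; each in [0, 1], summing to 1.
#' @slot g1Mean,g1Sd,g2Mean,g2Sd Fitted Gaussian parameters (channel units).
#' @slot residual Relative residual norm of the histogram fit.
#' @slot lowConfidence Flag set when the residual exceeds its threshold.
#' @export
setClass("CellCycleFit",
  slots = c(fractions = "numeric", g1Mean = "numeric", g1Sd = "numeric",
            g2Mean = "numeric", g2Sd = "numeric", residual = "numeric",
            lowConfidence = "logical"))

setValidity("CellCycleFit", function(object) {
  msg <- character()
  f <- object@fractions
  if (!identical(names(f), c("sub_g1", "g1", "s", "g2m")))
    msg <- c(msg, "fractions must be named sub_g1, g1, s, g2m")
  else {
    if (any(f < -1e-9 | f > 1 + 1e-9)) msg <- c(msg, "fractions must be in [0, 1]")
    if (abs(sum(f) - 1) > 1e-6) msg <- c(msg, "fractions must sum to 1")
  }
  r <- object@g2Mean / object@g1Mean
  if (is.finite(r) && (r < 1.8 - 1e-9 || r > 2.2 + 1e-9))
    msg <- c(msg, "G2 mean must lie within [1.8, 2.2] x G1 mean")
  if (length(msg)) msg else TRUE
})

#' QuadrantResult: two-channel quadrant gating of one event set
#'
#' Quadrants are defined semantically on the (cleaved PARP, phospho-H2AX)
#' channels by strict exceedance of each threshold: double-negative,
#' PARP-positive only, double-positive, H2AX-positive only.
#'
#' @slot thresholds Named numeric gates, \code{parp} and \code{h2ax}.
#' @slot counts Named integer event counts per quadrant
#'   (\code{dn}, \code{parp_pos}, \code{double_pos}, \code{h2ax_pos}).
#' @slot percentages Counts as percentages of all events (sum 100).
#' @export
setClass("QuadrantResult",
  slots = c(thresholds = "numeric", counts = "integer",
            percentages = "numeric"))

setValidity("QuadrantResult", function(object) {
  msg <- character()
  qn <- c("dn", "parp_pos", "double_pos", "h2ax_pos")
  if (!identical(names(object@counts), qn) ||
      !identical(names(object@percentages), qn))
    msg <- c(msg, "counts/percentages must be named dn, parp_pos, double_pos, h2ax_pos")
  else if (sum(object@counts) > 0 && abs(sum(object@percentages) - 100) > 1e-6)
    msg <- c(msg, "percentages must sum to 100")
  if (!identical(names(object@thresholds), c("parp", "h2ax")))
    msg <- c(msg, "thresholds must be named parp, h2ax")
  if (length(msg)) msg else TRUE
})
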