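#' Accessors
#'
#' Small accessor generics for the package's S4 classes.
#'
#' @param x,object An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("controlGroup", function(x) standardGeneric("controlGroup"))

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname accessors
#' @export
setGeneric("peaksTable", function(x) standardGeneric("peaksTable"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("quadrantCounts", function(x) standardGeneric("quadrantCounts"))

#' @rdname accessors
#' @export
setGeneric("quadrantPercentages",
           function(x) standardGeneric("quadrantPercentages"))

#' @rdname accessors
#' @export
setMethod("controlGroup", "StudyDesign", function(x) x@groups[1L])

#' The vehicle-control group label of a MetaboSet/ProteomeSet column annotation
#' is whatever its sample sheet calls the first group; for designs it is the
#' first group label by construction.
#' @rdname accessors
#' @export
setMethod("sampleSheet", "StudyDesign", function(x) {
  grid <- expand.grid(donor = x@donors, group = x@groups,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(grid$group, grid$donor, sep = "_"),
    group = grid$group, donor = grid$donor, role = "sample",
    stringsAsFactors = FALSE)
  if (x@blanks > 0L) {
    blanks <- data.frame(
      sample_id = paste0("blank_", seq_len(x@blanks)),
      group = NA_character_, donor = NA_character_, role = "blank",
      stringsAsFactors = FALSE)
    samples <- rbind(samples, blanks)
  }
  samples
})

#' @rdname accessors
#' @export
setMethod("peaksTable", "MsRun", function(x) x@peaks)

#' @rdname accessors
#' @export
setMethod("thresholds", "DetectionThresholds", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("thresholds", "QuadrantResult", function(x) x@thresholds)

#' @rdname accessors
#' @export
setMethod("fractions", "CellCycleFit", function(x) x@fractions)

#' @rdname accessors
#' @export
setMethod("quadrantCounts", "QuadrantResult", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("quadrantPercentages", "QuadrantResult", function(x) x@percentages)

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@groups), "groups x",
      length(object@donors), "donors,", object@blanks, "blanks\n")
  cat("  control:", controlGroup(object), "| treatments:",
      paste(object@groups[-1L], collapse = ", "), "\n")
})

setMethod("show", "MsRun", function(object) {
  cat(sprintf("MsRun '%s' (%s): %d centroids, %d scans\n",
              object@sampleId, object@role, nrow(object@peaks),
              nrow(unique(object@peaks[, c("rt", "polarity")]))))
})

setMethod("show", "DetectionThresholds", function(object) {
  cat(sprintf(
    "DetectionThresholds: %d analytes, S/N multiple %g, floor %g\n",
    length(object@threshold), object@snMultiple, object@floor))
  cat(sprintf("  floor binds for %d analytes\n",
              sum(object@threshold == object@floor)))
})

setMethod("show", "CellCycleFit", function(object) {
  f <- object@fractions
  cat(sprintf(
    "CellCycleFit: sub-G1 %.3f | G1 %.3f | S %.3f | G2/M %.3f\n",
    f["sub_g1"], f["g1"], f["s"], f["g2m"]))
  cat(sprintf("  G1 %.1f +/- %.1f, G2 %.1f +/- %.1f, residual %.3f%s\n",
              object@g1Mean, object@g1Sd, object@g2Mean, object@g2Sd,
              object@residual,
              if (object@lowConfidence) " (low confidence)" else ""))
})

setMethod("show", "QuadrantResult", function(object) {
  p <- object@percentages
  cat(sprintf(
    "QuadrantResult (gates parp > %.3g, h2ax > %.3g), %d events:\n",
    object@thresholds["parp"], object@thresholds["h2ax"],
    sum(object@counts)))
  cat(sprintf("  -/-: %.2f%% | PARP+: %.2f%% | +/+: %.2f%% | H2AX+: %.2f%%\n",
              p["dn"], p["parp_pos"], p["double_pos"], p["h2ax_pos"]))
})
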