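# Targeted peak-height extraction: ppm m/z windows, a study-wide consensus
# apex located inside the wide RT search window, then per-sample maximum
# centroid height inside the narrow apex tolerance.

#' ppm-based m/z window
#'
#' Half-open window \code{[mz(1 - ppm 1e-6), mz(1 + ppm 1e-6))}.
#'
#' @param mz Target m/z in Thomsons (> 0).
#' @param ppm Tolerance half-width in parts-per-million (> 0).
#' @return Numeric \code{c(low, high)}.
#' @examples
#' mzWindow(500, 5) # [499.9975, 500.0025)
#' @export
mzWindow <- function(mz, ppm) {
  .assertScalar(mz, "mz", positive = TRUE)
  .assertScalar(ppm, "ppm", positive = TRUE)
  c(mz * (1 - ppm * 1e-6), mz * (1 + ppm * 1e-6))
}

# Max-intensity in-window centroid of one run near an expected RT.
# Returns NULL when no centroid qualifies; ties at the maximum intensity are
# broken toward the earliest RT (then lowest m/z) for determinism.
.locateApex <- function(run, entry, rt_center, rt_halfwidth, config) {
  p <- run@peaks
  w <- mzWindow(entry$mz, config@ppmTol)
  sel <- p$polarity == entry$polarity &
    p$mz >= w[1] & p$mz < w[2] &
    abs(p$rt - rt_center) <= rt_halfwidth &
    p$intensity > 0
  if (!any(sel)) return(NULL)
  p <- p[sel, , drop = FALSE]
  p <- p[order(-p$intensity, p$rt, p$mz), , drop = FALSE]
  list(rt = p$rt[1L], intensity = p$intensity[1L])
}

#' Study-wide consensus apex retention time
#'
#' For each non-blank run, the maximum-intensity centroid inside the analyte's
#' m/z window and within \code{searchWindow} seconds of the library retention
#' time is located; the consensus is the median apex RT over runs with any
#' signal. \code{NULL} when no run has signal (absence is a valid outcome).
#'
#' @param runs List of \linkS4class{MsRun} (blank runs are ignored).
#' @param entry One library row (list or single-row data.frame with
#'   \code{mz}, \code{polarity}, \code{rt_seconds}).
#' @param config An \linkS4class{ExtractionConfig}.
#' @return Consensus apex RT in seconds, or \code{NULL}.
#' @export
consensusApex <- function(runs, entry, config = ExtractionConfig()) {
  entry <- as.list(entry)
  samples <- Filter(function(r) r@role == "sample", runs)
  if (!length(samples))
    stop("at least one non-blank run is required for consensus localization")
  apexes <- vapply(samples, function(r) {
    a <- .locateApex(r, entry, entry$rt_seconds, config@searchWindow, config)
    if (is.null(a)) NA_real_ else a$rt
  }, numeric(1))
  if (all(is.na(apexes))) return(NULL)
  stats::median(apexes, na.rm = TRUE)
}

#' Extract one peak-height measurement
#'
#' Height is the maximum centroid intensity over all scans within
#' \code{apexTol} seconds of the consensus apex and inside the ppm m/z window
#' (RT comparisons inclusive, m/z window half-open). Blanks are processed
#' identically to samples.
#'
#' @param run An \linkS4class{MsRun}.
#' @param entry Library row (needs \code{name}, \code{mz}, \code{polarity},
#'   \code{rt_seconds}).
#' @param consensus Consensus apex RT (must lie within
#'   \code{rt_seconds +/- searchWindow}).
#' @param config An \linkS4class{ExtractionConfig}.
#' @return data.frame row: \code{analyte}, \code{sample_id}, \code{height},
#'   \code{apex_rt} (\code{NA} when not found), \code{found}.
#' @export
extractPeak <- function(run, entry, consensus, config = ExtractionConfig()) {
  entry <- as.list(entry)
  if (abs(consensus - entry$rt_seconds) > config@searchWindow)
    stop("consensus apex lies outside the retention-time search window")
  if (nrow(run@peaks) && !any(run@peaks$polarity == entry$polarity))
    stop(sprintf("polarity mismatch: entry '%s' is %s but run '%s' has no %s scans",
                 entry$name, entry$polarity, run@sampleId, entry$polarity))
  a <- .locateApex(run, entry, consensus, config@apexTol, config)
  data.frame(analyte = entry$name, sample_id = run@sampleId,
             height = if (is.null(a)) 0 else a$intensity,
             apex_rt = if (is.null(a)) NA_real_ else a$rt,
             found = !is.null(a), stringsAsFactors = FALSE)
}

#' Build the analyte x run intensity matrix
#'
#' One row per library entry and one column per run (blanks included and
#' flagged via the sample sheet). Consensus apexes are located on the sample
#' runs only; heights come from \code{\link{extractPeak}}. Analytes with no
#' signal in any sample run get zero height everywhere. Deterministic for
#' fixed inputs.
#'
#' @param runs List of \linkS4class{MsRun} with unique sample ids.
#' @param library Metabolite library data.frame (see
#'   \code{\link{defaultMetaboliteLibrary}}).
#' @param config An \linkS4class{ExtractionConfig}.
#' @return A \linkS4class{MetaboSet} with assay \code{"height"}, assay
#'   \code{"found"} (logical), \code{rowData} = library and the consensus
#'   apex per analyte in \code{rowData(x)$consensus_rt}.
#' @export
buildIntensityMatrix <- function(runs, library,
                                 config = ExtractionConfig()) {
  ids <- vapply(runs, function(r) r@sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id among runs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n_a <- nrow(library)
  height <- matrix(0, n_a, length(runs),
                   dimnames = list(library$name, ids))
  found <- matrix(FALSE, n_a, length(runs),
                  dimnames = list(library$name, ids))
  consensus_rt <- rep(NA_real_, n_a)
  has_sample <- any(vapply(runs, function(r) r@role == "sample", logical(1)))
  for (i in seq_len(n_a)) {
    entry <- library[i, ]
    cons <- if (has_sample) consensusApex(runs, entry, config) else NULL
    if (is.null(cons)) next
    consensus_rt[i] <- cons
    for (j in seq_along(runs)) {
      m <- extractPeak(runs[[j]], entry, cons, config)
      height[i, j] <- m$height
      found[i, j] <- m$found
    }
  }
  sheet <- do.call(rbind, lapply(runs, function(r)
    data.frame(sample_id = r@sampleId, group = r@group, donor = r@donor,
               role = r@role, stringsAsFactors = FALSE)))
  rd <- S4Vectors::DataFrame(library)
  rd$consensus_rt <- consensus_rt
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(height = height, found = found),
    rowData = rd,
    colData = S4Vectors::DataFrame(sheet, row.names = ids))
  new("MetaboSet", se)
}
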