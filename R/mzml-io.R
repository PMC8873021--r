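# mzML 1.1 read/write for MsRun objects, via mzR (proteowizard backend).
# Scans are the unique (rt, polarity) combinations of the centroid table;
# the per-spectrum polarity attribute carries the ion mode.

#' Write an MsRun to an mzML file
#'
#' Centroided MS1 spectra only; the per-spectrum polarity attribute encodes
#' the ion mode. Writing is byte-deterministic for identical input.
#'
#' @param run An \linkS4class{MsRun}.
#' @param path Output path (conventionally \code{<sample_id>.mzML}).
#' @return \code{path}, invisibly.
#' @export
writeRunMzML <- function(run, path) {
  stopifnot(is(run, "MsRun"))
  p <- run@peaks
  if (!nrow(p)) stop("cannot write an empty run to mzML")
  key <- paste(format(p$rt, digits = 15), p$polarity)
  ord <- order(p$rt, p$polarity, p$mz)
  p <- p[ord, , drop = FALSE]
  key <- key[ord]
  idx <- split(seq_len(nrow(p)), factor(key, levels = unique(key)))
  pks <- lapply(idx, function(ii)
    cbind(mz = p$mz[ii], intensity = p$intensity[ii]))
  rt <- vapply(idx, function(ii) p$rt[ii[1L]], numeric(1))
  pol <- vapply(idx, function(ii)
    if (p$polarity[ii[1L]] == "pos") 1L else 0L, integer(1))
  n <- length(pks)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = pol,
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(pks, function(x) sum(x[, 2L]), numeric(1)),
    retentionTime = rt,
    basePeakMZ = vapply(pks, function(x) x[which.max(x[, 2L]), 1L], numeric(1)),
    basePeakIntensity = vapply(pks, function(x) max(x[, 2L]), numeric(1)),
    collisionEnergy = NA_real_, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(x) min(x[, 1L]), numeric(1)),
    highMZ = vapply(pks, function(x) max(x[, 1L]), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    row.names = NULL)
  mzR::writeMSData(unname(pks), path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a centroided MS1 mzML file into an MsRun
#'
#' @param path Path to an mzML file.
#' @param sample_id Run identifier; defaults to the file name without
#'   extension.
#' @param role,group,donor Run annotations.
#' @return An \linkS4class{MsRun}.
#' @export
readRunMzML <- function(path, sample_id = NULL, role = "sample",
                        group = NA_character_, donor = NA_character_) {
  if (is.null(sample_id))
    sample_id <- sub("\\.mzml$", "", basename(path), ignore.case = TRUE)
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  hdr <- mzR::header(f)
  hdr <- hdr[hdr$msLevel == 1L, , drop = FALSE]
  pk <- mzR::peaks(f)
  rows <- lapply(seq_len(nrow(hdr)), function(i) {
    x <- pk[[hdr$seqNum[i]]]
    if (!nrow(x)) return(NULL)
    data.frame(rt = hdr$retentionTime[i],
               polarity = if (hdr$polarity[i] == 1L) "pos" else "neg",
               mz = x[, 1L], intensity = x[, 2L])
  })
  peaks <- do.call(rbind, rows)
  if (is.null(peaks))
    peaks <- data.frame(rt = numeric(), polarity = character(),
                        mz = numeric(), intensity = numeric())
  MsRun(sample_id, role = role, group = group, donor = donor, peaks = peaks)
}

#' Write a set of runs plus sample sheet to a directory
#'
#' @param runs Named list of \linkS4class{MsRun}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (mzML files plus
#'   \code{samples.csv}).
#' @export
writeRunSet <- function(runs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(runs, function(r) {
    writeRunMzML(r, file.path(dir, paste0(r@sampleId, ".mzML")))
  }, character(1))
  sheet <- do.call(rbind, lapply(runs, function(r)
    data.frame(sample_id = r@sampleId, group = r@group, donor = r@donor,
               role = r@role, stringsAsFactors = FALSE)))
  sheet_path <- file.path(dir, "samples.csv")
  utils::write.csv(sheet, sheet_path, row.names = FALSE)
  invisible(c(paths, sheet_path))
}

#' Read a run set written by \code{writeRunSet}
#'
#' @param dir Directory holding \code{samples.csv} and one mzML per run.
#' @return Named list of \linkS4class{MsRun}.
#' @export
readRunSet <- function(dir) {
  sheet <- utils::read.csv(file.path(dir, "samples.csv"),
                           stringsAsFactors = FALSE)
  runs <- lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet[i, ]
    readRunMzML(file.path(dir, paste0(s$sample_id, ".mzML")),
                sample_id = s$sample_id, role = s$role,
                group = s$group, donor = s$donor)
  })
  names(runs) <- sheet$sample_id
  runs
}
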