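# Synthetic targeted-metabolomics runs: Gaussian chromatographic peaks on a
# fixed scan grid, per-run jitter, and signal-free blanks.

.FWHM_TO_SD <- 1 / (2 * sqrt(2 * log(2)))

#' Simulate centroided MS1 runs for a targeted metabolite panel
#'
#' Every sample run carries, for each analyte present in its group, one
#' Gaussian chromatographic peak (fixed FWHM) sampled on the scan grid: apex
#' height \code{base_height * 2^effect} times log-normal noise, apex retention
#' time jittered around the library value, and a single per-run centroid m/z
#' jittered in ppm around the theoretical value. Blank runs contain only
#' uniform low-intensity background centroids (below \code{floor/3}), so
#' blanks can never trigger blank-based detection downstream. Both polarity
#' streams share the scan grid; each run owns an RNG stream keyed by
#' \code{(seed, sample_id)}.
#'
#' @param design A \linkS4class{StudyDesign} whose groups match the truth's
#'   effect columns.
#' @param truth A \linkS4class{MetaboliteTruth}.
#' @param grid Scan spacing in seconds (must be <= 2).
#' @param rt_span Run retention-time span \code{c(min, max)} in seconds;
#'   defaults to 0 .. max library RT + 60. All library RTs must lie inside.
#' @param fwhm Chromatographic peak full width at half maximum in seconds.
#' @param floor Detection floor used to scale blank background (background
#'   intensities are uniform on \code{(0, floor/3)}).
#' @param ppm_tol m/z tolerance used only for the co-elution ambiguity check
#'   (library pairs of equal polarity closer than twice the tolerance at
#'   overlapping RT raise a warning).
#' @param blank_bg_per_scan Background centroids per blank scan and polarity.
#' @return A list with \code{runs} (named list of \linkS4class{MsRun}) and
#'   \code{truth} (data.frame of every sampled apex: \code{name},
#'   \code{sample_id}, \code{group}, \code{donor}, \code{true_height},
#'   \code{apex_rt}, \code{mz_observed}; absent analytes have height 0).
#' @examples
#' d <- StudyDesign(c("vehicle", "WIN"), donors = 2, blanks = 1)
#' sim <- simulateMetabolomeRuns(d, defaultMetaboliteTruth(noise_cv = 0,
#'   rt_jitter_sd = 0, mz_jitter_ppm = 0))
#' sim$runs[[1]]
#' @export
simulateMetabolomeRuns <- function(design, truth = defaultMetaboliteTruth(),
                                   grid = 1, rt_span = NULL, fwhm = 12,
                                   floor = 1e4, ppm_tol = 5,
                                   blank_bg_per_scan = 3) {
  stopifnot(is(design, "StudyDesign"), is(truth, "MetaboliteTruth"))
  validObject(design); validObject(truth)
  if (grid <= 0 || grid > 2)
    stop("'grid' must be a scan spacing in (0, 2] seconds")
  lib <- truth@library
  if (is.null(rt_span)) rt_span <- c(0, max(lib$rt_seconds) + 60)
  if (any(lib$rt_seconds < rt_span[1] | lib$rt_seconds > rt_span[2]))
    stop("all expected retention times must lie inside 'rt_span'")
  if (!all(design@groups %in% colnames(truth@effects)))
    stop("truth effects must cover every design group")
  .warnCoelution(lib, ppm_tol, fwhm)

  sheet <- sampleSheet(design)
  times <- seq(rt_span[1], rt_span[2], by = grid)
  sigma <- fwhm * .FWHM_TO_SD
  # vehicle carries no peak for analytes encoded +Inf in any group
  absent_in_control <- apply(truth@effects, 1, function(e) any(e == Inf))

  runs <- vector("list", nrow(sheet))
  names(runs) <- sheet$sample_id
  truth_rows <- vector("list", nrow(sheet))

  for (i in seq_len(nrow(sheet))) {
    s <- sheet[i, ]
    set.seed(deriveSeed(design@seed, s$sample_id))
    if (s$role == "blank") {
      peaks <- .blankBackground(times, lib, floor, blank_bg_per_scan)
      runs[[i]] <- MsRun(s$sample_id, role = "blank", peaks = peaks)
      next
    }
    eff <- truth@effects[, s$group]
    present <- eff != -Inf
    if (s$group == colnames(truth@effects)[1L])
      present <- present & !absent_in_control
    height <- ifelse(present,
                     truth@baseHeight * 2^ifelse(is.finite(eff), eff, 0) *
                       .rlnormCV(nrow(lib), truth@noiseCv), 0)
    apex <- lib$rt_seconds +
      if (truth@rtJitterSd > 0) stats::rnorm(nrow(lib), 0, truth@rtJitterSd)
      else 0
    mz_obs <- lib$mz *
      (1 + (if (truth@mzJitterPpm > 0)
        stats::rnorm(nrow(lib), 0, truth@mzJitterPpm) else 0) * 1e-6)
    pk <- lapply(which(present), function(j) {
      span <- sigma * sqrt(2 * log(pmax(height[j], 2)))  # down to intensity 1
      tt <- times[abs(times - apex[j]) <= span]
      if (!length(tt)) return(NULL)
      data.frame(rt = tt, polarity = lib$polarity[j], mz = mz_obs[j],
                 intensity = height[j] *
                   exp(-(tt - apex[j])^2 / (2 * sigma^2)))
    })
    pk <- do.call(rbind, pk)
    if (is.null(pk))
      pk <- data.frame(rt = numeric(), polarity = character(),
                       mz = numeric(), intensity = numeric())
    runs[[i]] <- MsRun(s$sample_id, role = "sample", group = s$group,
                       donor = s$donor, peaks = pk)
    truth_rows[[i]] <- data.frame(
      name = lib$name, sample_id = s$sample_id, group = s$group,
      donor = s$donor, true_height = height,
      apex_rt = ifelse(present, apex, NA_real_),
      mz_observed = ifelse(present, mz_obs, NA_real_),
      stringsAsFactors = FALSE)
  }
  truth_tab <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null,
                                                 logical(1))])
  rownames(truth_tab) <- NULL
  list(runs = runs, truth = truth_tab)
}

.blankBackground <- function(times, lib, floor, per_scan) {
  if (per_scan < 1) {
    return(data.frame(rt = numeric(), polarity = character(),
                      mz = numeric(), intensity = numeric()))
  }
  mz_range <- range(lib$mz) + c(-10, 10)
  out <- lapply(c("pos", "neg"), function(pol) {
    n <- length(times) * per_scan
    data.frame(rt = rep(times, each = per_scan), polarity = pol,
               mz = stats::runif(n, mz_range[1], mz_range[2]),
               intensity = stats::runif(n, 0, floor / 3))
  })
  do.call(rbind, out)
}

.warnCoelution <- function(lib, ppm_tol, fwhm) {
  n <- nrow(lib)
  if (n < 2L) return(invisible())
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (lib$polarity[i] != lib$polarity[j]) next
    tol <- 2 * lib$mz[i] * ppm_tol * 1e-6
    if (abs(lib$mz[i] - lib$mz[j]) < 2 * tol &&
        abs(lib$rt_seconds[i] - lib$rt_seconds[j]) < fwhm)
      warning(sprintf("co-elution ambiguity: '%s' and '%s' overlap in m/z and RT",
                      lib$name[i], lib$name[j]), call. = FALSE)
  }
  invisible()
}
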