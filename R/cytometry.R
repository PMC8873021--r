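# DNA-content cell-cycle deconvolution (Dean-Jett-Fox style) and two-channel
# apoptosis / DNA-damage quadrant analytics.

#' Deconvolve a DNA-content histogram into cell-cycle fractions
#'
#' The histogram (default 256 bins over [0, 99.5th percentile x 1.1]) is
#' decomposed Dean-Jett-Fox style: the dominant mode is taken as G1 and a
#' Gaussian is fit locally (apex by parabolic interpolation of log counts,
#' width from the left half-maximum); the G2/M Gaussian is constrained to
#' \code{g2_window} times the G1 mean with proportional width; S phase is a
#' constant density between the peaks convolved with the G1 width. Component
#' amplitudes are estimated by non-negative least squares on the bins at or
#' above the sub-G1 gate (\code{G1 mean - subg1_sd_mult x G1 sd}); the G2/M
#' position is chosen on a grid by residual. The sub-G1 fraction (fragmented
#' DNA, the screen's cell-death proxy) is the fraction of raw events below
#' the gate; all fractions are renormalized over all events. The estimate is
#' invariant to uniform rescaling of the channel.
#'
#' @param events data.frame with column \code{dna}, or a numeric vector;
#'   at least 1000 events.
#' @param bins Number of histogram bins.
#' @param g2_window Allowed G2/M-to-G1 mean ratio window.
#' @param subg1_sd_mult Sub-G1 gate distance below the G1 mean, in G1 SDs.
#' @param residual_threshold Relative residual above which the fit is
#'   flagged low-confidence.
#' @return A \linkS4class{CellCycleFit}.
#' @examples
#' set.seed(1)
#' fit <- fitDnaContent(simulateDnaContent(CytometryTruth()))
#' fractions(fit)
#' @export
fitDnaContent <- function(events, bins = 256, g2_window = c(1.8, 2.2),
                          subg1_sd_mult = 3, residual_threshold = 0.1) {
  x <- if (is.data.frame(events)) events$dna else as.numeric(events)
  if (length(x) < 1000L) stop("at least 1000 events are required for fitting")
  if (any(x <= 0)) stop("DNA-content values must be positive")
  upper <- as.numeric(stats::quantile(x, 0.995)) * 1.1
  edges <- seq(0, upper, length.out = bins + 1L)
  binw <- edges[2L] - edges[1L]
  counts <- tabulate(findInterval(x[x < upper], edges,
                                  rightmost.closed = TRUE), nbins = bins)
  centers <- edges[-1L] - binw / 2
  k <- which.max(counts)
  if (counts[k] == 0L) stop("no resolvable G1 mode in the DNA histogram")
  # apex refinement on log counts (0.5 pseudocount), clamped to the bin
  lc <- log(counts + 0.5)
  delta <- 0
  if (k > 1L && k < bins) {
    den <- lc[k - 1L] - 2 * lc[k] + lc[k + 1L]
    if (den < 0) delta <- max(-0.5, min(0.5,
                                        0.5 * (lc[k - 1L] - lc[k + 1L]) / den))
  }
  mu0 <- centers[k] + delta * binw
  sigma0 <- .leftHalfWidthSd(counts, centers, k, binw)
  gate0 <- mu0 - subg1_sd_mult * sigma0
  if (gate0 <= 0) stop("sub-G1 gate is non-positive; G1 peak too wide")

  # separable least squares: Nelder-Mead over (G1 mean, log G1 sd,
  # logit-mapped G2 ratio); component amplitudes by NNLS at each step.
  solve_at <- function(mu1, sigma1, ratio, fit_bins) {
    mu2 <- ratio * mu1
    sigma2 <- sigma1 * ratio
    A <- cbind(
      g1 = stats::pnorm(edges[fit_bins + 1L], mu1, sigma1) -
        stats::pnorm(edges[fit_bins], mu1, sigma1),
      s = (stats::pnorm(centers[fit_bins], mu1, sigma1) -
             stats::pnorm(centers[fit_bins], mu2, sigma1)) /
        (mu2 - mu1) * binw,
      g2m = stats::pnorm(edges[fit_bins + 1L], mu2, sigma2) -
        stats::pnorm(edges[fit_bins], mu2, sigma2))
    y <- counts[fit_bins]
    sol <- pracma::lsqnonneg(A, y)
    list(mu2 = mu2, sigma2 = sigma2, a = sol$x,
         resid = sqrt(sum((A %*% sol$x - y)^2)) / sqrt(sum(y^2)))
  }
  fit_bins0 <- which(centers >= gate0)
  rwidth <- diff(g2_window)
  # scale-free parametrization: offsets in units of the initial G1 width
  unmap <- function(p) list(
    mu1 = mu0 + p[1L] * sigma0,
    sigma1 = sigma0 * exp(p[2L]),
    ratio = g2_window[1L] + rwidth * stats::plogis(p[3L]))
  opt <- stats::optim(
    c(0, 0, 0),
    function(p) {
      q <- unmap(p)
      if (q$mu1 < mu0 - 3 * sigma0 || q$mu1 > mu0 + 3 * sigma0 ||
          q$sigma1 < binw / 4 || q$sigma1 > 0.25 * mu0) return(1e6)
      solve_at(q$mu1, q$sigma1, q$ratio, fit_bins0)$resid
    },
    method = "Nelder-Mead",
    control = list(maxit = 400, reltol = 1e-8))
  q <- unmap(opt$par)
  mu1 <- q$mu1; sigma1 <- q$sigma1
  gate <- mu1 - subg1_sd_mult * sigma1
  if (gate <= 0) stop("sub-G1 gate is non-positive; G1 peak too wide")
  sub_g1 <- mean(x < gate)
  best <- solve_at(mu1, sigma1, q$ratio, which(centers >= gate))
  a <- best$a
  if (sum(a) <= 0) stop("no resolvable cell-cycle structure above the sub-G1 gate")
  cyc <- (1 - sub_g1) * a / sum(a)
  fr <- c(sub_g1 = sub_g1, g1 = cyc[1L], s = cyc[2L], g2m = cyc[3L])
  names(fr) <- c("sub_g1", "g1", "s", "g2m")
  new("CellCycleFit", fractions = fr, g1Mean = mu1, g1Sd = sigma1,
      g2Mean = best$mu2, g2Sd = best$sigma2, residual = best$resid,
      lowConfidence = best$resid > residual_threshold)
}

# G1 width from the left half-maximum crossing of the histogram, floored at
# half a bin; falls back to the right side when the mode sits at the left
# edge of the histogram.
.leftHalfWidthSd <- function(counts, centers, k, binw) {
  half <- counts[k] / 2
  to_sd <- 1 / sqrt(2 * log(2))
  j <- k
  while (j > 1L && counts[j - 1L] > half) j <- j - 1L
  if (j > 1L) {
    # linear interpolation of the crossing between bins j-1 and j
    frac <- (counts[j] - half) / max(counts[j] - counts[j - 1L], 1)
    xh <- centers[j] - frac * binw
    return(max((centers[k] - xh) * to_sd, binw / 2))
  }
  j <- k
  n <- length(counts)
  while (j < n && counts[j + 1L] > half) j <- j + 1L
  if (j < n) {
    frac <- (counts[j] - half) / max(counts[j] - counts[j + 1L], 1)
    xh <- centers[j] + frac * binw
    return(max((xh - centers[k]) * to_sd, binw / 2))
  }
  binw / 2
}

#' Gating thresholds from an unstained sample
#'
#' Per-channel threshold = the configured upper quantile of the unstained
#' event set (background-free gating: an unstained control defines what
#' "negative" looks like).
#'
#' @param unstained data.frame with columns \code{parp} and \code{h2ax};
#'   at least 1000 events.
#' @param quantile Upper quantile (default 0.999); \code{1} gives the
#'   channel maximum.
#' @return Named numeric thresholds \code{c(parp, h2ax)}.
#' @export
deriveThresholds <- function(unstained, quantile = 0.999) {
  stopifnot(all(c("parp", "h2ax") %in% names(unstained)))
  if (nrow(unstained) < 1000L) stop("at least 1000 unstained events required")
  c(parp = as.numeric(stats::quantile(unstained$parp, quantile)),
    h2ax = as.numeric(stats::quantile(unstained$h2ax, quantile)))
}

#' Quadrant gating of a two-channel event set
#'
#' Each event falls in exactly one quadrant by strict exceedance of each
#' channel threshold.
#'
#' @param events data.frame with columns \code{parp}, \code{h2ax}; non-empty.
#' @param thresholds Named numeric \code{c(parp, h2ax)}, both > 0.
#' @return A \linkS4class{QuadrantResult}.
#' @export
quadrantGate <- function(events, thresholds) {
  stopifnot(all(c("parp", "h2ax") %in% names(events)))
  if (!nrow(events)) stop("empty event set")
  if (any(thresholds[c("parp", "h2ax")] <= 0))
    stop("thresholds must be > 0")
  ph <- events$parp > thresholds[["parp"]]
  hh <- events$h2ax > thresholds[["h2ax"]]
  counts <- c(dn = sum(!ph & !hh), parp_pos = sum(ph & !hh),
              double_pos = sum(ph & hh), h2ax_pos = sum(!ph & hh))
  new("QuadrantResult",
      thresholds = c(parp = thresholds[["parp"]],
                     h2ax = thresholds[["h2ax"]]),
      counts = as.integer(counts) |> stats::setNames(names(counts)),
      percentages = 100 * counts / nrow(events))
}

#' Fold changes of per-sample quadrant percentages versus the control
#'
#' Percentages are computed per sample, averaged within group, and the fold
#' change is the group mean over the control mean. A one-way ANOVA with
#' Dunnett-style post-hoc tests versus the control is run per statistic on
#' the per-sample percentages. A zero control mean yields an undefined
#' (\code{NA}) fold change, flagged.
#'
#' @param pct data.frame with columns \code{sample_id}, \code{group} and one
#'   column per statistic (e.g. \code{parp_pos}, \code{double_pos},
#'   \code{h2ax_pos}).
#' @param control Control group label.
#' @param statistics Character vector of statistic columns; defaults to all
#'   columns except \code{sample_id} and \code{group}.
#' @param alpha Significance level.
#' @param posthoc \code{"dunnett"} or \code{"holm"}.
#' @return Named list per statistic: \code{fold_changes} (data.frame
#'   \code{group}, \code{mean_pct}, \code{fold_change}, \code{defined}),
#'   \code{anova_p}, \code{posthoc} (many-to-one table, \code{NULL} when the
#'   omnibus test is not significant).
#' @export
foldChangeVsControl <- function(pct, control, statistics = NULL,
                                alpha = 0.05,
                                posthoc = c("dunnett", "holm")) {
  posthoc <- match.arg(posthoc)
  if (is.null(statistics))
    statistics <- setdiff(names(pct), c("sample_id", "group"))
  if (!control %in% pct$group) stop("control group not found: ", control)
  g <- stats::relevel(factor(pct$group), ref = control)
  out <- lapply(statistics, function(s) {
    v <- pct[[s]]
    means <- tapply(v, g, mean)
    ctrl_mean <- means[[control]]
    fc <- if (ctrl_mean == 0) rep(NA_real_, length(means)) else
      as.numeric(means) / ctrl_mean
    fold <- data.frame(group = names(means), mean_pct = as.numeric(means),
                       fold_change = fc, defined = ctrl_mean != 0,
                       stringsAsFactors = FALSE, row.names = NULL)
    if (ctrl_mean == 0)
      warning("control mean is 0 for '", s,
              "': fold changes undefined", call. = FALSE)
    p <- .onewayP(v, g)
    ph <- if (!is.na(p) && p < alpha) .manyToOne(v, g, alpha, posthoc)
      else NULL
    list(fold_changes = fold, anova_p = p, posthoc = ph)
  })
  names(out) <- statistics
  out
}
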