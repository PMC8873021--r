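#' MetaboliteTruth: ground-truth parameters for simulated metabolome runs
#'
#' One row of \code{library} per targeted analyte, with a per-group log2
#' effect matrix relative to the base peak height. Effects of \code{+Inf}
#' encode "absent in the vehicle control, present in this group" (the analyte
#' then carries no peak in any vehicle run); \code{-Inf} encodes "absent in
#' this group".
#'
#' @slot library data.frame with columns \code{name}, \code{ion_type},
#'   \code{mz}, \code{polarity}, \code{rt_seconds}.
#' @slot effects Numeric matrix, analytes x groups, log2 effects
#'   (vehicle column all 0 or \code{-Inf}).
#' @slot baseHeight Per-analyte base apex height (arbitrary units, > 0).
#' @slot noiseCv Multiplicative log-normal noise CV in [0, 0.5].
#' @slot rtJitterSd Per-run apex retention-time jitter SD in seconds (>= 0).
#' @slot mzJitterPpm Per-run centroid m/z jitter SD in ppm (>= 0).
#' @export
setClass("MetaboliteTruth",
  slots = c(library = "data.frame", effects = "matrix",
            baseHeight = "numeric", noiseCv = "numeric",
            rtJitterSd = "numeric", mzJitterPpm = "numeric"))

setValidity("MetaboliteTruth", function(object) {
  msg <- character()
  need <- c("name", "ion_type", "mz", "polarity", "rt_seconds")
  if (!all(need %in% names(object@library)))
    msg <- c(msg, sprintf("library needs columns %s",
                          paste(need, collapse = ", ")))
  if (nrow(object@effects) != nrow(object@library))
    msg <- c(msg, "effects must have one row per library analyte")
  if (is.null(colnames(object@effects)))
    msg <- c(msg, "effects columns must be named after groups")
  if (any(object@baseHeight <= 0)) msg <- c(msg, "baseHeight must be > 0")
  if (object@noiseCv < 0 || object@noiseCv > 0.5)
    msg <- c(msg, "noiseCv must lie in [0, 0.5]")
  if (object@rtJitterSd < 0) msg <- c(msg, "rtJitterSd must be >= 0")
  if (object@mzJitterPpm < 0) msg <- c(msg, "mzJitterPpm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname MetaboliteTruth-class
#' @param library,effects,base_height,noise_cv,rt_jitter_sd,mz_jitter_ppm
#'   See slot documentation; \code{base_height} is recycled across analytes.
#' @return A \linkS4class{MetaboliteTruth}.
#' @export
MetaboliteTruth <- function(library, effects, base_height = 5e5,
                            noise_cv = 0.05, rt_jitter_sd = 1,
                            mz_jitter_ppm = 1) {
  new("MetaboliteTruth", library = library,
      effects = as.matrix(effects),
      baseHeight = rep_len(base_height, nrow(library)),
      noiseCv = noise_cv, rtJitterSd = rt_jitter_sd,
      mzJitterPpm = mz_jitter_ppm)
}

setMethod("show", "MetaboliteTruth", function(object) {
  cat(sprintf(
    "MetaboliteTruth: %d analytes x %d groups (cv %.2f, rt sd %.1f s, mz sd %.1f ppm)\n",
    nrow(object@library), ncol(object@effects), object@noiseCv,
    object@rtJitterSd, object@mzJitterPpm))
})

#' CytometryTruth: ground truth for simulated flow-cytometry event sets
#'
#' @slot fractions Named cell-cycle fractions (\code{sub_g1, g1, s, g2m}),
#'   summing to 1.
#' @slot dnaCv Coefficient of variation of the G1 DNA-content peak.
#' @slot nEvents Number of events per simulated sample (>= 1000).
#' @slot quadrantProbs Named quadrant membership probabilities
#'   (\code{dn, parp_pos, double_pos, h2ax_pos}), summing to 1.
#' @export
setClass("CytometryTruth",
  slots = c(fractions = "numeric", dnaCv = "numeric", nEvents = "integer",
            quadrantProbs = "numeric"))

setValidity("CytometryTruth", function(object) {
  msg <- character()
  if (!identical(names(object@fractions), c("sub_g1", "g1", "s", "g2m")))
    msg <- c(msg, "fractions must be named sub_g1, g1, s, g2m")
  else if (abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1")
  if (!identical(names(object@quadrantProbs),
                 c("dn", "parp_pos", "double_pos", "h2ax_pos")))
    msg <- c(msg, "quadrantProbs must be named dn, parp_pos, double_pos, h2ax_pos")
  else if (abs(sum(object@quadrantProbs) - 1) > 1e-9)
    msg <- c(msg, "quadrantProbs must sum to 1")
  if (object@nEvents < 1000L) msg <- c(msg, "nEvents must be >= 1000")
  if (object@dnaCv <= 0) msg <- c(msg, "dnaCv must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname CytometryTruth-class
#' @param fractions,dna_cv,n_events,quadrant_probs See slot documentation.
#' @return A \linkS4class{CytometryTruth}.
#' @export
CytometryTruth <- function(fractions = c(sub_g1 = 0.05, g1 = 0.60,
                                         s = 0.20, g2m = 0.15),
                           dna_cv = 0.05, n_events = 20000,
                           quadrant_probs = c(dn = 0.9742, parp_pos = 0.0118,
                                              double_pos = 0.004,
                                              h2ax_pos = 0.01)) {
  new("CytometryTruth", fractions = fractions, dnaCv = dna_cv,
      nEvents = as.integer(n_events), quadrantProbs = quadrant_probs)
}

setMethod("show", "CytometryTruth", function(object) {
  f <- object@fractions
  cat(sprintf(
    "CytometryTruth: %d events, cv %.2f | sub-G1 %.3f G1 %.3f S %.3f G2/M %.3f\n",
    object@nEvents, object@dnaCv, f[1], f[2], f[3], f[4]))
})
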