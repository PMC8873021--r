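# Synthetic flow-cytometry event sets: one-channel DNA-content clouds with
# sub-G1/G1/S/G2M structure and two-channel apoptosis (cleaved PARP) /
# DNA-damage (phospho-H2AX) clouds with quadrant structure.

#' Simulate a DNA-content event set
#'
#' Events are drawn multinomially across compartments: G1 is Gaussian at
#' \code{g1_mean} with the given CV, G2/M Gaussian at twice the G1 position
#' with the same CV, S uniform between the two peaks convolved with the G1
#' Gaussian width, and sub-G1 (fragmented DNA, a proxy of cell death)
#' uniform on \code{(0.2, 1 - 3 cv) * g1_mean}. All values are strictly
#' positive singlet events.
#'
#' @param truth A \linkS4class{CytometryTruth} (its \code{fractions},
#'   \code{dnaCv} and \code{nEvents} are used).
#' @param g1_mean Position of the G1 peak in channel units (> 0).
#' @param sample_id,group Annotations attached to the result.
#' @return data.frame with column \code{dna} plus attributes
#'   \code{sample_id}, \code{group} and \code{compartments} (the realized
#'   per-compartment counts).
#' @export
simulateDnaContent <- function(truth, g1_mean = 100,
                               sample_id = "s1", group = NA_character_) {
  stopifnot(is(truth, "CytometryTruth"))
  .assertScalar(g1_mean, "g1_mean", positive = TRUE)
  cv <- truth@dnaCv
  if (1 - 3 * cv <= 0.2)
    stop("dnaCv too large: no room for a sub-G1 band below G1 - 3 sd")
  n <- truth@nEvents
  comp <- sample(names(truth@fractions), n, replace = TRUE,
                 prob = truth@fractions)
  x <- numeric(n)
  i <- comp == "g1"
  x[i] <- stats::rnorm(sum(i), g1_mean, cv * g1_mean)
  i <- comp == "g2m"
  x[i] <- stats::rnorm(sum(i), 2 * g1_mean, cv * 2 * g1_mean)
  i <- comp == "s"
  x[i] <- stats::runif(sum(i), g1_mean, 2 * g1_mean) +
    stats::rnorm(sum(i), 0, cv * g1_mean)
  i <- comp == "sub_g1"
  x[i] <- stats::runif(sum(i), 0.2 * g1_mean, (1 - 3 * cv) * g1_mean)
  x <- pmax(x, g1_mean * 1e-3)
  out <- data.frame(dna = x)
  attr(out, "sample_id") <- sample_id
  attr(out, "group") <- group
  attr(out, "compartments") <- table(factor(comp, names(truth@fractions)))
  out
}

# Cluster geometry of the two-channel generator, log10 channel units.
.DMG_NEG_MEAN <- 1.5
.DMG_POS_MEAN <- 2.9
.DMG_SD <- 0.12

#' Simulate a two-channel apoptosis / DNA-damage event set
#'
#' Four bivariate log-normal clusters (double-negative, PARP+ only,
#' double-positive, H2AX+ only) with multinomial membership at the truth's
#' quadrant probabilities. Cluster centers sit more than 3 cluster SDs away
#' from the design gates (100 channel units per channel), so the gating
#' ground truth is unambiguous.
#'
#' @param truth A \linkS4class{CytometryTruth} (its \code{quadrantProbs} are
#'   used).
#' @param n Number of events (>= 1000); defaults to the truth's
#'   \code{nEvents}.
#' @param sample_id,group Annotations attached to the result.
#' @return data.frame with columns \code{parp}, \code{h2ax}; attributes
#'   \code{sample_id}, \code{group}, \code{quadrants} (realized counts) and
#'   \code{design_gates} (the generator's gate coordinates).
#' @export
simulateDamageEvents <- function(truth, n = NULL, sample_id = "s1",
                                 group = NA_character_) {
  stopifnot(is(truth, "CytometryTruth"))
  if (is.null(n)) n <- truth@nEvents
  if (n < 1000) stop("at least 1000 events are required")
  quad <- sample(names(truth@quadrantProbs), n, replace = TRUE,
                 prob = truth@quadrantProbs)
  parp_hot <- quad %in% c("parp_pos", "double_pos")
  h2ax_hot <- quad %in% c("h2ax_pos", "double_pos")
  out <- data.frame(
    parp = 10^stats::rnorm(n, ifelse(parp_hot, .DMG_POS_MEAN, .DMG_NEG_MEAN),
                           .DMG_SD),
    h2ax = 10^stats::rnorm(n, ifelse(h2ax_hot, .DMG_POS_MEAN, .DMG_NEG_MEAN),
                           .DMG_SD))
  attr(out, "sample_id") <- sample_id
  attr(out, "group") <- group
  attr(out, "quadrants") <-
    table(factor(quad, names(truth@quadrantProbs)))
  attr(out, "design_gates") <- c(parp = 100, h2ax = 100)
  out
}

#' Simulate an unstained (all-negative) two-channel event set
#'
#' Both channels draw from the double-negative cluster; used to derive
#' background-free gating thresholds.
#'
#' @param n Number of events (>= 1000).
#' @return data.frame with columns \code{parp}, \code{h2ax}.
#' @export
simulateUnstained <- function(n = 20000) {
  if (n < 1000) stop("at least 1000 events are required")
  data.frame(parp = 10^stats::rnorm(n, .DMG_NEG_MEAN, .DMG_SD),
             h2ax = 10^stats::rnorm(n, .DMG_NEG_MEAN, .DMG_SD))
}
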