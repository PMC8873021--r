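# Default study conditions: the 7-arm enviromimetic screen (vehicle control,
# cannabinoid agonist WIN 55,212-2, IL17a, cortisol, nicotine, ethanol,
# endomorphin), the 18-analyte targeted metabolite panel with its published
# group effects, and the flow-cytometry presets.

.DEFAULT_GROUPS <- c("vehicle", "WIN", "IL17a", "cortisol", "nicotine",
                     "ethanol", "endomorphin")

#' Default treatment groups of the enviromimetic screen
#'
#' Vehicle control first, then the six enviromimetic compounds.
#' @return Character vector of 7 group labels.
#' @export
defaultGroups <- function() .DEFAULT_GROUPS

#' Default targeted metabolite library
#'
#' The 18 polar metabolites of the screen's targeted panel. Theoretical m/z
#' values are computed from molecular formulas as singly protonated or
#' deprotonated ions; retention times are plausible values for a polar
#' (HILIC-style) separation and carry no meaning beyond placing each analyte
#' on the chromatographic axis.
#'
#' @return data.frame with columns \code{name}, \code{formula},
#'   \code{ion_type}, \code{mz}, \code{polarity}, \code{rt_seconds}.
#' @examples
#' head(defaultMetaboliteLibrary())
#' @export
defaultMetaboliteLibrary <- function() {
  lib <- data.frame(
    name = c("3-Phosphoglyceric Acid", "Acetylcysteine", "Allantoin",
             "Creatinine", "D-Ribose 5-Phosphate", "Guanosine Monophosphate",
             "Guanosine Triphosphate", "Inosine", "L-Leucine", "L-Methionine",
             "L-Phenylalanine", "L-Tyrosine", "L-Valine", "N-Acetylglutamine",
             "N-Acetylornithine", "Pyruvic Acid", "S-Adenosylhomocysteine",
             "Succinic Acid"),
    formula = c("C3H7O7P", "C5H9NO3S", "C4H6N4O3", "C4H7N3O", "C5H11O8P",
                "C10H14N5O8P", "C10H16N5O14P3", "C10H12N4O5", "C6H13NO2",
                "C5H11NO2S", "C9H11NO2", "C9H11NO3", "C5H11NO2", "C7H12N2O4",
                "C7H14N2O3", "C3H4O3", "C14H20N6O5S", "C4H6O4"),
    polarity = c("neg", "neg", "neg", "pos", "neg", "neg", "neg", "pos",
                 "pos", "pos", "pos", "pos", "pos", "neg", "pos", "neg",
                 "pos", "neg"),
    rt_seconds = c(420, 250, 180, 120, 440, 400, 470, 210, 140, 160,
                   170, 200, 130, 230, 260, 110, 310, 150),
    stringsAsFactors = FALSE)
  lib$ion_type <- ifelse(lib$polarity == "pos", "[M+H]+", "[M-H]-")
  lib$mz <- vapply(seq_len(nrow(lib)), function(i)
    adductMz(monoisotopicMass(lib$formula[i]), lib$polarity[i]), numeric(1))
  lib[, c("name", "formula", "ion_type", "mz", "polarity", "rt_seconds")]
}

#' Default per-group log2 effects for the metabolite panel
#'
#' Log2 fold changes of each treated group relative to the vehicle control,
#' used as the generator's ground truth. Finite values are the published
#' screen-scale effects (all decreases, magnitudes ~0.1-2.7); guanosine
#' triphosphate is encoded as undetected in the vehicle control (\code{+Inf}:
#' present in the group, absent in vehicle) in all arms except WIN 55,212-2,
#' where it is absent altogether (\code{-Inf}).
#'
#' @return Numeric matrix, 18 analytes x 7 groups (vehicle column zero).
#' @export
defaultMetaboliteEffects <- function() {
  lib <- defaultMetaboliteLibrary()
  eff <- matrix(0, nrow(lib), length(.DEFAULT_GROUPS),
                dimnames = list(lib$name, .DEFAULT_GROUPS))
  set_ <- function(name, group, value) eff[name, group] <<- value
  set_("3-Phosphoglyceric Acid", "IL17a", -2.72)
  set_("3-Phosphoglyceric Acid", "cortisol", -2.23)
  set_("Acetylcysteine", "nicotine", -0.74)
  set_("Allantoin", "IL17a", -0.66)
  set_("Allantoin", "nicotine", -0.65)
  set_("Creatinine", c("IL17a", "cortisol", "nicotine", "ethanol"),
       c(-0.36, -0.22, -0.27, -0.23))
  set_("D-Ribose 5-Phosphate", "nicotine", -1.06)
  set_("Guanosine Monophosphate", "ethanol", -0.61)
  set_("Guanosine Triphosphate", "WIN", -Inf)
  set_("Guanosine Triphosphate",
       c("IL17a", "cortisol", "nicotine", "ethanol", "endomorphin"), Inf)
  set_("Inosine", "ethanol", -1.19)
  set_("L-Leucine", c("IL17a", "cortisol", "nicotine"),
       c(-0.26, -0.17, -0.20))
  set_("L-Methionine",
       c("IL17a", "cortisol", "nicotine", "ethanol", "endomorphin"),
       c(-0.45, -0.39, -0.33, -0.38, -0.27))
  set_("L-Phenylalanine",
       c("WIN", "IL17a", "cortisol", "nicotine", "ethanol", "endomorphin"),
       c(-0.30, -0.32, -0.27, -0.25, -0.26, -0.21))
  set_("L-Tyrosine",
       c("WIN", "IL17a", "cortisol", "nicotine", "ethanol"),
       c(-0.27, -0.30, -0.22, -0.22, -0.19))
  set_("L-Valine", c("WIN", "IL17a", "cortisol", "ethanol"),
       c(-0.31, -0.19, -0.13, -0.15))
  set_("N-Acetylglutamine", "cortisol", -0.85)
  set_("N-Acetylornithine", c("cortisol", "nicotine", "ethanol"),
       c(-0.51, -0.56, -0.47))
  set_("Pyruvic Acid", "IL17a", -1.68)
  set_("S-Adenosylhomocysteine", c("nicotine", "ethanol"), c(-1.39, -1.61))
  set_("Succinic Acid", "ethanol", -0.43)
  eff
}

#' Default metabolome ground truth for the screen
#'
#' @param base_height,noise_cv,rt_jitter_sd,mz_jitter_ppm Generator noise
#'   settings; see \linkS4class{MetaboliteTruth}.
#' @return A \linkS4class{MetaboliteTruth} over the default library, effects
#'   and groups.
#' @export
defaultMetaboliteTruth <- function(base_height = 5e5, noise_cv = 0.05,
                                   rt_jitter_sd = 1, mz_jitter_ppm = 1) {
  MetaboliteTruth(defaultMetaboliteLibrary(), defaultMetaboliteEffects(),
                  base_height = base_height, noise_cv = noise_cv,
                  rt_jitter_sd = rt_jitter_sd, mz_jitter_ppm = mz_jitter_ppm)
}

# Fold changes of quadrant rates relative to the vehicle control, spanning the
# screen's reported ranges (PARP+ 1.71-14.56; double-positive 1.80-11.13, the
# extremes belonging to WIN 55,212-2). Intermediate group values are spread
# across the range; only their order matters for the analytics.
.PARP_FOLDS <- c(vehicle = 1, WIN = 14.56, IL17a = 1.71, cortisol = 2.0,
                 nicotine = 2.5, ethanol = 3.0, endomorphin = 3.5)
.DP_FOLDS <- c(vehicle = 1, WIN = 11.13, IL17a = 1.80, cortisol = 2.1,
               nicotine = 2.6, ethanol = 3.0, endomorphin = 3.4)

#' Flow-cytometry ground-truth preset for a treatment group
#'
#' Control preset: cell-cycle fractions (sub-G1 0.05, G1 0.60, S 0.20,
#' G2/M 0.15), PARP+ rate 1.58\% of cells with 0.4\% double-positive. The
#' WIN 55,212-2 preset multiplies the sub-G1 fraction by 2.29 (the other
#' phases shrink proportionally) and carries the largest quadrant fold
#' changes (14.56 for PARP+, 11.13 for double-positives); the remaining
#' groups carry intermediate fold changes inside the reported ranges.
#'
#' @param group One of \code{defaultGroups()}.
#' @param dna_cv G1 peak coefficient of variation.
#' @param n_events Events per simulated sample.
#' @return A \linkS4class{CytometryTruth}.
#' @examples
#' cytometryPreset("WIN")
#' @export
cytometryPreset <- function(group = "vehicle", dna_cv = 0.05,
                            n_events = 20000) {
  group <- match.arg(group, .DEFAULT_GROUPS)
  frac <- c(sub_g1 = 0.05, g1 = 0.60, s = 0.20, g2m = 0.15)
  if (group == "WIN") {
    sub <- 0.05 * 2.29
    rest <- frac[c("g1", "s", "g2m")] / sum(frac[c("g1", "s", "g2m")])
    frac <- c(sub_g1 = sub, (1 - sub) * rest)
    names(frac) <- c("sub_g1", "g1", "s", "g2m")
  }
  p_parp <- 0.0158 * .PARP_FOLDS[[group]]
  p_dp <- 0.004 * .DP_FOLDS[[group]]
  qp <- c(dn = 1 - (p_parp - p_dp) - p_dp - 0.01,
          parp_pos = p_parp - p_dp, double_pos = p_dp, h2ax_pos = 0.01)
  CytometryTruth(fractions = frac, dna_cv = dna_cv, n_events = n_events,
                 quadrant_probs = qp)
}

#' Default study design of the screen
#'
#' Seven treatment arms with a paired donor set. The metabolome arm of the
#' screen used five donors per group and the proteome arm four; the default
#' follows the requested assay.
#'
#' @param assay \code{"metabolome"} (5 donors), \code{"proteome"} (4) or
#'   \code{"cytometry"} (5).
#' @param blanks Number of blank LC/MS runs.
#' @param seed Master RNG seed.
#' @return A \linkS4class{StudyDesign}.
#' @export
defaultStudyDesign <- function(assay = c("metabolome", "proteome",
                                         "cytometry"),
                               blanks = 3, seed = 1) {
  assay <- match.arg(assay)
  donors <- switch(assay, metabolome = 5, proteome = 4, cytometry = 5)
  StudyDesign(.DEFAULT_GROUPS, donors = donors, blanks = blanks, seed = seed)
}
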