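# Shared fixtures and independent oracles, all built in code.

# A two-treatment design small enough for run-level tests.
smallDesign <- function(seed = 1, donors = 2, blanks = 2) {
  StudyDesign(c("vehicle", "WIN", "IL17a"), donors = donors, blanks = blanks,
              seed = seed)
}

zeroNoiseTruth <- function() {
  defaultMetaboliteTruth(noise_cv = 0, rt_jitter_sd = 0, mz_jitter_ppm = 0)
}

# One-analyte library row for hand-built runs.
phenylalanineEntry <- function() {
  lib <- defaultMetaboliteLibrary()
  lib[lib$name == "L-Phenylalanine", ]
}

# Hand-built run from explicit centroids.
makeRun <- function(sample_id, rt, mz, intensity, polarity = "pos",
                    role = "sample", group = "g", donor = "d") {
  MsRun(sample_id, role = role, group = group, donor = donor,
        peaks = data.frame(rt = rt, polarity = polarity, mz = mz,
                           intensity = intensity))
}

# Random small centroided run around an entry's m/z and RT neighbourhood,
# mixing in-window and out-of-window centroids of both polarities.
randomRun <- function(entry, n = 60) {
  rt <- sort(runif(n, entry$rt_seconds - 40, entry$rt_seconds + 40))
  mz <- entry$mz * (1 + rnorm(n, 0, 8) * 1e-6)      # within ~ +/- 25 ppm
  makeRun(paste0("r", sample.int(1e6, 1)), rt = rt, mz = mz,
          intensity = runif(n, 0, 1e5),
          polarity = sample(c("pos", "neg"), n, replace = TRUE,
                            prob = c(0.8, 0.2)))
}

# Brute-force oracle: maximum intensity over every (scan, centroid) pair
# satisfying the window predicates, ties broken toward earliest RT.
oracleExtract <- function(run, entry, consensus, config) {
  p <- peaksTable(run)
  lo <- entry$mz * (1 - config@ppmTol * 1e-6)
  hi <- entry$mz * (1 + config@ppmTol * 1e-6)
  best <- list(height = 0, rt = NA_real_)
  for (i in seq_len(nrow(p))) {
    if (p$polarity[i] != entry$polarity) next
    if (p$mz[i] < lo || p$mz[i] >= hi) next
    if (abs(p$rt[i] - consensus) > config@apexTol) next
    if (p$intensity[i] <= 0) next
    if (p$intensity[i] > best$height ||
        (p$intensity[i] == best$height && !is.na(best$rt) &&
         p$rt[i] < best$rt)) {
      best <- list(height = p$intensity[i], rt = p$rt[i])
    }
  }
  best
}

# Brute-force oracle: per-event quadrant classification.
oracleQuadrant <- function(events, thr) {
  counts <- c(dn = 0L, parp_pos = 0L, double_pos = 0L, h2ax_pos = 0L)
  for (i in seq_len(nrow(events))) {
    p <- events$parp[i] > thr[["parp"]]
    h <- events$h2ax[i] > thr[["h2ax"]]
    q <- if (p && h) "double_pos" else if (p) "parp_pos" else
      if (h) "h2ax_pos" else "dn"
    counts[q] <- counts[q] + 1L
  }
  counts
}

# Matrix-level MetaboSet with the given group layout; heights are log-normal
# around `base` with per-group multiplicative effects.
syntheticMetaboMatrix <- function(n_analytes, n_per_group,
                                  groups = c("vehicle", "treated"),
                                  effects = NULL, cv = 0.05, base = 5e5,
                                  blanks = 2) {
  sheet <- data.frame(
    sample_id = c(paste0(rep(groups, each = n_per_group), "_",
                         seq_len(n_per_group)),
                  if (blanks > 0) paste0("blank_", seq_len(blanks))),
    group = c(rep(groups, each = n_per_group), rep(NA, blanks)),
    donor = NA_character_,
    role = c(rep("sample", n_per_group * length(groups)),
             rep("blank", blanks)),
    stringsAsFactors = FALSE)
  sdlog <- sqrt(log(1 + cv^2))
  h <- matrix(0, n_analytes, nrow(sheet),
              dimnames = list(sprintf("a%03d", seq_len(n_analytes)),
                              sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    if (sheet$role[j] == "blank") next
    eff <- if (is.null(effects)) rep(0, n_analytes) else
      effects[, sheet$group[j]]
    h[, j] <- base * 2^eff * rlnorm(n_analytes, -sdlog^2 / 2, sdlog)
  }
  MetaboSet(h, sheet)
}

# A corrected (detected + imputed) MetaboSet from the same generator.
correctedMetaboMatrix <- function(...) {
  mset <- syntheticMetaboMatrix(...)
  applyDetection(mset, computeThresholds(mset))
}
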