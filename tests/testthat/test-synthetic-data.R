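# Synthetic-data generators: exactness at zero noise, encoding of
# absent-in-control analytes, per-run RNG stream stability, mzML round trip,
# and the cytometry event generators.

test_that("zero-noise generation reproduces configured effects exactly and is bit-stable", {
  d <- smallDesign(seed = 42)
  sim1 <- simulateMetabolomeRuns(d, zeroNoiseTruth())
  sim2 <- simulateMetabolomeRuns(d, zeroNoiseTruth())
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(peaksTable(sim1$runs[["WIN_D1"]]),
                   peaksTable(sim2$runs[["WIN_D1"]]))

  eff <- defaultMetaboliteEffects()
  tt <- sim1$truth
  phe_win <- tt[tt$name == "L-Phenylalanine" & tt$group == "WIN", ]
  expect_equal(phe_win$true_height, rep(5e5 * 2^-0.30, nrow(phe_win)))
  phe_veh <- tt[tt$name == "L-Phenylalanine" & tt$group == "vehicle", ]
  expect_equal(phe_veh$true_height, rep(5e5, nrow(phe_veh)))
})

test_that("adding samples never perturbs existing runs (per-run RNG streams)", {
  t3 <- defaultMetaboliteTruth()
  small <- simulateMetabolomeRuns(StudyDesign(c("vehicle", "WIN"),
                                              donors = 2, seed = 9), t3)
  big <- simulateMetabolomeRuns(StudyDesign(c("vehicle", "WIN", "ethanol"),
                                            donors = 3, seed = 9), t3)
  expect_identical(peaksTable(small$runs[["WIN_D2"]]),
                   peaksTable(big$runs[["WIN_D2"]]))
})

test_that("infinite effects encode vehicle- and group-absence", {
  sim <- simulateMetabolomeRuns(smallDesign(seed = 5), zeroNoiseTruth())
  gtp <- sim$truth[sim$truth$name == "Guanosine Triphosphate", ]
  expect_true(all(gtp$true_height[gtp$group == "vehicle"] == 0))
  expect_true(all(gtp$true_height[gtp$group == "WIN"] == 0))      # -Inf arm
  expect_true(all(gtp$true_height[gtp$group == "IL17a"] == 5e5))  # +Inf arm
})

test_that("blank runs carry only sub-floor background", {
  sim <- simulateMetabolomeRuns(smallDesign(seed = 2),
                                defaultMetaboliteTruth(), floor = 1e4)
  bl <- peaksTable(sim$runs[["blank_1"]])
  expect_gt(nrow(bl), 0)
  expect_true(all(bl$intensity < 1e4 / 3))
})

test_that("invalid designs and overlapping libraries are rejected/flagged", {
  expect_error(StudyDesign("vehicle", donors = 4), "2 groups")
  expect_error(StudyDesign(c("vehicle", "vehicle", "WIN"), donors = 4),
               "unique")
  expect_error(StudyDesign(c("vehicle", "WIN"), donors = 1), "2 donors")

  lib <- defaultMetaboliteLibrary()[1:2, ]
  lib$mz[2] <- lib$mz[1] * (1 + 4e-6)   # within 2x the 5 ppm tolerance
  lib$polarity[2] <- lib$polarity[1]
  lib$rt_seconds[2] <- lib$rt_seconds[1]
  tr <- MetaboliteTruth(lib, matrix(0, 2, 2,
                                    dimnames = list(lib$name,
                                                    c("vehicle", "WIN"))))
  expect_warning(
    simulateMetabolomeRuns(StudyDesign(c("vehicle", "WIN"), donors = 2,
                                       blanks = 1), tr),
    "co-elution")
})

test_that("written mzML round-trips through the package reader", {
  d <- StudyDesign(c("vehicle", "WIN"), donors = 2, blanks = 1, seed = 3)
  sim <- simulateMetabolomeRuns(d, defaultMetaboliteTruth())
  dir <- withr::local_tempdir()
  writeRunSet(sim$runs, dir)
  back <- readRunSet(dir)
  expect_setequal(names(back), names(sim$runs))
  for (id in names(sim$runs)) {
    a <- peaksTable(sim$runs[[id]]); b <- peaksTable(back[[id]])
    expect_equal(nrow(a), nrow(b))
    expect_lt(max(abs(b$mz - a$mz) / a$mz), 1e-6)
    expect_lt(max(abs(b$intensity - a$intensity) /
                    pmax(a$intensity, 1e-9)), 1e-6)
    expect_equal(b$rt, a$rt, tolerance = 1e-9)
    expect_identical(b$polarity, a$polarity)
  }
  expect_identical(back[["blank_1"]]@role, "blank")
})

test_that("protein generator honours missingness, effects and noise scale", {
  d <- defaultStudyDesign("proteome", seed = 4)
  full <- simulateProteinMatrix(d, n_proteins = 300, n_affected = 20,
                                missing_rate = 0)
  m <- SummarizedExperiment::assay(full$matrix, "intensity")
  expect_false(anyNA(m))
  expect_equal(nrow(suppressMessages(completeCaseFilter(full$matrix))), 300)
  expect_equal(nrow(full$truth), 20)
  expect_true(all(full$truth$sign == sign(full$truth$effect)))

  miss <- simulateProteinMatrix(d, n_proteins = 500, n_affected = 0,
                                missing_rate = 0.1)
  mm <- SummarizedExperiment::assay(miss$matrix, "intensity")
  expect_gt(mean(is.na(mm)), 0.08); expect_lt(mean(is.na(mm)), 0.12)

  # cv 5 %, no donor structure -> per-group CV estimates center on 5 %
  pure <- simulateProteinMatrix(d, n_proteins = 400, n_affected = 0,
                                noise_cv = 0.05, donor_sd = 0,
                                missing_rate = 0)
  qc <- qcReport(pure$matrix)
  expect_true(all(abs(qc$cv_group_median - 0.05) < 0.01))

  expect_error(simulateProteinMatrix(d, n_proteins = 10, n_affected = 11),
               "n_affected")
  expect_error(simulateProteinMatrix(d, missing_rate = 0.6), "missing_rate")
})

test_that("DNA-content generator produces the configured structure", {
  tr <- CytometryTruth(fractions = c(sub_g1 = 0, g1 = 1, s = 0, g2m = 0),
                       dna_cv = 0.01, n_events = 2000)
  set.seed(1)
  ev <- simulateDnaContent(tr, g1_mean = 100)
  expect_true(all(abs(ev$dna - 100) < 100 * 0.01 * 5))

  expect_error(
    simulateDnaContent(CytometryTruth(dna_cv = 0.3), g1_mean = 100),
    "sub-G1")

  # multinomial fractions average to truth within 3 standard errors
  tr2 <- CytometryTruth(n_events = 5000)
  counts <- matrix(0, 30, 4)
  for (s in 1:30) {
    set.seed(s)
    counts[s, ] <- as.numeric(
      attr(simulateDnaContent(tr2, 100), "compartments"))
  }
  avg <- colMeans(counts) / 5000
  se3 <- 3 * sqrt(tr2@fractions * (1 - tr2@fractions) / (5000 * 30))
  expect_true(all(abs(avg - tr2@fractions) <= se3))
})

test_that("damage-event generator separates clusters from its design gates", {
  tr <- CytometryTruth(quadrant_probs = c(dn = 1, parp_pos = 0,
                                          double_pos = 0, h2ax_pos = 0))
  set.seed(2)
  ev <- simulateDamageEvents(tr, n = 2000)
  q <- quadrantGate(ev, attr(ev, "design_gates"))
  expect_equal(unname(quadrantCounts(q)[["dn"]]), 2000)
  expect_error(simulateDamageEvents(tr, n = 500), "1000")
})
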