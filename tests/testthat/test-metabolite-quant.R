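# Targeted extraction: window arithmetic, consensus localization, peak
# height extraction (with a brute-force oracle), matrix assembly, and the
# synthetic round trip.

test_that("mzWindow implements the half-open ppm window", {
  expect_equal(mzWindow(500, 5), c(500 * (1 - 5e-6), 500 * (1 + 5e-6)))
  expect_equal(mzWindow(500, 5), c(499.9975, 500.0025))
  # half-width of the 5 ppm window at m/z 180.0634
  w <- mzWindow(180.0634, 5)
  expect_equal((w[2] - w[1]) / 2, 180.0634 * 5e-6)
  expect_equal((w[2] - w[1]) / 2, 9.00317e-4, tolerance = 1e-6)
  # window shrinks to the point as ppm -> 0
  w0 <- mzWindow(100, 1e-9)
  expect_equal(w0[1], 100, tolerance = 1e-12)
  expect_equal(w0[2], 100, tolerance = 1e-12)
  expect_error(mzWindow(-1, 5), "> 0")
  expect_error(mzWindow(100, 0), "> 0")
})

test_that("consensusApex takes the median apex over runs with signal", {
  entry <- phenylalanineEntry()
  entry$rt_seconds <- 300
  runs <- lapply(c(298, 300, 304), function(rt)
    makeRun(paste0("s", rt), rt = rt, mz = entry$mz, intensity = 1e5))
  expect_equal(consensusApex(runs, entry), 300)

  at_expected <- lapply(1:3, function(i)
    makeRun(paste0("e", i), rt = entry$rt_seconds, mz = entry$mz,
            intensity = 1e5))
  expect_equal(consensusApex(at_expected, entry), entry$rt_seconds)

  empty <- list(makeRun("none", rt = entry$rt_seconds,
                        mz = entry$mz * 1.01, intensity = 1e5))
  expect_null(consensusApex(empty, entry))

  blankonly <- list(makeRun("b", rt = 1, mz = entry$mz, intensity = 1,
                            role = "blank"))
  expect_error(consensusApex(blankonly, entry), "non-blank")
})

test_that("extractPeak matches its stated point examples", {
  entry <- phenylalanineEntry()
  cfg <- ExtractionConfig()
  run <- makeRun("s1", rt = 300, mz = 180.0634, intensity = 5e4)
  entry$rt_seconds <- 300
  entry$mz <- 180.0634
  m <- extractPeak(run, entry, consensus = 300, config = cfg)
  expect_equal(m$height, 5e4)
  expect_true(m$found)
  expect_equal(m$apex_rt, 300)

  off <- makeRun("s2", rt = 300, mz = 180.0634 * (1 + 10e-6),
                 intensity = 5e4)
  m2 <- extractPeak(off, entry, consensus = 300, config = cfg)
  expect_equal(m2$height, 0)
  expect_false(m2$found)

  nothing <- makeRun("s3", rt = 100, mz = 500, intensity = 1e4)
  m3 <- extractPeak(nothing, entry, consensus = 300, config = cfg)
  expect_equal(m3$height, 0)
  expect_false(m3$found)

  negrun <- makeRun("s4", rt = 300, mz = 180.0634, intensity = 5e4,
                    polarity = "neg")
  expect_error(extractPeak(negrun, entry, 300, cfg), "polarity mismatch")
  expect_error(extractPeak(run, entry, consensus = 400, config = cfg),
               "search window")
})

test_that("extractPeak equals the exhaustive-scan oracle on random runs", {
  entry <- phenylalanineEntry()
  cfg <- ExtractionConfig()
  set.seed(101)
  for (i in 1:40) {
    run <- randomRun(entry)
    cons <- entry$rt_seconds + runif(1, -20, 20)
    got <- extractPeak(run, entry, cons, cfg)
    want <- oracleExtract(run, entry, cons, cfg)
    expect_identical(got$height, want$height)
    if (want$height > 0) expect_identical(got$apex_rt, want$rt)
  }
})

test_that("enlarging tolerances never decreases the extracted height", {
  entry <- phenylalanineEntry()
  set.seed(77)
  for (i in 1:20) {
    run <- randomRun(entry)
    cons <- entry$rt_seconds
    h <- vapply(c(2, 5, 10, 20), function(ppm)
      extractPeak(run, entry, cons,
                  ExtractionConfig(ppm_tol = ppm))$height, numeric(1))
    expect_true(all(diff(h) >= 0))
    h2 <- vapply(c(2, 7.5, 15, 30), function(tol)
      extractPeak(run, entry, cons,
                  ExtractionConfig(apex_tol = tol,
                                   search_window = 30))$height, numeric(1))
    expect_true(all(diff(h2) >= 0))
  }
})

test_that("buildIntensityMatrix composes extractPeak and flags blanks", {
  lib <- defaultMetaboliteLibrary()[c(11, 12), ]   # Phe, Tyr (both pos)
  cfg <- ExtractionConfig()
  runs <- list(
    makeRun("s1", rt = c(lib$rt_seconds[1], lib$rt_seconds[2]),
            mz = lib$mz, intensity = c(2e5, 3e5)),
    makeRun("s2", rt = c(lib$rt_seconds[1], lib$rt_seconds[2]),
            mz = lib$mz, intensity = c(4e5, 5e5)),
    makeRun("b1", rt = 100, mz = 400, intensity = 10, role = "blank"))
  mset <- buildIntensityMatrix(runs, lib, cfg)
  expect_s4_class(mset, "MetaboSet")
  expect_equal(dim(mset), c(2L, 3L))
  h <- SummarizedExperiment::assay(mset, "height")
  for (i in 1:2) {
    cons <- consensusApex(runs, lib[i, ], cfg)
    for (j in 1:3)
      expect_equal(h[i, j], extractPeak(runs[[j]], lib[i, ], cons,
                                        cfg)$height)
  }
  expect_identical(SummarizedExperiment::colData(mset)$role,
                   c("s1" = "sample", "s2" = "sample", "b1" = "blank") |>
                     unname())

  # empty library -> empty matrix, no error
  empty <- buildIntensityMatrix(runs, lib[0, ], cfg)
  expect_equal(nrow(empty), 0L)

  # blank-only input: columns flagged, nothing extracted
  bl <- buildIntensityMatrix(runs[3], lib, cfg)
  expect_true(all(SummarizedExperiment::colData(bl)$role == "blank"))
  expect_true(all(SummarizedExperiment::assay(bl, "height") == 0))

  runs_dup <- runs
  runs_dup[[2]] <- makeRun("s1", rt = 1, mz = 100, intensity = 1)
  expect_error(buildIntensityMatrix(runs_dup, lib, cfg), "duplicate")
})

test_that("synthetic round trip: zero jitter exact, default jitter < 1 % error", {
  d <- smallDesign(seed = 12)
  sim0 <- simulateMetabolomeRuns(d, zeroNoiseTruth())
  mset0 <- buildIntensityMatrix(sim0$runs, defaultMetaboliteLibrary())
  h0 <- SummarizedExperiment::assay(mset0, "height")
  tt0 <- sim0$truth
  for (i in seq_len(nrow(tt0)))
    expect_identical(h0[tt0$name[i], tt0$sample_id[i]], tt0$true_height[i])

  simj <- simulateMetabolomeRuns(d, defaultMetaboliteTruth())
  msetj <- buildIntensityMatrix(simj$runs, defaultMetaboliteLibrary())
  hj <- SummarizedExperiment::assay(msetj, "height")
  ttj <- simj$truth
  ttj <- ttj[ttj$true_height > 0, ]
  rel <- vapply(seq_len(nrow(ttj)), function(i)
    abs(hj[ttj$name[i], ttj$sample_id[i]] - ttj$true_height[i]) /
      ttj$true_height[i], numeric(1))
  expect_gte(mean(rel < 0.01), 0.99)
})
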