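# Quantile normalization, complete-case filtering, QC, omnibus + post-hoc
# testing and the pairwise group-versus-control analysis.

psetFrom <- function(m, groups, donors = NULL) {
  if (is.null(colnames(m)))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m)))
    rownames(m) <- paste0("p", seq_len(nrow(m)))
  if (is.null(donors)) donors <- paste0("d", seq_len(ncol(m)))
  ProteomeSet(m, group = groups, donor = donors)
}

test_that("quantile normalization matches the 2x2 worked example and its invariants", {
  expect_equal(quantileNormalizeColumns(matrix(c(1, 3, 4, 2), 2)),
               matrix(c(1.5, 3.5, 3.5, 1.5), 2))

  set.seed(8)
  m <- matrix(rlnorm(600, 10, 1), 100, 6)
  q <- quantileNormalizeColumns(m)
  sorted <- apply(q, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) <= 1e-9))
  # idempotence
  expect_equal(quantileNormalizeColumns(q), q, tolerance = 1e-12)
  # identical columns unchanged
  same <- matrix(rep(sort(rnorm(50)), 3), 50, 3)
  expect_equal(quantileNormalizeColumns(same), same)

  p <- psetFrom(2^m, rep(c("a", "b", "c"), each = 2))
  p <- log2QuantileNormalize(p)
  expect_true("norm" %in% SummarizedExperiment::assayNames(p))
  badm <- 2^m
  badm[1, 1] <- NA
  expect_error(log2QuantileNormalize(psetFrom(badm, rep("a", 6))),
               "missing")
})

test_that("complete-case filter keeps exactly the fully observed proteins", {
  set.seed(2)
  m <- matrix(rlnorm(60, 12, 0.5), 10, 6)
  m[1, 2] <- NA; m[4, c(1, 5)] <- NA; m[9, 6] <- NA
  p <- psetFrom(m, rep(c("a", "b"), each = 3))
  expect_message(f <- completeCaseFilter(p), "7 of 10")
  expect_equal(nrow(f), 7)
  expect_false(any(rownames(f) %in% c("p1", "p4", "p9")))

  all_na <- m; all_na[] <- NA
  expect_error(completeCaseFilter(psetFrom(all_na, rep("a", 6))),
               "nothing to analyze")
})

test_that("QC report: unit diagonal, r2 = 1 for duplicated samples, CV of constants is 0", {
  set.seed(5)
  m <- matrix(rlnorm(200, 12, 0.6), 50, 4)
  m[, 2] <- m[, 1]                      # duplicated sample
  m[7, ] <- 1e5                         # constant protein
  p <- psetFrom(m, c("a", "a", "b", "b"))
  qc <- qcReport(p)
  expect_equal(unname(diag(qc$r2)), rep(1, 4))
  expect_equal(qc$r2[1, 2], 1)
  expect_equal(unname(qc$cv["p7", ]), c(0, 0))
  expect_true(all(qc$cv >= 0, na.rm = TRUE))
})

test_that("omnibus ANOVA matches the closed-form two-group example", {
  m <- matrix(2^c(1, 2, 3, 4, 5, 6), 1)   # log2 values 1..6
  p <- psetFrom(m, rep(c("vehicle", "t"), each = 3))
  res <- anovaPosthoc(p, control = "vehicle")
  # closed form: SSB = 13.5, SSW = 4, F = 13.5 / (4/4), df (1, 4)
  expect_equal(res$omnibus$p_omnibus,
               pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$omnibus$p_omnibus, 0.0214, tolerance = 1e-2)
  expect_equal(res$posthoc$differential, TRUE)
  expect_equal(res$posthoc$direction, 1L)

  flat <- psetFrom(matrix(2^5, 1, 6), rep(c("vehicle", "t"), each = 3))
  rflat <- anovaPosthoc(flat, control = "vehicle")
  expect_equal(rflat$omnibus$p_omnibus, 1)
  expect_equal(nrow(rflat$posthoc), 0)
})

test_that("directions are only reported for significant post-hoc contrasts", {
  set.seed(31)
  groups <- rep(c("vehicle", "a", "b"), each = 4)
  m <- 2^matrix(rnorm(4 * 12, 15, 0.05), 4, 12)
  m[1, groups == "a"] <- m[1, groups == "a"] * 2^1.5  # strong shift in a only
  res <- anovaPosthoc(psetFrom(m, groups), control = "vehicle")
  ph <- res$posthoc[res$posthoc$protein == "p1", ]
  expect_true(ph$differential[ph$group == "a"])
  expect_identical(ph$direction[ph$group == "a"], 1L)
  expect_true(all(is.na(ph$direction[!ph$differential])))

  res_holm <- anovaPosthoc(psetFrom(m, groups), control = "vehicle",
                           posthoc = "holm")
  ph2 <- res_holm$posthoc[res_holm$posthoc$protein == "p1", ]
  expect_true(ph2$differential[ph2$group == "a"])
})

test_that("pairwise vs control: boundary and spiked-recovery behaviour", {
  same <- psetFrom(matrix(2^10, 3, 8), rep(c("vehicle", "g"), each = 4))
  r <- pairwiseVsControl(same, "g")
  expect_equal(r$p_value, rep(1, 3))
  expect_false(any(r$called))

  set.seed(9)
  sdlog2 <- sqrt(log(1 + 0.05^2)) / log(2)
  m <- 2^matrix(rnorm(50 * 8, 18, sdlog2), 50, 8)
  spiked <- 1:25
  m[spiked, 5:8] <- m[spiked, 5:8] * 2   # +1 log2 shift, cv 5 %, n = 4
  rs <- pairwiseVsControl(psetFrom(m, rep(c("vehicle", "g"), each = 4)), "g")
  expect_true(all(rs$called[spiked]))
  expect_true(all(rs$log2diff[spiked] > 0))
})

test_that("pairwise coincides with the metabolome differential on shared data", {
  set.seed(21)
  vals <- matrix(rnorm(40 * 8, 16, 0.3), 40, 8,
                 dimnames = list(sprintf("f%02d", 1:40), paste0("s", 1:8)))
  groups <- rep(c("vehicle", "g"), each = 4)
  pw <- pairwiseVsControl(psetFrom(2^vals, groups), "g")
  # same numbers through the metabolome route, without imputation
  sheet <- data.frame(sample_id = colnames(vals), group = groups,
                      donor = NA, role = "sample")
  mset <- MetaboSet(vals, sheet)
  SummarizedExperiment::assay(mset, "detected") <- vals > -Inf
  SummarizedExperiment::assay(mset, "imputed") <- vals
  dm <- differentialAbundance(mset, "g", "vehicle")
  expect_equal(pw$p_value, dm$p_value)
  expect_identical(pw$called, dm$significant)
  clear <- abs(pw$log2diff) > 0.1
  expect_equal(sign(pw$log2diff[clear]), sign(dm$log2fc[clear]))
})
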