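# Blank thresholds, detection/imputation, differential statistics with the
# infinite fold-change convention, clustering order and the volcano table.

mkSheet <- function(n_samp, n_blank, groups) {
  data.frame(
    sample_id = c(paste0("s", seq_len(n_samp)),
                  if (n_blank) paste0("b", seq_len(n_blank))),
    group = c(groups, rep(NA, n_blank)), donor = NA,
    role = c(rep("sample", n_samp), rep("blank", n_blank)))
}

# Corrected MetaboSet from explicit heights (floor-only thresholds).
correctedFrom <- function(h, groups) {
  mset <- MetaboSet(h, mkSheet(ncol(h), 0, groups))
  hh <- SummarizedExperiment::assay(mset, "height")
  SummarizedExperiment::assay(mset, "detected") <- hh >= 1e4
  SummarizedExperiment::assay(mset, "imputed") <- pmax(hh, 1e4)
  mset
}

test_that("thresholds are max(sn x blank mean, floor)", {
  h <- rbind(a = c(5e5, 5e5, 1000, 1000),
             b = c(5e5, 5e5, 20000, 20000),
             c = c(5e5, 5e5, 0, 0))
  mset <- MetaboSet(h, mkSheet(2, 2, c("vehicle", "g")))
  thr <- thresholds(computeThresholds(mset))
  expect_equal(unname(thr), c(10000, 60000, 10000))

  expect_equal(
    unname(thresholds(computeThresholds(mset, blank_stat = "max"))["b"]),
    60000)

  nob <- MetaboSet(h[, 1:2], mkSheet(2, 0, c("vehicle", "g")))
  expect_error(computeThresholds(nob), "blank")
})

test_that("detection is inclusive at the threshold and imputes it", {
  h <- rbind(a = c(9000, 10000, 10001, 0))
  mset <- MetaboSet(h, mkSheet(3, 1, rep("g", 3)))
  mset <- applyDetection(mset, computeThresholds(mset))
  det <- SummarizedExperiment::assay(mset, "detected")
  imp <- SummarizedExperiment::assay(mset, "imputed")
  expect_identical(unname(det[1, 1:3]), c(FALSE, TRUE, TRUE))
  expect_equal(unname(imp[1, ]), c(10000, 10000, 10001, 10000))

  # fully detected matrix -> identity transform (clean blanks)
  h2 <- cbind(matrix(2e5, 2, 3), 0)
  rownames(h2) <- c("a", "b")
  m2 <- MetaboSet(h2, mkSheet(3, 1, rep("g", 3)))
  m2 <- applyDetection(m2, computeThresholds(m2))
  expect_equal(SummarizedExperiment::assay(m2, "imputed")[, 1:3],
               SummarizedExperiment::assay(m2, "height")[, 1:3])
  expect_true(all(SummarizedExperiment::assay(m2, "detected")[, 1:3]))

  expect_error(applyDetection(m2, new("DetectionThresholds",
                                      threshold = c(x = 1e4),
                                      snMultiple = 3, floor = 1e4)),
               "cover")
})

test_that("raising blank heights never increases detections", {
  set.seed(3)
  mset <- syntheticMetaboMatrix(50, 4, cv = 0.3, base = 3e4)
  h <- SummarizedExperiment::assay(mset, "height")
  n_det <- function(scale) {
    hh <- h
    hh[, grepl("blank", colnames(hh))] <- scale * 2e4
    m <- MetaboSet(hh, as.data.frame(SummarizedExperiment::colData(mset)))
    sum(SummarizedExperiment::assay(
      applyDetection(m, computeThresholds(m)), "detected"))
  }
  dets <- vapply(c(0, 0.5, 1, 2, 4), n_det, numeric(1))
  expect_true(all(diff(dets) <= 0))
})

test_that("differential matches a hand-computed pooled t-test", {
  h <- rbind(a = 1e4 * c(10, 12, 11, 13, 20, 22, 21, 23))
  mset <- correctedFrom(h, rep(c("vehicle", "g"), each = 4))
  res <- differentialAbundance(mset, "g", "vehicle")
  # oracle: pooled-variance two-sample t with df = 6
  x <- c(10, 12, 11, 13); y <- c(20, 22, 21, 23)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  tstat <- (mean(y) - mean(x)) / (sp * sqrt(1 / 2))
  p_oracle <- 2 * pt(-abs(tstat), df = 6)
  expect_equal(res$log2fc, log2(21.5 / 11.5))
  expect_equal(res$log2fc, 0.9027, tolerance = 1e-4)
  expect_equal(res$p_value, p_oracle)
  expect_lt(res$p_value, 1e-4)
  expect_true(res$significant)
  expect_identical(res$inf_reason, "none")
})

test_that("identical arms give log2fc 0 and p 1; tiny arms warn", {
  h <- rbind(a = rep(2e5, 8))
  mset <- correctedFrom(h, rep(c("vehicle", "g"), each = 4))
  res <- differentialAbundance(mset, "g", "vehicle")
  expect_equal(res$log2fc, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  h1 <- rbind(a = c(2e5, 2e5, 3e5))
  m1 <- correctedFrom(h1, c("vehicle", "vehicle", "g"))
  expect_warning(r1 <- differentialAbundance(m1, "g", "vehicle"), "fewer")
  expect_true(is.na(r1$p_value))
  expect_false(r1$significant)
})

test_that("all-undetected control triggers the Inf convention", {
  # control below threshold everywhere, treated detected: the GTP pattern
  h <- rbind(gtp = c(0, 0, 0, 0, 5e5, 5.2e5, 4.9e5, 5.1e5))
  mset <- correctedFrom(h, rep(c("vehicle", "g"), each = 4))
  res <- differentialAbundance(mset, "g", "vehicle")
  expect_identical(res$log2fc, Inf)
  expect_identical(res$inf_reason, "control_undetected")
  expect_lt(res$p_value, 0.05)   # t-test on imputed values still reported

  rev <- differentialAbundance(
    correctedFrom(h[, c(5:8, 1:4), drop = FALSE],
                  rep(c("vehicle", "g"), each = 4)), "g", "vehicle")
  expect_identical(rev$log2fc, -Inf)
  expect_identical(rev$inf_reason, "group_undetected")
})

test_that("imputation floors bound finite fold changes from below-threshold arms", {
  # control undetected in 3 of 4 samples: Inf rule must NOT fire, and the
  # finite estimate cannot exceed log2(max observed / threshold)
  h <- rbind(a = c(0, 0, 0, 1.2e4, 8e5, 8e5, 8e5, 8e5))
  mset <- correctedFrom(h, rep(c("vehicle", "g"), each = 4))
  res <- differentialAbundance(mset, "g", "vehicle")
  expect_true(is.finite(res$log2fc))
  expect_lte(res$log2fc, log2(max(h) / 1e4))
})

test_that("cluster order is deterministic and groups duplicates", {
  m <- cbind(s1 = c(0, 5, 100), s2 = c(0.4, 5.4, 100.4),
             s3 = c(50, 55, 150))
  rownames(m) <- c("r1", "r2", "r3")
  ord <- clusterOrder(m)
  # 1-D toy {0, 1, 10}: the two near rows merge before the far one joins
  pos <- match(c("r1", "r2"), ord$rows)
  expect_equal(abs(diff(pos)), 1)
  cpos <- match(c("s1", "s2"), ord$cols)
  expect_equal(abs(diff(cpos)), 1)
  expect_identical(clusterOrder(m), ord)

  dup <- cbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  rownames(dup) <- c("x", "y")
  odup <- clusterOrder(dup)
  expect_equal(abs(diff(match(c("a", "b"), odup$cols))), 1)

  cm <- matrix(1, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  expect_warning(oc <- clusterOrder(cm), "constant")
  expect_identical(oc$rows, letters[1:3])
  expect_error(clusterOrder(m[1, , drop = FALSE]), "at least 2")
})

test_that("volcano table sorts by p and flags infinite rows at a sentinel", {
  res <- data.frame(
    analyte = c("a", "b", "c"), group = "g",
    log2fc = c(0.5, Inf, -0.2), p_value = c(0.05, 0.01, 1),
    significant = c(FALSE, TRUE, FALSE),
    inf_reason = c("none", "control_undetected", "none"))
  v <- volcanoTable(res)
  expect_identical(v$analyte, c("b", "a", "c"))
  expect_equal(v$neg_log10_p[v$analyte == "c"], 0)
  expect_false(v$significant[v$analyte == "a"])  # p = 0.05 is not < 0.05
  expect_true(v$is_infinite[v$analyte == "b"])
  expect_equal(v$log2fc_plot[v$analyte == "b"], 1.5)  # max |finite| + 1
  expect_error(volcanoTable(res[0, ]), "empty")
})
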