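# Blank-based detection, threshold imputation and group-versus-vehicle
# differential statistics on the metabolite intensity matrix.

#' Per-analyte blank-based detection thresholds
#'
#' \code{threshold = max(sn_multiple * blank_statistic, floor)} per analyte,
#' the blank statistic being the mean (default) or maximum of the analyte's
#' blank-run heights.
#'
#' @param mset A \linkS4class{MetaboSet} with at least one blank column.
#' @param sn_multiple Signal-to-noise multiple (default 3).
#' @param floor Absolute detection floor in arbitrary units (default 10000).
#' @param blank_stat \code{"mean"} or \code{"max"}.
#' @return A \linkS4class{DetectionThresholds}.
#' @examples
#' # blank mean 20000 -> threshold 60000; blank mean 1000 -> the floor binds
#' @export
computeThresholds <- function(mset, sn_multiple = 3, floor = 1e4,
                              blank_stat = c("mean", "max")) {
  stopifnot(is(mset, "MetaboSet"))
  blank_stat <- match.arg(blank_stat)
  role <- SummarizedExperiment::colData(mset)$role
  if (!any(role == "blank"))
    stop("at least one blank column is required to compute thresholds")
  b <- SummarizedExperiment::assay(mset, "height")[, role == "blank",
                                                  drop = FALSE]
  stat <- apply(b, 1L, if (blank_stat == "mean") mean else max)
  thr <- pmax(sn_multiple * stat, floor)
  names(thr) <- rownames(mset)
  new("DetectionThresholds", threshold = thr, snMultiple = sn_multiple,
      floor = floor)
}

#' Apply detection thresholds and impute non-detections
#'
#' A cell is detected iff its height is at or above the analyte threshold
#' (inclusive boundary). Non-detected cells are imputed with the threshold
#' value so fold changes remain estimable; the detection mask is kept in
#' assay \code{"detected"}.
#'
#' @param mset A \linkS4class{MetaboSet}.
#' @param thr A \linkS4class{DetectionThresholds} covering every analyte.
#' @return The \linkS4class{MetaboSet} with added assays \code{"detected"}
#'   and \code{"imputed"} and the thresholds in
#'   \code{metadata(x)$thresholds}.
#' @export
applyDetection <- function(mset, thr) {
  stopifnot(is(mset, "MetaboSet"), is(thr, "DetectionThresholds"))
  tv <- thresholds(thr)
  if (!all(rownames(mset) %in% names(tv)))
    stop("thresholds must cover every analyte")
  tv <- tv[rownames(mset)]
  h <- SummarizedExperiment::assay(mset, "height")
  detected <- h >= tv   # column-wise recycling over analytes (rows)
  imputed <- ifelse(detected, h, tv)
  dimnames(detected) <- dimnames(imputed) <- dimnames(h)
  SummarizedExperiment::assay(mset, "detected") <- detected
  SummarizedExperiment::assay(mset, "imputed") <- imputed
  S4Vectors::metadata(mset)$thresholds <- thr
  mset
}

#' Group-versus-control differential abundance
#'
#' Per analyte: \code{log2fc = log2(mean(group) / mean(control))} on imputed
#' values and a two-sample t-test (pooled variance by default, Welch by
#' option) on imputed values. When every control sample is undetected and at
#' least one group sample is detected, the fold change is reported as
#' \code{+Inf} with \code{inf_reason = "control_undetected"} (mirrored as
#' \code{-Inf} / \code{"group_undetected"}); the t-test p-value on imputed
#' values is still reported alongside. Significance is the strict comparison
#' \code{p < alpha}.
#'
#' @param mset A detection-corrected \linkS4class{MetaboSet}
#'   (\code{\link{applyDetection}}).
#' @param group Treatment group label.
#' @param control Control group label (default: first group of the sample
#'   sheet ordering).
#' @param alpha Significance level (default 0.05, strict).
#' @param var_equal Pooled-variance t-test if \code{TRUE} (default), Welch
#'   otherwise.
#' @return data.frame: \code{analyte}, \code{group}, \code{log2fc},
#'   \code{p_value}, \code{significant}, \code{inf_reason}.
#' @export
differentialAbundance <- function(mset, group, control = NULL, alpha = 0.05,
                                  var_equal = TRUE) {
  stopifnot(is(mset, "MetaboSet"))
  if (!"imputed" %in% SummarizedExperiment::assayNames(mset))
    stop("run applyDetection() before differential testing")
  cd <- SummarizedExperiment::colData(mset)
  if (is.null(control)) control <- cd$group[cd$role == "sample"][1L]
  gi <- which(cd$group == group & cd$role == "sample")
  ci <- which(cd$group == control & cd$role == "sample")
  if (length(gi) < 2L || length(ci) < 2L)
    warning("fewer than 2 samples in an arm; p-values undefined",
            call. = FALSE)
  imp <- SummarizedExperiment::assay(mset, "imputed")
  det <- SummarizedExperiment::assay(mset, "detected")
  res <- lapply(rownames(mset), function(a) {
    x <- imp[a, ci]; y <- imp[a, gi]
    l2 <- log2(mean(y) / mean(x))
    p <- if (length(gi) < 2L || length(ci) < 2L) NA_real_ else
      suppressWarnings(.twoSampleP(x, y, var_equal))
    reason <- "none"
    if (!any(det[a, ci]) && any(det[a, gi])) {
      l2 <- Inf; reason <- "control_undetected"
    } else if (!any(det[a, gi]) && any(det[a, ci])) {
      l2 <- -Inf; reason <- "group_undetected"
    }
    data.frame(analyte = a, group = group, log2fc = l2, p_value = p,
               significant = !is.na(p) && p < alpha, inf_reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Differential abundance of every treatment group versus control
#'
#' @inheritParams differentialAbundance
#' @return Row-bound \code{\link{differentialAbundance}} tables over all
#'   non-control groups.
#' @export
differentialAll <- function(mset, control = NULL, alpha = 0.05,
                            var_equal = TRUE) {
  cd <- SummarizedExperiment::colData(mset)
  groups <- unique(cd$group[cd$role == "sample"])
  if (is.null(control)) control <- groups[1L]
  do.call(rbind, lapply(setdiff(groups, control), function(g)
    differentialAbundance(mset, g, control, alpha, var_equal)))
}

#' Hierarchical-clustering leaf orders of the imputed matrix
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of the
#' imputed value matrix, for heatmap export. Orders are deterministic; a
#' constant matrix yields the input order with a warning.
#'
#' @param mset A detection-corrected \linkS4class{MetaboSet}, or a plain
#'   numeric matrix.
#' @return list with \code{rows} and \code{cols}: leaf-ordered label vectors.
#' @export
clusterOrder <- function(mset) {
  m <- if (is(mset, "MetaboSet")) {
    if (!"imputed" %in% SummarizedExperiment::assayNames(mset))
      stop("run applyDetection() before clustering")
    SummarizedExperiment::assay(mset, "imputed")
  } else as.matrix(mset)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("clustering requires at least 2 rows and 2 columns")
  if (stats::sd(m) == 0) {
    warning("constant matrix: returning input order", call. = FALSE)
    return(list(rows = rownames(m), cols = colnames(m)))
  }
  ord <- function(d) stats::hclust(d, method = "complete")
  list(rows = rownames(m)[ord(stats::dist(m))$order],
       cols = colnames(m)[ord(stats::dist(t(m)))$order])
}

#' Volcano table of differential results
#'
#' Adds \code{neg_log10_p} and places infinite fold changes at a sentinel
#' abscissa (default: largest finite |log2fc| + 1, signed); rows are sorted
#' by p-value. An optional Benjamini-Hochberg FDR column is appended for
#' convenience; the primary significance call remains the unadjusted strict
#' \code{p < alpha}.
#'
#' @param results Output of \code{\link{differentialAbundance}} (or row-bound
#'   tables).
#' @param sentinel Abscissa magnitude for infinite fold changes; \code{NULL}
#'   picks \code{max(|finite log2fc|) + 1}.
#' @return data.frame sorted by p-value with columns of \code{results} plus
#'   \code{neg_log10_p}, \code{log2fc_plot}, \code{is_infinite}, \code{fdr}.
#' @export
volcanoTable <- function(results, sentinel = NULL) {
  if (!nrow(results)) stop("empty differential results")
  fin <- abs(results$log2fc[is.finite(results$log2fc)])
  if (is.null(sentinel)) sentinel <- if (length(fin)) max(fin) + 1 else 1
  out <- results
  out$neg_log10_p <- -log10(out$p_value)
  out$is_infinite <- is.infinite(out$log2fc)
  out$log2fc_plot <- ifelse(out$is_infinite, sign(out$log2fc) * sentinel,
                            out$log2fc)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
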