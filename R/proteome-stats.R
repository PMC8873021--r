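# Post-search proteome statistics: log2 + quantile normalization,
# complete-case filtering, reproducibility QC, omnibus ANOVA with
# Dunnett-style many-to-one post-hoc tests, and group-stratified pairwise
# tests versus the vehicle control.

#' Quantile normalization of matrix columns
#'
#' Forces every column to share one empirical distribution: each column's
#' sorted values are replaced by the vector of row means of the
#' column-sorted matrix; ties receive the mean of the tied reference values.
#'
#' @param m Numeric matrix (values on the scale to be normalized, typically
#'   log2).
#' @return The normalized matrix.
#' @examples
#' quantileNormalizeColumns(matrix(c(1, 3, 4, 2), 2)) # [[1.5,3.5],[3.5,1.5]]
#' @export
quantileNormalizeColumns <- function(m) {
  m <- as.matrix(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2 transform and quantile normalize a proteome matrix
#'
#' Normalization order is log2 first, then column quantile normalization.
#' Requires a complete matrix: run \code{\link{completeCaseFilter}} first.
#'
#' @param pset A \linkS4class{ProteomeSet} with no missing cells.
#' @return The \linkS4class{ProteomeSet} with added assay \code{"norm"}.
#' @export
log2QuantileNormalize <- function(pset) {
  stopifnot(is(pset, "ProteomeSet"))
  m <- SummarizedExperiment::assay(pset, "intensity")
  if (anyNA(m))
    stop("matrix has missing cells; run completeCaseFilter() first")
  if (any(m <= 0)) stop("non-positive intensity: cannot log2 transform")
  SummarizedExperiment::assay(pset, "norm") <-
    quantileNormalizeColumns(log2(m))
  pset
}

#' Retain proteins with no missing values
#'
#' The complete-case rule used for all downstream statistics: a protein is
#' kept iff it has a value in every sample.
#'
#' @param pset A \linkS4class{ProteomeSet}.
#' @return The complete-case subset, with the retained count in a message.
#' @export
completeCaseFilter <- function(pset) {
  stopifnot(is(pset, "ProteomeSet"))
  m <- SummarizedExperiment::assay(pset, "intensity")
  keep <- rowSums(is.na(m)) == 0L
  if (!any(keep))
    stop("no protein is observed in every sample; nothing to analyze")
  message(sum(keep), " of ", nrow(m),
          " proteins complete in all samples; retained")
  pset[keep, ]
}

#' Reproducibility QC report
#'
#' Per-sample log2-intensity distribution summaries, per-group per-protein
#' coefficients of variation on linear intensities (a CV of log values is not
#' a CV), group median CVs, and the sample x sample squared Pearson
#' correlation matrix on log2 values.
#'
#' @param pset A \linkS4class{ProteomeSet} (complete cases recommended).
#' @return list: \code{sample_summary} (data.frame of quartiles per sample),
#'   \code{cv} (protein x group matrix), \code{cv_group_median} (named
#'   vector), \code{r2} (sample x sample matrix, unit diagonal).
#' @export
qcReport <- function(pset) {
  stopifnot(is(pset, "ProteomeSet"))
  m <- SummarizedExperiment::assay(pset, "intensity")
  grp <- SummarizedExperiment::colData(pset)$group
  lg <- log2(m)
  qs <- t(apply(lg, 2L, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
  sample_summary <- data.frame(sample_id = colnames(m), qs,
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
  groups <- unique(grp)
  cv <- vapply(groups, function(g) {
    sub <- m[, grp == g, drop = FALSE]
    apply(sub, 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) return(NA_real_)
      stats::sd(x) / mean(x)
    })
  }, numeric(nrow(m)))
  colnames(cv) <- groups
  r2 <- stats::cor(lg, use = "pairwise.complete.obs")^2
  diag(r2) <- 1
  list(sample_summary = sample_summary, cv = cv,
       cv_group_median = apply(cv, 2L, stats::median, na.rm = TRUE),
       r2 = r2)
}

# Omnibus one-way fixed-effects ANOVA p-value for one protein with the
# package's degenerate conventions.
.onewayP <- function(y, g) {
  if (stats::sd(y) == 0) return(1)
  if (all(tapply(y, g, stats::sd) == 0)) return(0)  # separated, no noise
  stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
}

#' Omnibus ANOVA with Dunnett-style post-hoc versus the control
#'
#' Per protein: one-way fixed-effects ANOVA across all groups; where the
#' omnibus p-value is below \code{alpha}, many-to-one comparisons against the
#' control give a per-group post-hoc p-value and direction (Dunnett
#' single-step adjustment via \pkg{multcomp}, or Holm-corrected pooled
#' t-tests by option). A protein is differential in group g iff the omnibus
#' p < alpha AND the post-hoc p(g) < alpha (both strict); directions are only
#' reported where the post-hoc test is significant.
#'
#' @param pset A \linkS4class{ProteomeSet} carrying assay \code{"norm"}
#'   (see \code{\link{log2QuantileNormalize}}), or a plain matrix via
#'   \code{assay_name = NULL}.
#' @param control Control group label.
#' @param alpha Significance level (strict comparisons).
#' @param posthoc \code{"dunnett"} (default) or \code{"holm"}.
#' @return list: \code{omnibus} (data.frame \code{protein}, \code{p_omnibus})
#'   and \code{posthoc} (data.frame \code{protein}, \code{group}, \code{p},
#'   \code{direction}, \code{differential}), post-hoc rows present only for
#'   omnibus-significant proteins.
#' @export
anovaPosthoc <- function(pset, control = "vehicle", alpha = 0.05,
                         posthoc = c("dunnett", "holm")) {
  stopifnot(is(pset, "ProteomeSet"))
  posthoc <- match.arg(posthoc)
  m <- .statAssay(pset)
  grp <- SummarizedExperiment::colData(pset)$group
  if (!control %in% grp) stop("control group not found: ", control)
  g <- stats::relevel(factor(grp), ref = control)
  p_omni <- apply(m, 1L, .onewayP, g = g)
  omnibus <- data.frame(protein = rownames(m), p_omnibus = p_omni,
                        stringsAsFactors = FALSE, row.names = NULL)
  sig <- which(p_omni < alpha)
  ph <- lapply(sig, function(i)
    cbind(protein = rownames(m)[i],
          .manyToOne(m[i, ], g, alpha, posthoc)))
  ph <- if (length(ph)) do.call(rbind, ph) else
    data.frame(protein = character(), group = character(), p = numeric(),
               direction = integer(), differential = logical())
  rownames(ph) <- NULL
  list(omnibus = omnibus, posthoc = ph)
}

# Many-to-one comparisons of every treatment level against the reference
# level of g. Returns group, p, direction (sign of estimate, NA unless
# significant), differential flag.
.manyToOne <- function(y, g, alpha, method) {
  lev <- levels(g)[-1L]
  if (method == "dunnett") {
    # aov warns "essentially perfect fit" on noiseless degenerate input;
    # the Dunnett statistics are still well defined there
    gl <- withCallingHandlers({
      fit <- stats::aov(y ~ g)
      summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")),
              test = multcomp::adjusted("single-step"))
    }, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
    p <- as.numeric(gl$test$pvalues)
    est <- as.numeric(gl$test$coefficients)
  } else {
    ctrl <- y[g == levels(g)[1L]]
    p_raw <- vapply(lev, function(l)
      suppressWarnings(.twoSampleP(ctrl, y[g == l])), numeric(1))
    p <- stats::p.adjust(p_raw, method = "holm")
    est <- vapply(lev, function(l) mean(y[g == l]) - mean(ctrl), numeric(1))
  }
  sig <- !is.na(p) & p < alpha
  data.frame(group = lev, p = p,
             direction = ifelse(sig, as.integer(sign(est)), NA_integer_),
             differential = sig, stringsAsFactors = FALSE)
}

#' Group-stratified pairwise tests versus the control
#'
#' Two-sample t-test per protein restricted to the columns of one treatment
#' group and the control (the analysis behind the screen's distinct-protein
#' counts). Strict \code{p < alpha} calls.
#'
#' @inheritParams anovaPosthoc
#' @param group Treatment group label.
#' @param var_equal Pooled-variance t-test if \code{TRUE}.
#' @return data.frame: \code{protein}, \code{group}, \code{log2diff}
#'   (mean difference on the normalized log2 scale), \code{p_value},
#'   \code{called}.
#' @export
pairwiseVsControl <- function(pset, group, control = "vehicle",
                              alpha = 0.05, var_equal = TRUE) {
  stopifnot(is(pset, "ProteomeSet"))
  m <- .statAssay(pset)
  grp <- SummarizedExperiment::colData(pset)$group
  gi <- which(grp == group)
  ci <- which(grp == control)
  if (length(gi) < 2L || length(ci) < 2L)
    stop("at least 2 samples per arm required")
  res <- t(apply(m, 1L, function(y) {
    c(diff = mean(y[gi]) - mean(y[ci]),
      p = suppressWarnings(.twoSampleP(y[ci], y[gi], var_equal)))
  }))
  data.frame(protein = rownames(m), group = group,
             log2diff = res[, "diff"], p_value = res[, "p"],
             called = !is.na(res[, "p"]) & res[, "p"] < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Matrix used by the statistics: the normalized assay when present, else
# log2 of the raw intensities.
.statAssay <- function(pset) {
  if ("norm" %in% SummarizedExperiment::assayNames(pset))
    SummarizedExperiment::assay(pset, "norm")
  else log2(SummarizedExperiment::assay(pset, "intensity"))
}
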