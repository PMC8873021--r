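# Synthetic isobaric-label proteome matrices: log-normal intensities with
# additive donor offsets (log2 scale), group effects on an affected subset,
# multiplicative noise and missing-at-random cells.

#' Simulate a protein x sample intensity matrix with known truth
#'
#' Log2 intensities are \code{base + donor offset + group effect + noise};
#' base levels are drawn once per protein, donor offsets once per donor
#' (shared across groups, reflecting the paired design), group effects are
#' drawn for a random affected subset of proteins (one affected treatment
#' group each), and noise is multiplicative log-normal with the given CV.
#' Missing cells are missing completely at random.
#'
#' @param design A \linkS4class{StudyDesign}.
#' @param n_proteins Number of proteins (default 4857, the quantifiable-panel
#'   scale of the screen).
#' @param n_affected Number of proteins carrying a group effect
#'   (default 400, the scale of the screen's pairwise differential count).
#' @param effect_sd SD of the log2 group effects.
#' @param noise_cv Multiplicative noise CV on the linear scale.
#' @param donor_sd SD of the additive per-donor log2 offsets.
#' @param missing_rate Probability that a cell is missing; in [0, 0.5).
#' @param base_mean,base_sd Mean and SD of the per-protein base log2
#'   intensity.
#' @return list with \code{matrix} (a \linkS4class{ProteomeSet}) and
#'   \code{truth} (data.frame \code{protein}, \code{group}, \code{effect},
#'   \code{sign} for the affected subset).
#' @export
simulateProteinMatrix <- function(design, n_proteins = 4857,
                                  n_affected = 400, effect_sd = 0.5,
                                  noise_cv = 0.05, donor_sd = 0.1,
                                  missing_rate = 0.01,
                                  base_mean = 20, base_sd = 2) {
  stopifnot(is(design, "StudyDesign"))
  if (n_affected > n_proteins)
    stop("'n_affected' must not exceed 'n_proteins'")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("'missing_rate' must lie in [0, 0.5)")
  set.seed(deriveSeed(design@seed, "proteome"))
  sheet <- sampleSheet(design)
  sheet <- sheet[sheet$role == "sample", , drop = FALSE]
  n_s <- nrow(sheet)
  proteins <- sprintf("P%05d", seq_len(n_proteins))
  base <- stats::rnorm(n_proteins, base_mean, base_sd)
  donor_off <- stats::setNames(
    stats::rnorm(length(design@donors), 0, donor_sd), design@donors)
  treatments <- design@groups[-1L]
  truth <- data.frame(protein = character(), group = character(),
                      effect = numeric(), sign = integer(),
                      stringsAsFactors = FALSE)
  eff <- matrix(0, n_proteins, length(design@groups),
                dimnames = list(proteins, design@groups))
  if (n_affected > 0L) {
    idx <- sort(sample.int(n_proteins, n_affected))
    grp <- sample(treatments, n_affected, replace = TRUE)
    delta <- stats::rnorm(n_affected, 0, effect_sd)
    eff[cbind(idx, match(grp, design@groups))] <- delta
    truth <- data.frame(protein = proteins[idx], group = grp,
                        effect = delta, sign = as.integer(sign(delta)),
                        stringsAsFactors = FALSE)
  }
  log2sd <- sqrt(log(1 + noise_cv^2)) / log(2)
  m <- matrix(NA_real_, n_proteins, n_s,
              dimnames = list(proteins, sheet$sample_id))
  for (j in seq_len(n_s)) {
    mu <- base + donor_off[[sheet$donor[j]]] + eff[, sheet$group[j]]
    noise <- if (noise_cv > 0) stats::rnorm(n_proteins, 0, log2sd) else 0
    m[, j] <- 2^(mu + noise)
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_proteins * n_s) < missing_rate,
                   n_proteins, n_s)
    m[miss] <- NA_real_
  }
  list(matrix = ProteomeSet(m, group = sheet$group, donor = sheet$donor),
       truth = truth)
}

#' Construct a ProteomeSet from a matrix and sample annotations
#'
#' @param m Numeric protein x sample matrix, linear scale, \code{NA} for
#'   missing cells.
#' @param group,donor Per-sample labels.
#' @return A \linkS4class{ProteomeSet}.
#' @export
ProteomeSet <- function(m, group, donor) {
  m <- as.matrix(m)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    colData = S4Vectors::DataFrame(group = group, donor = donor,
                                   row.names = colnames(m)))
  new("ProteomeSet", se)
}

#' Write / read a protein matrix as TSV with a sample-sheet CSV
#'
#' The TSV has the accession in the first column and one column per sample;
#' missing cells are written as empty fields.
#'
#' @param pset A \linkS4class{ProteomeSet}.
#' @param matrix_tsv,samples_csv File paths.
#' @return \code{writeProteinMatrix}: the paths, invisibly;
#'   \code{readProteinMatrix}: a \linkS4class{ProteomeSet}.
#' @export
writeProteinMatrix <- function(pset, matrix_tsv, samples_csv) {
  m <- SummarizedExperiment::assay(pset, "intensity")
  df <- data.frame(accession = rownames(m),
                   format(m, digits = 12, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(m)] <- ""
  utils::write.table(df, matrix_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(pset))
  utils::write.csv(data.frame(sample_id = colnames(m), cd,
                              stringsAsFactors = FALSE),
                   samples_csv, row.names = FALSE)
  invisible(c(matrix_tsv, samples_csv))
}

#' @rdname writeProteinMatrix
#' @export
readProteinMatrix <- function(matrix_tsv, samples_csv) {
  df <- utils::read.delim(matrix_tsv, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  sheet <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  ProteomeSet(m, group = sheet$group, donor = sheet$donor)
}
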