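# Matrix-level ingest for the metabolome statistics: users (and tests) can
# supply an analyte x sample height matrix directly instead of mzML runs.

#' Construct a MetaboSet from a height matrix
#'
#' @param height Numeric analyte x sample matrix of peak heights (0 = no
#'   signal).
#' @param sample_sheet data.frame with columns \code{sample_id},
#'   \code{group}, \code{donor}, \code{role} covering the matrix columns.
#' @param library Optional metabolite library data.frame used as
#'   \code{rowData}.
#' @return A \linkS4class{MetaboSet} with assays \code{"height"} and
#'   \code{"found"}.
#' @export
MetaboSet <- function(height, sample_sheet, library = NULL) {
  height <- as.matrix(height)
  if (is.null(colnames(height))) colnames(height) <- sample_sheet$sample_id
  sheet <- sample_sheet[match(colnames(height), sample_sheet$sample_id), ,
                        drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("sample_sheet must cover every matrix column")
  rd <- if (is.null(library)) {
    S4Vectors::DataFrame(name = rownames(height))
  } else S4Vectors::DataFrame(library)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(height = height, found = height > 0),
    rowData = rd,
    colData = S4Vectors::DataFrame(sheet, row.names = colnames(height)))
  new("MetaboSet", se)
}

#' Read an intensity matrix written as TSV plus sample sheet
#'
#' Reads the \code{matrix.tsv} / \code{mask.tsv} / \code{samples.csv} trio
#' produced by the pipeline (first TSV column = analyte name).
#'
#' @param matrix_tsv Height matrix TSV path.
#' @param samples_csv Sample sheet CSV path.
#' @param mask_tsv Optional detection-mask TSV; when given, assays
#'   \code{"detected"} is populated from it.
#' @return A \linkS4class{MetaboSet}.
#' @export
readIntensityMatrix <- function(matrix_tsv, samples_csv, mask_tsv = NULL) {
  df <- utils::read.delim(matrix_tsv, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  sheet <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  mset <- MetaboSet(m, sheet)
  if (!is.null(mask_tsv)) {
    md <- utils::read.delim(mask_tsv, check.names = FALSE,
                            stringsAsFactors = FALSE)
    mask <- as.matrix(md[, -1, drop = FALSE])
    mode(mask) <- "logical"
    rownames(mask) <- md[[1]]
    SummarizedExperiment::assay(mset, "detected") <-
      mask[rownames(m), colnames(m)]
  }
  mset
}
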