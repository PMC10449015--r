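#' Read a gene x sample expression matrix
#'
#' Expects genes as rows with a \code{gene_id} first column and one column per
#' sample, values on the log scale. Delimiter is inferred from the file
#' extension (\code{.csv} comma, otherwise tab).
#'
#' @param path input file.
#' @return numeric matrix with gene IDs as rownames and sample IDs as colnames.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "gene_id") {
    stop("expression table must have `gene_id` as its first column")
  }
  Y <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(Y)) stop("expression values must be numeric")
  if (any(!is.finite(Y))) {
    stop("expression matrix contains non-finite values; ",
         "missing entries are not supported")
  }
  rownames(Y) <- as.character(tab$gene_id)
  Y
}

#' Write a gene x sample expression matrix
#'
#' Inverse of [read_expression()]; values are written at full double precision
#' so that a write/read round trip is lossless.
#'
#' @param Y numeric matrix, genes x samples, with dimnames.
#' @param path output file (\code{.csv} for comma-separated, otherwise TSV).
#' @export
write_expression <- function(Y, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  stopifnot(is.matrix(Y), !is.null(rownames(Y)), !is.null(colnames(Y)))
  tab <- data.frame(gene_id = rownames(Y),
                    format(Y, digits = 17, trim = TRUE, scientific = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# validate an expression matrix against a design; returns Y with dimnames set
check_expression <- function(Y, d = NULL) {
  if (!is.matrix(Y) || !is.numeric(Y)) stop("Y must be a numeric matrix")
  if (any(!is.finite(Y))) stop("Y contains non-finite values")
  if (is.null(rownames(Y))) rownames(Y) <- paste0("gene_", seq_len(nrow(Y)))
  if (!is.null(d)) {
    if (ncol(Y) != d$n) {
      stop("Y has ", ncol(Y), " columns but the design has ", d$n, " samples")
    }
    if (is.null(colnames(Y))) {
      colnames(Y) <- d$sample_ids
    } else if (!all(colnames(Y) == d$sample_ids)) {
      bad <- union(setdiff(colnames(Y), d$sample_ids),
                   setdiff(d$sample_ids, colnames(Y)))
      if (!length(bad)) bad <- "(same IDs, different order)"
      stop("expression columns do not match design samples: ",
           paste(bad, collapse = ", "))
    }
  }
  Y
}

#' Write a differential-expression result table
#'
#' @param res a \code{data.frame} as returned by the DE engines
#'   (columns \code{gene_id}, \code{estimate}, \code{se}, \code{t}, \code{df},
#'   \code{p}, \code{q}, \code{method}); row order is preserved.
#' @param path output TSV path.
#' @export
write_de_result <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
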