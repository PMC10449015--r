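#' Build a group-batch design
#'
#' Constructs the pair of design matrices used throughout the package: \code{X1}
#' holds an intercept column plus reference-coded (drop-first) indicators of the
#' biological groups, and \code{X2} holds reference-coded indicators of the
#' batches. The combined matrix \code{[X1, X2]} must be full rank; a
#' rank-deficient (confounded) design is rejected with an error naming the
#' collinear columns.
#'
#' @param groups character or factor vector of biological group labels, one per
#'   sample.
#' @param batches character or factor vector of batch labels, one per sample.
#' @param sample_ids optional character vector of unique sample identifiers;
#'   defaults to \code{sample_1 ... sample_n}.
#' @param reference_batch optional batch level to use as the reference (the
#'   level dropped from \code{X2}).
#' @param reference_group optional group level to use as the reference.
#'
#' @return An object of class \code{group_batch_design}: a list with elements
#'   \code{sample_ids}, \code{group}, \code{batch} (factors), \code{X1},
#'   \code{X2}, \code{n}, \code{B} (number of batches), \code{p1}
#'   (columns of \code{X1}), and \code{batch_sizes}.
#'
#' @examples
#' d <- build_design(groups  = c("A", "A", "B", "B"),
#'                   batches = c(1, 2, 1, 2))
#' d$X1  # intercept + group dummy
#' d$X2  # one batch dummy
#' @export
build_design <- function(groups, batches, sample_ids = NULL,
                         reference_batch = NULL, reference_group = NULL) {
  if (length(groups) != length(batches)) {
    stop("`groups` and `batches` must have the same length")
  }
  n <- length(groups)
  if (n < 2L) stop("need at least 2 samples")
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample_", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != n) stop("sample_ids length must match samples")

  group <- factor(as.character(groups))
  batch <- factor(as.character(batches))
  if (!is.null(reference_group)) {
    if (!reference_group %in% levels(group)) {
      stop("reference_group '", reference_group, "' is not a group level")
    }
    group <- stats::relevel(group, ref = as.character(reference_group))
  }
  if (!is.null(reference_batch)) {
    if (!reference_batch %in% levels(batch)) {
      stop("reference_batch '", reference_batch, "' is not a batch level")
    }
    batch <- stats::relevel(batch, ref = as.character(reference_batch))
  }
  if (any(table(batch) < 1L)) stop("every batch level needs at least 1 sample")

  if (nlevels(group) >= 2L) {
    X1 <- stats::model.matrix(~group)
    colnames(X1) <- c("(Intercept)",
                      paste0("group_", levels(group)[-1L]))
  } else {
    # intercept-only group design (no biological contrast; valid for
    # correlation-structure computations, not for DE)
    X1 <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  B <- nlevels(batch)
  if (B > 1L) {
    X2 <- stats::model.matrix(~batch)[, -1L, drop = FALSE]
    colnames(X2) <- paste0("batch_", levels(batch)[-1L])
  } else {
    X2 <- matrix(numeric(0), nrow = n, ncol = 0L)
  }
  attr(X1, "assign") <- NULL; attr(X1, "contrasts") <- NULL
  attr(X2, "assign") <- NULL; attr(X2, "contrasts") <- NULL

  X <- cbind(X1, X2)
  qrX <- qr(X)
  full_rank <- ncol(X1) + ncol(X2)
  if (qrX$rank < full_rank) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, full_rank)]]
    stop("confounded group-batch design: column(s) ",
         paste(sQuote(dropped), collapse = ", "),
         " are collinear with the remaining design columns")
  }

  structure(list(
    sample_ids  = sample_ids,
    group       = group,
    batch       = batch,
    X1          = X1,
    X2          = X2,
    n           = n,
    B           = B,
    p1          = ncol(X1),
    batch_sizes = as.integer(table(batch))
  ), class = "group_batch_design")
}

#' @export
print.group_batch_design <- function(x, ...) {
  cat("group-batch design:", x$n, "samples,",
      nlevels(x$group), "groups,", x$B, "batches\n")
  print(table(group = x$group, batch = x$batch))
  invisible(x)
}

#' Group-batch balance report
#'
#' Computes the sample covariance \code{S12} between the group-indicator
#' columns of \code{X1} (intercept excluded) and the batch-indicator columns
#' of \code{X2}, and the covariance \code{S22} of \code{X2}. The design is
#' balanced exactly when every group is distributed proportionally across
#' batches, which is equivalent to \code{S12 = 0}.
#'
#' @param d a \code{group_batch_design}.
#' @param tol tolerance on \code{max(abs(S12))} for declaring balance. Balance
#'   is a combinatorial property, so the tolerance only absorbs floating-point
#'   round-off.
#'
#' @return A list of class \code{balance_report} with \code{S12}, \code{S22},
#'   \code{max_abs_S12} and logical \code{is_balanced}.
#' @export
balance_report <- function(d, tol = 1e-10) {
  stopifnot(inherits(d, "group_batch_design"))
  if (d$B < 2L) {
    return(structure(list(S12 = matrix(numeric(0), 0, 0),
                          S22 = matrix(numeric(0), 0, 0),
                          max_abs_S12 = 0,
                          is_balanced = TRUE),
                     class = "balance_report"))
  }
  G1 <- d$X1[, -1L, drop = FALSE]
  S12 <- stats::cov(G1, d$X2)
  S22 <- stats::cov(d$X2)
  m <- if (length(S12)) max(abs(S12)) else 0
  structure(list(S12 = S12, S22 = S22,
                 max_abs_S12 = m,
                 is_balanced = m <= tol),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("group-batch balance: ",
      if (x$is_balanced) "balanced" else "unbalanced",
      " (max |S12| = ", format(x$max_abs_S12, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Read a phenotype table and build the matching design
#'
#' The phenotype table must have columns \code{sample}, \code{group} and
#' \code{batch}. Sample order must match the expression-matrix columns; any
#' mismatch is a hard error listing the offending identifiers.
#'
#' @param path path to a TSV or CSV phenotype file (delimiter inferred from the
#'   extension; \code{.csv} means comma, anything else tab).
#' @param sample_ids optional character vector (e.g. expression-matrix column
#'   names) that the table's \code{sample} column must match in order.
#' @param reference_batch,reference_group passed to [build_design()].
#' @return a \code{group_batch_design}.
#' @export
read_phenotype <- function(path, sample_ids = NULL,
                           reference_batch = NULL, reference_group = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ph <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "group", "batch")
  miss <- setdiff(need, names(ph))
  if (length(miss)) {
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != nrow(ph) ||
        !all(as.character(ph$sample) == as.character(sample_ids))) {
      bad <- union(setdiff(sample_ids, ph$sample), setdiff(ph$sample, sample_ids))
      if (!length(bad)) bad <- "(same IDs, different order)"
      stop("phenotype samples do not match expression columns: ",
           paste(bad, collapse = ", "))
    }
  }
  build_design(ph$group, ph$batch, sample_ids = ph$sample,
               reference_batch = reference_batch,
               reference_group = reference_group)
}
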