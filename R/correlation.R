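#' Oblique projector onto the batch design, group design projected out
#'
#' Removing estimated per-batch means from each gene is the linear map
#' \code{I - H12} applied to the sample vector, where
#' \deqn{H_{12} = X_2 (X_2^T P_1^\perp X_2)^{-1} X_2^T P_1^\perp,}
#' with \eqn{P_1^\perp = I - X_1 (X_1^T X_1)^{-1} X_1^T}. \code{H12} is
#' idempotent but in unbalanced designs not symmetric (an oblique projector),
#' and satisfies \code{H12 \%*\% X2 = X2}.
#'
#' @param d a \code{group_batch_design}.
#' @return an \code{n x n} matrix. With a single batch (empty \code{X2}) the
#'   zero matrix is returned: there is nothing to remove.
#' @export
compute_H12 <- function(d) {
  stopifnot(inherits(d, "group_batch_design"))
  n <- d$n
  if (ncol(d$X2) == 0L) return(matrix(0, n, n))
  X1 <- d$X1
  X2 <- d$X2
  P1 <- X1 %*% solve(crossprod(X1), t(X1))
  P1perp_X2 <- X2 - P1 %*% X2
  A <- crossprod(X2, P1perp_X2)          # X2' P1perp X2
  Ai <- tryCatch(solve(A), error = function(e) {
    stop("confounded design: X2' P1perp X2 is singular (batch indicators ",
         "lie in the span of the group design)")
  })
  X2 %*% Ai %*% t(P1perp_X2)
}

#' Induced sample correlation (up to scale) of two-step adjusted data
#'
#' The covariance of mean-adjusted data \eqn{\tilde Y_g = (I - H_{12}) Y_g} is
#' \eqn{\sigma_g^2 M} with \eqn{M = (I - H_{12})(I - H_{12})^T}. \code{M}
#' depends only on the design, not on the gene, and is rank-deficient: its rank
#' is \code{n - (B - 1)} for a non-confounded design with \code{B} batches.
#'
#' @param H12 matrix from [compute_H12()].
#' @return symmetric positive semi-definite \code{n x n} matrix.
#' @export
compute_M <- function(H12) {
  n <- nrow(H12)
  ImH <- diag(n) - H12
  M <- tcrossprod(ImH)
  (M + t(M)) / 2
}

#' Recommended range for the noise fraction zeta
#'
#' The rank repair of \code{M} adds a fraction \code{zeta} of the retained
#' eigenvalue mass back onto the null directions. Values between \code{0.1/n}
#' and \code{1/n} keep false positives controlled without a large power cost;
#' outside this range power degrades.
#'
#' @param n total sample size (>= 2).
#' @return numeric vector \code{c(low, high)} = \code{c(0.1/n, 1/n)}.
#' @export
recommended_zeta_range <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  c(low = 0.1 / n, high = 1 / n)
}

#' Parse a zeta value given as a fraction or a percentage
#'
#' Accepts \code{0.01}, \code{"0.01"} or \code{"1\%"} (all meaning the same
#' fraction). Internally zeta is always a fraction in (0, 1).
#'
#' @param zeta numeric fraction or a string, optionally with a \code{\%} suffix.
#' @return numeric fraction.
#' @export
parse_zeta <- function(zeta) {
  if (is.character(zeta)) {
    z <- trimws(zeta)
    if (grepl("%$", z)) {
      zeta <- as.numeric(sub("%$", "", z)) / 100
    } else {
      zeta <- as.numeric(z)
    }
  }
  if (!is.finite(zeta) || zeta <= 0 || zeta >= 1) {
    stop("zeta must be a fraction strictly between 0 and 1")
  }
  zeta
}

#' Full-rank spectral approximation of the induced correlation matrix
#'
#' Eigendecomposes \code{M = Q L Q'}, replaces the (structurally) zero
#' eigenvalues by \code{theta = zeta * sum(retained eigenvalues)}, and returns
#' \code{M_tilde = Q L_tilde Q'} together with its lower-triangular Cholesky
#' factor, used to whiten data for generalized least squares.
#'
#' Eigenvalues below \code{1e-10 * max(eigenvalue)} are treated as the zero
#' set. For a non-confounded design this set has exactly \code{B - 1} members;
#' pass \code{expected_null} to have the function verify that and warn on a
#' mismatch.
#'
#' @param M symmetric PSD matrix from [compute_M()].
#' @param zeta noise fraction in (0, 1); strings like \code{"1\%"} are
#'   accepted. Values outside [recommended_zeta_range()] trigger a warning
#'   (power loss) but are allowed.
#' @param expected_null optional integer: expected number of zero eigenvalues.
#' @return object of class \code{correlation_model}: list with \code{M},
#'   \code{eigenvalues}, \code{rank_M}, \code{n_replaced}, \code{zeta},
#'   \code{theta}, \code{M_tilde} and \code{whitener} (lower triangular
#'   \code{L} with \code{L L' = M_tilde}).
#' @export
approximate_M <- function(M, zeta, expected_null = NULL) {
  zeta <- parse_zeta(zeta)
  if (max(abs(M - t(M))) > 1e-8) stop("M must be symmetric")
  n <- nrow(M)
  rng <- recommended_zeta_range(n)
  if (zeta < rng[1L] || zeta > rng[2L]) {
    warning(sprintf(
      "zeta = %g is outside the recommended range [%.3g, %.3g] for n = %d; %s",
      zeta, rng[1L], rng[2L], n,
      "expect reduced statistical power"))
  }
  es <- eigen(M, symmetric = TRUE)
  lam <- es$values
  if (min(lam) < -1e-8 * max(lam)) {
    stop("M is not positive semi-definite")
  }
  null_set <- lam < 1e-10 * max(lam)
  if (!is.null(expected_null) && sum(null_set) != expected_null) {
    warning("found ", sum(null_set), " zero eigenvalues, expected ",
            expected_null, " from the design")
  }
  theta <- zeta * sum(lam[!null_set])
  lam_tilde <- lam
  lam_tilde[null_set] <- theta
  M_tilde <- es$vectors %*% (lam_tilde * t(es$vectors))
  M_tilde <- (M_tilde + t(M_tilde)) / 2
  L <- t(chol(M_tilde))
  structure(list(M = M,
                 eigenvalues = lam,
                 rank_M = sum(!null_set),
                 n_replaced = sum(null_set),
                 zeta = zeta,
                 theta = theta,
                 M_tilde = M_tilde,
                 whitener = L),
            class = "correlation_model")
}

#' Correlation model of a design in one call
#'
#' Convenience wrapper: [compute_H12()] then [compute_M()] then
#' [approximate_M()], verifying that the number of repaired eigenvalues equals
#' \code{B - 1}.
#'
#' @param d a \code{group_batch_design} with \code{B >= 2}.
#' @param zeta noise fraction (or percent string); defaults to the midpoint of
#'   [recommended_zeta_range()].
#' @return a \code{correlation_model} (see [approximate_M()]); also carries
#'   \code{H12}.
#' @export
correlation_model <- function(d, zeta = NULL) {
  stopifnot(inherits(d, "group_batch_design"))
  if (d$B < 2L) stop("correlation model needs at least 2 batches")
  if (is.null(zeta)) zeta <- mean(recommended_zeta_range(d$n))
  H12 <- compute_H12(d)
  M <- compute_M(H12)
  cm <- approximate_M(M, zeta, expected_null = d$B - 1L)
  cm$H12 <- H12
  cm
}

#' @export
print.correlation_model <- function(x, ...) {
  cat("induced-correlation model: n =", nrow(x$M),
      " rank(M) =", x$rank_M,
      " repaired =", x$n_replaced, "\n")
  cat("zeta =", format(x$zeta, digits = 4),
      " theta =", format(x$theta, digits = 4), "\n")
  invisible(x)
}
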