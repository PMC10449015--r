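# Per-gene differential-expression engines: OLS (with or without batch
# covariates), GLS on batch-adjusted data with the induced-correlation model,
# and the full correlation-aware two-step pipeline.

# assemble the standard DE table from vectorized ingredients
de_table <- function(gene_ids, estimate, se, df, method, zero_var = NULL) {
  t_stat <- estimate / se
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  if (!is.null(zero_var) && any(zero_var)) {
    estimate[zero_var] <- 0
    se[zero_var] <- NA_real_
    t_stat[zero_var] <- 0
    p[zero_var] <- 1
  } else {
    zero_var <- rep(FALSE, length(estimate))
  }
  data.frame(gene_id = gene_ids,
             estimate = estimate,
             se = se,
             t = t_stat,
             df = df,
             p = p,
             q = bh_adjust(p),
             zero_variance = zero_var,
             method = method,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values with enforced monotonicity, as in
#' \code{p.adjust(method = "BH")} (which is the implementation used).
#'
#' @param p vector of p-values in [0, 1]; \code{NA}/\code{NaN} is an error.
#' @return vector of q-values, same order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("p-values contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene OLS differential expression
#'
#' Ordinary least squares of each gene on the group design \code{X1}, with the
#' batch design \code{X2} optionally included as covariates (the one-step
#' model). A two-sided t-test is reported for one group coefficient. Genes with
#' zero residual variance get \code{p = 1} and are flagged rather than
#' returning \code{NaN}.
#'
#' @param Y genes x samples matrix. May be raw or batch-adjusted data.
#' @param d a \code{group_batch_design}.
#' @param include_batch logical; include \code{X2} in the model (one-step
#'   correction).
#' @param df residual degrees of freedom override. The default is
#'   \code{n - rank(model used)}; when testing batch-adjusted data with the
#'   group-only model, pass \code{n - rank([X1, X2])} to account for the batch
#'   parameters consumed during correction.
#' @param coef which group coefficient to test (index among the non-intercept
#'   columns of \code{X1}; default the first, i.e. a two-level group's only
#'   contrast).
#' @param method label stored in the result's \code{method} column.
#' @return \code{data.frame} with columns \code{gene_id}, \code{estimate},
#'   \code{se}, \code{t}, \code{df}, \code{p}, \code{q}, \code{zero_variance},
#'   \code{method}; rows in input gene order.
#' @export
ols_de <- function(Y, d, include_batch = FALSE, df = NULL, coef = 1L,
                   method = if (include_batch) "one_step" else "ols") {
  stopifnot(inherits(d, "group_batch_design"))
  Y <- check_expression(Y, d)
  X <- if (include_batch) cbind(d$X1, d$X2) else d$X1
  if (coef < 1L || coef > d$p1 - 1L) stop("coef out of range for the group design")
  j <- 1L + as.integer(coef)
  fit <- fit_ols(X, t(Y))
  if (fit$rank < ncol(X)) stop("design matrix is rank deficient")
  rss <- colSums(fit$residuals^2)
  df_fit <- d$n - ncol(X)
  if (is.null(df)) df <- df_fit
  if (df <= 0) stop("non-positive residual degrees of freedom")
  xtxi_jj <- chol2inv(qr.R(fit$qr))[j, j]
  zero_var <- rss <= .Machine$double.eps * d$n * apply(Y, 1L, function(r) max(1, max(abs(r))))^2
  s2 <- rss / df
  se <- sqrt(s2 * xtxi_jj)
  de_table(rownames(Y), fit$coefficients[j, ], se, df, method, zero_var)
}

#' Naive two-sample t-test per gene
#'
#' Equal-variance two-sample t-test of group on the (unadjusted) data;
#' identical to [ols_de()] without batch covariates but labelled as the
#' unadjusted baseline.
#'
#' @inheritParams ols_de
#' @return DE table as in [ols_de()].
#' @export
ttest_de <- function(Y, d) {
  ols_de(Y, d, include_batch = FALSE, method = "ttest_raw")
}

#' GLS differential expression under the induced-correlation model
#'
#' Whitens \code{X1} and each adjusted gene vector by the inverse Cholesky
#' factor of \code{M_tilde} and runs OLS on the whitened data, which is GLS
#' with covariance proportional to \code{M_tilde}. A t-test is reported on the
#' group coefficient with the supplied degrees of freedom.
#'
#' @param Y_adj batch-adjusted genes x samples matrix.
#' @param d the \code{group_batch_design} the adjustment used.
#' @param cm a \code{correlation_model} built from the same design.
#' @param df residual degrees of freedom; default \code{n - rank([X1, X2])},
#'   accounting for the batch parameters estimated during adjustment.
#' @param coef,method as in [ols_de()].
#' @return DE table as in [ols_de()].
#' @export
gls_de <- function(Y_adj, d, cm, df = NULL, coef = 1L, method = "gls") {
  stopifnot(inherits(d, "group_batch_design"),
            inherits(cm, "correlation_model"))
  Y_adj <- check_expression(Y_adj, d)
  if (nrow(cm$M_tilde) != d$n) stop("correlation model does not match design n")
  if (is.null(df)) df <- d$n - (d$p1 + ncol(d$X2))
  if (df <= 0) stop("non-positive residual degrees of freedom")
  if (coef < 1L || coef > d$p1 - 1L) stop("coef out of range for the group design")
  j <- 1L + as.integer(coef)
  L <- cm$whitener
  W <- forwardsolve(L, cbind(d$X1, t(Y_adj)))     # n x (p1 + G)
  X1w <- W[, seq_len(d$p1), drop = FALSE]
  Yw <- W[, -seq_len(d$p1), drop = FALSE]         # n x G
  fit <- fit_ols(X1w, Yw)
  if (fit$rank < d$p1) stop("whitened design is rank deficient")
  rss <- colSums(fit$residuals^2)
  xtxi_jj <- chol2inv(qr.R(fit$qr))[j, j]
  zero_var <- rss <= .Machine$double.eps * d$n *
    apply(Y_adj, 1L, function(r) max(1, max(abs(r))))^2
  se <- sqrt(rss / df * xtxi_jj)
  de_table(rownames(Y_adj), fit$coefficients[j, ], se, df, method, zero_var)
}

#' Correlation-aware two-step differential expression (ComBat+Cor)
#'
#' The full pipeline: (1) empirical-Bayes location/scale batch correction;
#' (2) induced-correlation model of the design with rank repair at noise
#' fraction \code{zeta}; (3) GLS differential expression on the adjusted data
#' with residual degrees of freedom \code{n - rank([X1, X2])}. q-values are
#' Benjamini-Hochberg.
#'
#' @param Y genes x samples matrix (log scale, uncorrected).
#' @param d a \code{group_batch_design} with \code{B >= 2}.
#' @param zeta noise fraction for the rank repair (fraction or percent string);
#'   default the midpoint of [recommended_zeta_range()].
#' @param mean_only passed to [combat_fit()].
#' @param coef group coefficient to test.
#' @return DE table as in [ols_de()], method \code{"combatcor"}; attributes
#'   \code{fit} (the \code{batch_correction_fit}) and \code{correlation_model}
#'   carry the intermediate objects.
#' @export
combatcor_pipeline <- function(Y, d, zeta = NULL, mean_only = FALSE, coef = 1L) {
  stopifnot(inherits(d, "group_batch_design"))
  if (d$B < 2L) stop("nothing to correct: design has a single batch")
  fit <- combat_fit(Y, d, mean_only = mean_only)
  Y_adj <- combat_adjust(fit, Y)
  cm <- correlation_model(d, zeta = zeta)
  res <- gls_de(Y_adj, d, cm, df = d$n - (d$p1 + ncol(d$X2)),
                coef = coef, method = "combatcor")
  attr(res, "fit") <- fit
  attr(res, "correlation_model") <- cm
  res
}
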