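# Batch-effect removal on log-scale expression: mean-only regression
# adjustment and the empirical-Bayes location/scale (ComBat) model.

#' Mean-only two-step batch adjustment
#'
#' Per gene, fits OLS of the expression vector on \code{[X1, X2]} and removes
#' the estimated batch component, leaving the group structure in \code{X1}
#' untouched. Estimated batch effects are centred at their sample-size-weighted
#' mean before removal, so the corrected data are anchored at the grand mean
#' rather than at the reference batch; this shifts every sample of a gene by
#' the same constant and leaves group-effect inference unchanged.
#'
#' @param Y numeric genes x samples matrix (log scale).
#' @param d a \code{group_batch_design} with \code{B >= 2}.
#' @return matrix of the same dimension as \code{Y}.
#' @export
meanonly_adjust <- function(Y, d) {
  stopifnot(inherits(d, "group_batch_design"))
  if (d$B < 2L) stop("nothing to adjust: design has a single batch")
  Y <- check_expression(Y, d)
  X <- cbind(d$X1, d$X2)
  fit <- fit_ols(X, t(Y))
  coefs <- fit$coefficients                       # (p1 + B - 1) x G
  idx2 <- seq(d$p1 + 1L, ncol(X))
  beta2 <- coefs[idx2, , drop = FALSE]            # (B - 1) x G
  # weighted centring: gbar_g = sum_i (n_i/n) gamma_ig with gamma_ref = 0
  w <- d$batch_sizes / d$n
  gbar <- as.numeric(w[-1L] %*% beta2)            # length G
  adj <- d$X2 %*% beta2 - matrix(gbar, d$n, nrow(Y), byrow = TRUE)
  out <- Y - t(adj)
  dimnames(out) <- dimnames(Y)
  out
}

#' Fit the empirical-Bayes location/scale batch model
#'
#' Models each gene as background plus group effect plus per-batch mean shift
#' (gamma) and per-batch variance scaling (delta):
#' \deqn{Y_{ijg} = \alpha_g + X_1 \beta_g + \gamma_{ig} + \delta_{ig}
#'   \epsilon_{ijg}, \quad \epsilon_{ijg} \sim N(0, \sigma_g^2).}
#' The fit standardizes each gene by its full-design OLS fit, estimates batch
#' locations/scales per gene, and (optionally) shrinks them across genes with
#' parametric empirical Bayes: a normal prior on gamma and an inverse-gamma
#' prior on delta^2, hyperparameters by method of moments, posterior solved by
#' fixed-point iteration.
#'
#' @param Y numeric genes x samples matrix (log scale).
#' @param d a \code{group_batch_design} with \code{B >= 2}.
#' @param parametric logical; parametric EB priors (the only mode provided).
#' @param mean_only logical; if \code{TRUE} only batch means are corrected and
#'   all delta* are fixed at 1.
#' @param eb logical; if \code{FALSE} no shrinkage is applied and gamma*/delta*
#'   equal their per-gene method-of-moments estimates.
#' @param conv convergence tolerance of the EB fixed-point iteration (maximum
#'   relative change in gamma* and delta*).
#' @param max_iter iteration cap.
#'
#' @return object of class \code{batch_correction_fit}: per-gene \code{alpha}
#'   (grand-mean background), \code{beta} (group coefficients, p1-1 x G),
#'   \code{sigma2} (pooled residual variance, MLE divisor n), \code{gamma_hat}
#'   / \code{delta2_hat} (B x G raw batch location/scale on the standardized
#'   scale), \code{gamma_star} / \code{delta2_star} (shrunk values used for
#'   adjustment), per-batch hyperparameters, and flags.
#' @export
combat_fit <- function(Y, d, parametric = TRUE, mean_only = FALSE, eb = TRUE,
                       conv = 1e-4, max_iter = 500L) {
  stopifnot(inherits(d, "group_batch_design"))
  if (d$B < 2L) stop("batch correction needs at least 2 batches")
  if (!parametric) stop("only the parametric EB mode is implemented")
  Y <- check_expression(Y, d)
  if (!mean_only && any(d$batch_sizes < 2L)) {
    stop("batch level(s) ",
         paste(levels(d$batch)[d$batch_sizes < 2L], collapse = ", "),
         " have a single sample; the scale effect is not estimable -- ",
         "use mean_only = TRUE")
  }
  G <- nrow(Y)
  n <- d$n
  B <- d$B
  X <- cbind(d$X1, d$X2)

  fit <- fit_ols(X, t(Y))
  coefs <- fit$coefficients
  alpha_ref <- coefs[1L, ]                                  # reference-batch intercept
  beta <- coefs[seq(2L, d$p1), , drop = FALSE]              # group coefficients
  gamma_ols <- coefs[seq(d$p1 + 1L, ncol(X)), , drop = FALSE]  # (B-1) x G
  w <- d$batch_sizes / n
  gbar <- as.numeric(w[-1L] %*% gamma_ols)                  # weighted batch mean
  alpha <- alpha_ref + gbar                                 # grand-mean background
  resid <- t(fit$residuals)                                 # G x n
  sigma2 <- rowSums(resid^2) / n                            # MLE convention
  if (any(sigma2 <= 0)) {
    stop("gene(s) with zero residual variance: ",
         paste(utils::head(rownames(Y)[sigma2 <= 0], 5L), collapse = ", "))
  }
  sds <- sqrt(sigma2)

  # standardized data: remove background + group fit, divide by pooled sd;
  # batch mean structure is retained in Z
  stand <- matrix(alpha, G, n) + t(d$X1[, -1L, drop = FALSE] %*% beta)
  Z <- (Y - stand) / sds

  batch_idx <- split(seq_len(n), d$batch)
  gamma_hat <- matrix(NA_real_, B, G, dimnames = list(levels(d$batch), rownames(Y)))
  delta2_hat <- matrix(1, B, G, dimnames = dimnames(gamma_hat))
  for (i in seq_len(B)) {
    Zi <- Z[, batch_idx[[i]], drop = FALSE]
    gamma_hat[i, ] <- rowMeans(Zi)
    if (!mean_only) {
      ni <- length(batch_idx[[i]])
      delta2_hat[i, ] <- rowSums((Zi - gamma_hat[i, ])^2) / (ni - 1L)
    }
  }

  hyper <- data.frame(batch = levels(d$batch),
                      gamma_bar = rowMeans(gamma_hat),
                      tau2_bar = apply(gamma_hat, 1L, stats::var),
                      lambda_bar = NA_real_, theta_bar = NA_real_)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iters <- integer(B)

  if (eb) {
    for (i in seq_len(B)) {
      ni <- length(batch_idx[[i]])
      Zi <- Z[, batch_idx[[i]], drop = FALSE]
      g_bar <- hyper$gamma_bar[i]
      t2 <- hyper$tau2_bar[i]
      if (mean_only) {
        # posterior mean with delta fixed at 1; no iteration needed
        gamma_star[i, ] <- (t2 * ni * gamma_hat[i, ] + g_bar) / (t2 * ni + 1)
        next
      }
      m <- mean(delta2_hat[i, ])
      s2 <- stats::var(delta2_hat[i, ])
      lambda <- (2 * s2 + m^2) / s2            # inverse-gamma shape
      theta <- (m * s2 + m^3) / s2             # inverse-gamma scale
      hyper$lambda_bar[i] <- lambda
      hyper$theta_bar[i] <- theta
      g_old <- gamma_hat[i, ]
      d_old <- delta2_hat[i, ]
      it <- 0L
      repeat {
        it <- it + 1L
        g_new <- (t2 * ni * gamma_hat[i, ] + d_old * g_bar) / (t2 * ni + d_old)
        sum2 <- rowSums((Zi - g_new)^2)
        d_new <- (0.5 * sum2 + theta) / (ni / 2 + lambda - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old))
        g_old <- g_new
        d_old <- d_new
        if (change < conv || it >= max_iter) break
      }
      iters[i] <- it
      gamma_star[i, ] <- g_old
      delta2_star[i, ] <- d_old
    }
  }

  structure(list(alpha = alpha, beta = beta, sigma2 = sigma2,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 hyper = hyper, iterations = iters,
                 mean_only = mean_only, eb = eb, parametric = parametric,
                 design = d, gene_ids = rownames(Y)),
            class = "batch_correction_fit")
}

#' @export
print.batch_correction_fit <- function(x, ...) {
  cat("location/scale batch-correction fit:",
      length(x$gene_ids), "genes,", x$design$B, "batches",
      if (x$eb) "(EB shrinkage)" else "(no shrinkage)",
      if (x$mean_only) "[mean-only]" else "", "\n")
  print(x$hyper, digits = 3)
  invisible(x)
}

#' Apply a fitted location/scale correction
#'
#' Rescales the standardized data of each gene so that every batch shares the
#' pooled location and scale:
#' \deqn{\tilde Y_{ijg} = \hat\sigma_g (Z_{ijg} - \hat\gamma^*_{ig}) /
#'   \hat\delta^*_{ig} + \hat\alpha_g + X_1 \hat\beta_g.}
#'
#' @param fit a \code{batch_correction_fit}.
#' @param Y the matrix the fit was produced from (same genes and samples).
#' @return adjusted matrix with the dimensions of \code{Y}.
#' @export
combat_adjust <- function(fit, Y) {
  stopifnot(inherits(fit, "batch_correction_fit"))
  d <- fit$design
  Y <- check_expression(Y, d)
  if (nrow(Y) != length(fit$gene_ids) ||
      !all(rownames(Y) == fit$gene_ids)) {
    stop("gene set of Y does not match the fit")
  }
  G <- nrow(Y)
  n <- d$n
  sds <- sqrt(fit$sigma2)
  stand <- matrix(fit$alpha, G, n) +
    t(d$X1[, -1L, drop = FALSE] %*% fit$beta)
  Z <- (Y - stand) / sds
  bi <- as.integer(d$batch)
  gam <- t(fit$gamma_star)[, bi, drop = FALSE]     # G x n
  del <- sqrt(t(fit$delta2_star))[, bi, drop = FALSE]
  out <- sds * (Z - gam) / del + stand
  dimnames(out) <- dimnames(Y)
  out
}

#' Residual variance implied by the location/scale model
#'
#' The per-gene residual variance of corrected data under the location/scale
#' model is approximately the batch-size-weighted mixture
#' \deqn{\tilde\sigma_g^2 \approx \sum_i (n_i / n)\, \hat\delta^{*2}_{ig}
#'   \hat\sigma_g^2.}
#' With all delta* at 1 this reduces to the pooled variance. When some delta*
#' fall below 1 the mixture underestimates the noise (exaggerated
#' significance); when most exceed 1 it overestimates it (diminished
#' significance).
#'
#' @param fit a \code{batch_correction_fit}.
#' @param d optional design; defaults to the one stored in the fit.
#' @return numeric vector, one variance per gene.
#' @export
combat_residual_variance <- function(fit, d = NULL) {
  stopifnot(inherits(fit, "batch_correction_fit"))
  if (is.null(d)) d <- fit$design
  w <- d$batch_sizes / d$n
  as.numeric(w %*% fit$delta2_star) * fit$sigma2
}
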