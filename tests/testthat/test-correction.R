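# 6-sample hand oracle: 2 groups x 2 batches, normal equations solved directly
hand_design <- function() {
  build_design(c("A", "A", "B", "A", "B", "B"), c(1, 1, 1, 2, 2, 2))
}

test_that("mean-only adjustment matches a hand normal-equation oracle", {
  d <- hand_design()
  y <- c(3.1, 2.9, 5.0, 3.8, 5.9, 6.2)
  X <- cbind(d$X1, d$X2)
  beta <- solve(t(X) %*% X, t(X) %*% y)          # independent solve
  b2 <- beta[3L]
  w <- d$batch_sizes / d$n
  expect_oracle <- y - (d$X2[, 1L] * b2 - w[2L] * b2)  # grand-mean anchored
  Y <- matrix(y, 1, 6, dimnames = list("g1", d$sample_ids))
  expect_equal(as.numeric(meanonly_adjust(Y, d)), as.numeric(expect_oracle),
               tolerance = 1e-12)
})

test_that("data with no batch effect pass through mean-only adjustment", {
  d <- hand_design()
  y <- 1 + 2 * d$X1[, 2L]                         # Y = X1 beta exactly
  Y <- matrix(y, 1, 6, dimnames = list("g1", d$sample_ids))
  expect_equal(as.numeric(meanonly_adjust(Y, d)), as.numeric(y),
               tolerance = 1e-12)
})

test_that("group estimates after mean-only adjustment equal one-step OLS", {
  s <- small_scenario()
  sim <- simulate_dataset(s)
  d <- s$design
  Ya <- meanonly_adjust(sim$Y, d)
  one <- ols_de(sim$Y, d, include_batch = TRUE)
  two <- ols_de(Ya, d, include_batch = FALSE, df = d$n - 6L)
  expect_equal(two$estimate, one$estimate, tolerance = 1e-8)
})

test_that("EB fit matches the independent reference implementation", {
  skip_if_not_installed("sva")
  s <- small_scenario(n_genes = 300L, seed = 42L)
  sim <- simulate_dataset(s)
  d <- s$design
  mine <- combat_adjust(combat_fit(sim$Y, d), sim$Y)
  mod <- stats::model.matrix(~group, data = data.frame(group = d$group))
  ref <- suppressMessages(sva::ComBat(dat = sim$Y, batch = d$batch, mod = mod))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("without shrinkage gamma* equals per-batch means of standardized data", {
  s <- small_scenario(n_genes = 120L, seed = 9L)
  sim <- simulate_dataset(s)
  d <- s$design
  fit <- combat_fit(sim$Y, d, mean_only = TRUE, eb = FALSE)
  expect_equal(fit$gamma_star, fit$gamma_hat)
  expect_true(all(fit$delta2_star == 1))
  # gamma_hat really is the batch mean of the standardized matrix
  stand <- matrix(fit$alpha, nrow(sim$Y), d$n) +
    t(d$X1[, -1L, drop = FALSE] %*% fit$beta)
  Z <- (sim$Y - stand) / sqrt(fit$sigma2)
  for (b in levels(d$batch)) {
    expect_equal(fit$gamma_hat[b, ],
                 rowMeans(Z[, d$batch == b, drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("mean-only no-EB correction is identical to regression adjustment", {
  s <- small_scenario(n_genes = 100L, seed = 77L)
  sim <- simulate_dataset(s)
  d <- s$design
  fit <- combat_fit(sim$Y, d, mean_only = TRUE, eb = FALSE)
  expect_equal(combat_adjust(fit, sim$Y), meanonly_adjust(sim$Y, d),
               tolerance = 1e-10)
})

test_that("a constant shift moves alpha only", {
  s <- small_scenario(n_genes = 60L, seed = 13L)
  sim <- simulate_dataset(s)
  d <- s$design
  f1 <- combat_fit(sim$Y, d)
  Y2 <- sim$Y
  Y2[7L, ] <- Y2[7L, ] + 5
  f2 <- combat_fit(Y2, d)
  expect_equal(f2$alpha[7L], f1$alpha[7L] + 5, tolerance = 1e-8)
  expect_equal(f2$beta[, 7L], f1$beta[, 7L], tolerance = 1e-8)
  expect_equal(f2$gamma_hat[, 7L], f1$gamma_hat[, 7L], tolerance = 1e-8)
  expect_equal(f2$delta2_hat[, 7L], f1$delta2_hat[, 7L], tolerance = 1e-8)
})

test_that("correcting already-corrected data is a near no-op", {
  # location removal is exact, so a refit finds no batch means left even on
  # the tiny-batch unbalanced layout (scale medians there are dominated by
  # small-sample variance-divisor conventions and are checked on the
  # better-sized design below)
  s <- small_scenario(n_genes = 2000L, seed = 21L)
  sim <- simulate_dataset(s)
  d <- s$design
  fit <- combat_fit(sim$Y, d, eb = FALSE)
  refit <- combat_fit(combat_adjust(fit, sim$Y), d, eb = FALSE)
  expect_lt(max(abs(apply(refit$gamma_star, 1L, stats::median))), 0.05)
  # with EB shrinkage, residual batch scale after one pass stays small when
  # batches are large enough for the scale to be well estimated
  dr <- layout_design(cases = rep(10, 5), controls = rep(10, 5))
  hy <- data.frame(batch = 1:5, m = c(-0.5, 0.3, 0, 0.8, -0.2), v = 1,
                   alpha = 6, beta = 5, delta_fixed = FALSE)
  sr <- sim_scenario(design = dr, n_genes = 2000L, seed = 22L, hyper = hy)
  simr <- simulate_dataset(sr)
  fit2 <- combat_fit(simr$Y, dr)
  refit2 <- combat_fit(combat_adjust(fit2, simr$Y), dr)
  expect_lt(max(abs(apply(refit2$gamma_star, 1L, stats::median))), 0.05)
  expect_lt(max(abs(apply(refit2$delta2_star, 1L, stats::median) - 1)), 0.05)
})

test_that("residual variance mixture follows the weighted-delta formula", {
  d <- build_design(c("A", "B", "A", "B"), c(1, 1, 2, 2))
  # synthetic fit object with known parts: n = (2, 2) -> equal weights
  s <- small_scenario(n_genes = 50L, seed = 31L)
  sim <- simulate_dataset(s)
  fit <- combat_fit(sim$Y, s$design)
  # all delta at 1 returns sigma2 exactly
  fit1 <- fit
  fit1$delta2_star[] <- 1
  expect_equal(combat_residual_variance(fit1), fit$sigma2)
  # two batches n = (3, 1), delta*^2 = (2, 4), sigma2 = 1 -> 0.75*2 + 0.25*4
  d2 <- build_design(c("A", "A", "B", "B"), c(1, 1, 1, 2))
  fit2 <- fit
  fit2$design <- d2
  fit2$delta2_star <- matrix(c(2, 4), 2L, length(fit$sigma2))
  fit2$sigma2 <- rep(1, length(fit$sigma2))
  expect_equal(unique(combat_residual_variance(fit2)), 2.5)
})

test_that("variance batch effects raise the implied residual variance", {
  s_null <- small_scenario(n_genes = 2000L, seed = 5L, var_level = "null")
  s_lrg <- small_scenario(n_genes = 2000L, seed = 5L, var_level = "large")
  f_null <- combat_fit(simulate_dataset(s_null)$Y, s_null$design)
  f_lrg <- combat_fit(simulate_dataset(s_lrg)$Y, s_lrg$design)
  expect_gt(mean(combat_residual_variance(f_lrg)),
            mean(combat_residual_variance(f_null)))
})

test_that("EB recovers the identifiable batch parameters on synthetic truth", {
  # recovery is assessed against the estimable transforms: gamma centred by
  # the batch-size-weighted mean and scaled by the weighted variance mixture,
  # delta^2 relative to that mixture (the absolute values are not identified)
  d <- layout_design(cases = rep(50, 3), controls = rep(50, 3))
  hyper <- data.frame(batch = 1:3, m = c(-0.5, 0.3, 0.8), v = 1,
                      alpha = 8, beta = 7, delta_fixed = FALSE)
  s <- sim_scenario(design = d, n_genes = 20000L, seed = 11L, hyper = hyper)
  sim <- simulate_dataset(s)
  fit <- combat_fit(sim$Y, d)
  w <- d$batch_sizes / d$n
  gbar <- as.numeric(w %*% sim$gamma)
  mix <- as.numeric(w %*% sim$delta^2)
  for (i in seq_len(d$B)) {
    g_truth <- (sim$gamma[i, ] - gbar) / sqrt(sim$sigma2 * mix)
    expect_gt(stats::cor(fit$gamma_star[i, ], g_truth), 0.9)
    expect_gt(stats::cor(fit$delta2_star[i, ], sim$delta[i, ]^2 / mix), 0.8)
  }
})

test_that("variance-null data yield delta*^2 medians near 1", {
  s <- sim_scenario(design = "unbalanced", mean_level = "small",
                    var_level = "null", n_genes = 20000L, seed = 3L)
  fit <- combat_fit(simulate_dataset(s)$Y, s$design)
  med <- apply(fit$delta2_star, 1L, stats::median)
  expect_true(all(med > 0.9 & med < 1.1))
})

test_that("correction removes per-batch scale differences", {
  s <- sim_scenario(design = "unbalanced", mean_level = "small",
                    var_level = "small", n_genes = 20000L, seed = 15L)
  sim <- simulate_dataset(s)
  d <- s$design
  fit <- combat_fit(sim$Y, d)
  Ya <- combat_adjust(fit, sim$Y)
  stand <- matrix(fit$alpha, nrow(Ya), d$n) +
    t(d$X1[, -1L, drop = FALSE] %*% fit$beta)
  Z <- (Ya - stand) / sqrt(fit$sigma2)
  overall <- mean(apply(Z, 1L, stats::var))
  for (b in levels(d$batch)) {
    ratio <- mean(apply(Z[, d$batch == b, drop = FALSE], 1L, stats::var)) / overall
    expect_gt(ratio, 0.8)
    expect_lt(ratio, 1.25)
  }
})

test_that("singleton batches require mean-only mode", {
  set.seed(8)
  d <- build_design(c("A", "B", "A", "B", "A"), c(1, 2, 2, 2, 2))
  Y <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), d$sample_ids))
  expect_error(combat_fit(Y, d), "mean_only")
  expect_silent(fit <- combat_fit(Y, d, mean_only = TRUE))
  expect_true(all(fit$delta2_star == 1))
})

test_that("expression I/O round trip is lossless", {
  Y <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(Y, path)
  expect_equal(read_expression(path), Y)
})
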