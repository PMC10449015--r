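# Synthetic expression data from the hierarchical location/scale batch model,
# under the bladder-cancer study layouts used for benchmarking, plus matched
# batch-free benchmark data sharing the same biology and noise draws.

# per-batch hyperparameters of the mean (gamma ~ N(m, v)) and variance
# (delta ~ InvGamma(alpha, scale beta)) batch effects; the "small" column
# equals the values estimated from the original bladder data, "large" is the
# inflated variant
.tab1 <- list(
  m     = list(small = c(-0.04, 0.15, -0.15, -0.10, -0.08),
               large = c(-0.40, 1.50, -1.50,  1.00, -0.80)),
  v     = list(small = c(0.15, 0.35, 0.82, 0.46, 0.12),
               large = c(0.15, 0.35, 0.82, 0.46, 0.12)),
  alpha = list(small = c(60, 100, 56, 30, 100),
               large = c(100, 120, 100, 60, 40)),
  beta  = list(small = c(60, 100, 50, 30, 100),
               large = c(100, 40, 60, 100, 120))
)

#' Batch-effect hyperparameters for the built-in scenarios
#'
#' Returns the per-batch hyperparameters governing the simulated batch
#' effects: \code{gamma_ig ~ N(m_i, v_i)} (with \code{v_i} a variance) and
#' \code{delta_ig ~ InvGamma(alpha_i, scale = beta_i)} (mean
#' \code{beta/(alpha-1)}, close to 1 for the small condition). Levels:
#' \code{"null"} switches the effect off entirely (\code{gamma = 0} /
#' \code{delta = 1}), \code{"small"} uses the values estimated from the
#' original bladder-cancer data, \code{"large"} their inflated variants.
#'
#' @param mean_level,var_level one of \code{"null"}, \code{"small"},
#'   \code{"large"}.
#' @return \code{data.frame} with one row per batch (5) and columns
#'   \code{batch}, \code{m}, \code{v}, \code{alpha}, \code{beta},
#'   \code{delta_fixed} (TRUE when \code{delta} is pinned at 1).
#' @export
table1_hyperparams <- function(mean_level = c("null", "small", "large"),
                               var_level = c("null", "small", "large")) {
  mean_level <- match.arg(mean_level)
  var_level <- match.arg(var_level)
  B <- 5L
  out <- data.frame(batch = seq_len(B),
                    m = 0, v = 0,
                    alpha = NA_real_, beta = NA_real_,
                    delta_fixed = var_level == "null")
  if (mean_level != "null") {
    out$m <- .tab1$m[[mean_level]]
    out$v <- .tab1$v[[mean_level]]
  }
  if (var_level != "null") {
    out$alpha <- .tab1$alpha[[var_level]]
    out$beta <- .tab1$beta[[var_level]]
  }
  out
}

#' Built-in group-batch layouts
#'
#' \code{unbalanced_design()} reproduces the layout of the bladder-cancer
#' study used for benchmarking: five batches with case/control counts 11/0,
#' 14/4, 0/4, 0/5, 15/4 (n = 57), highly unbalanced with respect to group and
#' batch. \code{balanced_design()} distributes cases and controls evenly:
#' 6/6, 9/9, 2/2, 3/3, 10/10 (n = 60).
#'
#' @return a \code{group_batch_design} with groups \code{case}/\code{control}
#'   (control as reference) and batches \code{1..5}.
#' @export
unbalanced_design <- function() {
  layout_design(cases = c(11, 14, 0, 0, 15),
                controls = c(0, 4, 4, 5, 4))
}

#' @rdname unbalanced_design
#' @export
balanced_design <- function() {
  layout_design(cases = c(6, 9, 2, 3, 10),
                controls = c(6, 9, 2, 3, 10))
}

#' Design from per-batch case/control counts
#'
#' @param cases,controls integer vectors of per-batch sample counts (same
#'   length, the number of batches).
#' @return a \code{group_batch_design}.
#' @export
layout_design <- function(cases, controls) {
  stopifnot(length(cases) == length(controls))
  groups <- batches <- character(0)
  for (i in seq_along(cases)) {
    groups <- c(groups, rep("case", cases[i]), rep("control", controls[i]))
    batches <- c(batches, rep(as.character(i), cases[i] + controls[i]))
  }
  build_design(groups, batches, reference_group = "control")
}

#' Define a simulation scenario
#'
#' Collects the study conditions for one simulated dataset: the group-batch
#' layout, batch-effect levels, number of genes, and the set of true group
#' effects. Defaults match the benchmarking setup: 20 000 genes of which 2 000
#' are differentially expressed (500 each at effects 2, 1, -1, -2), background
#' expression 3 with gene-wise variation, and residual variances drawn from
#' Gamma(shape 4, rate 10) (mean 0.4).
#'
#' @param design a \code{group_batch_design}, or \code{"unbalanced"} /
#'   \code{"balanced"} for the built-in layouts.
#' @param mean_level,var_level batch-effect levels, see [table1_hyperparams()].
#'   Non-default layouts require explicit \code{hyper}.
#' @param n_genes number of genes.
#' @param de_spec two-column matrix-like of \code{(effect, count)} pairs. The
#'   default keeps the benchmark proportions (2.5\% of genes per effect tier,
#'   i.e. 500 each at 20 000 genes).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   scenario including the seed.
#' @param hyper optional hyperparameter table overriding
#'   [table1_hyperparams()] (needed for designs with a batch count other
#'   than 5); same columns.
#' @return list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(design = "unbalanced",
                         mean_level = "small", var_level = "small",
                         n_genes = 20000L,
                         de_spec = cbind(effect = c(2, 1, -1, -2),
                                         count = rep(max(1L, round(n_genes / 40)), 4L)),
                         seed = 1L, hyper = NULL) {
  if (is.character(design)) {
    design <- switch(match.arg(design, c("unbalanced", "balanced")),
                     unbalanced = unbalanced_design(),
                     balanced = balanced_design())
  }
  stopifnot(inherits(design, "group_batch_design"))
  de_spec <- as.matrix(de_spec)
  if (sum(de_spec[, 2L]) > n_genes) stop("DE gene counts exceed n_genes")
  if (is.null(hyper)) {
    if (design$B != 5L) {
      stop("built-in hyperparameters cover 5 batches; supply `hyper` for ",
           "other layouts")
    }
    hyper <- table1_hyperparams(mean_level, var_level)
  }
  stopifnot(nrow(hyper) == design$B)
  structure(list(design = design, mean_level = mean_level,
                 var_level = var_level, n_genes = as.integer(n_genes),
                 de_spec = de_spec, seed = as.integer(seed), hyper = hyper),
            class = "sim_scenario")
}

#' Simulate one expression dataset with and without batch effects
#'
#' Draws from the hierarchical location/scale model
#' \deqn{Y_{ijg} = \alpha_g + X_1\beta_g + \gamma_{ig} + \delta_{ig}
#'   \epsilon_{ijg}}
#' with \code{alpha_g = 3 + a_g} (gene-wise variation \code{a_g ~ N(0,
#' tau_g^2)}, \code{tau_g^2 ~ Gamma(4.5, rate 1.5)}), residual variances
#' \code{sigma_g^2 ~ Gamma(4, rate 10)}, batch means \code{gamma_ig ~ N(m_i,
#' v_i)} and batch scales \code{delta_ig ~ InvGamma(alpha_i, scale beta_i)}
#' per the scenario's hyperparameter table. The matched benchmark matrix
#' \code{Y_bench = alpha + X1 beta + eps} reuses the same biological and noise
#' draws with the batch terms removed.
#'
#' @param s a \code{sim_scenario}.
#' @return list of class \code{sim_dataset}: \code{Y}, \code{Y_bench} (genes x
#'   samples), \code{truth} (\code{data.frame} with \code{gene_id},
#'   \code{effect}, logical \code{is_de}), \code{gamma}, \code{delta} (B x G),
#'   \code{sigma2}, \code{scenario}.
#' @export
simulate_dataset <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  d <- s$design
  G <- s$n_genes
  n <- d$n
  B <- d$B
  set.seed(s$seed)

  effect <- numeric(G)
  k <- 0L
  for (r in seq_len(nrow(s$de_spec))) {
    cnt <- s$de_spec[r, 2L]
    effect[seq(k + 1L, k + cnt)] <- s$de_spec[r, 1L]
    k <- k + cnt
  }
  gene_ids <- sprintf("gene_%05d", seq_len(G))

  tau2 <- stats::rgamma(G, shape = 4.5, rate = 1.5)
  alpha_g <- 3 + stats::rnorm(G, sd = sqrt(tau2))
  sigma2 <- stats::rgamma(G, shape = 4, rate = 10)

  gamma <- matrix(0, B, G)
  delta <- matrix(1, B, G)
  for (i in seq_len(B)) {
    h <- s$hyper[i, ]
    if (h$v > 0 || h$m != 0) {
      gamma[i, ] <- stats::rnorm(G, mean = h$m, sd = sqrt(h$v))
    }
    if (!isTRUE(h$delta_fixed)) {
      delta[i, ] <- 1 / stats::rgamma(G, shape = h$alpha, rate = h$beta)
    }
  }

  eps <- matrix(stats::rnorm(G * n, sd = sqrt(sigma2)), G, n)
  x1 <- d$X1[, 2L]                                 # case indicator
  bio <- alpha_g + outer(effect, x1)               # G x n
  Y_bench <- bio + eps
  bi <- as.integer(d$batch)
  Y <- bio + t(gamma)[, bi] + t(delta)[, bi] * eps

  dimnames(Y) <- dimnames(Y_bench) <- list(gene_ids, d$sample_ids)
  truth <- data.frame(gene_id = gene_ids, effect = effect,
                      is_de = effect != 0, stringsAsFactors = FALSE)
  structure(list(Y = Y, Y_bench = Y_bench, truth = truth,
                 gamma = gamma, delta = delta, sigma2 = sigma2,
                 scenario = s),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("simulated dataset:", nrow(x$Y), "genes x", ncol(x$Y), "samples;",
      sum(x$truth$is_de), "DE genes; mean =", x$scenario$mean_level,
      "var =", x$scenario$var_level, "\n")
  invisible(x)
}

# deterministic per-replicate child seed from a base seed (kept < 2^31)
child_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) + 1000003 * (rep - 1)) %% 2147483647)
}

#' Run one DE method on a simulated dataset
#'
#' Dispatcher used by [run_replicates()] and the evaluation grid. Methods:
#' \describe{
#'   \item{ttest_raw}{equal-variance t-test on the uncorrected data}
#'   \item{benchmark}{OLS on the matched batch-free data (the ceiling)}
#'   \item{one_step}{OLS with batch covariates in the model}
#'   \item{combat_naive}{EB location/scale correction, then OLS ignoring the
#'     induced correlation}
#'   \item{combatcor}{the correlation-aware pipeline
#'     ([combatcor_pipeline()]) at noise fraction \code{zeta}}
#' }
#'
#' @param sim a \code{sim_dataset}.
#' @param method one of the tags above.
#' @param zeta noise fraction for \code{combatcor} (default 1\%).
#' @return DE table as in [ols_de()].
#' @export
run_method <- function(sim, method, zeta = 0.01) {
  stopifnot(inherits(sim, "sim_dataset"))
  d <- sim$scenario$design
  switch(method,
    ttest_raw = ttest_de(sim$Y, d),
    benchmark = ols_de(sim$Y_bench, d, include_batch = FALSE,
                       method = "benchmark"),
    one_step = ols_de(sim$Y, d, include_batch = TRUE),
    combat_naive = {
      fit <- combat_fit(sim$Y, d)
      Y_adj <- combat_adjust(fit, sim$Y)
      ols_de(Y_adj, d, include_batch = FALSE, method = "combat_naive")
    },
    combatcor = combatcor_pipeline(sim$Y, d, zeta = zeta),
    stop("unknown method tag: ", method)
  )
}

#' Seeded replicate stream of simulations and DE analyses
#'
#' Draws \code{n_reps} datasets from the scenario, with replicate \code{r}
#' simulated under the child seed \code{(seed + 1000003 * (r - 1)) mod
#' (2^31 - 1)}, and applies each requested method.
#'
#' @param s a \code{sim_scenario}; its \code{seed} is the base seed.
#' @param n_reps number of replicates.
#' @param methods character vector of method tags, see [run_method()].
#' @param zeta noise fraction used by \code{combatcor}.
#' @return list with one element per replicate, each a list with \code{sim}
#'   and \code{results} (named list of DE tables).
#' @export
run_replicates <- function(s, n_reps = 1L, methods = c("benchmark", "combatcor"),
                           zeta = 0.01) {
  stopifnot(inherits(s, "sim_scenario"))
  known <- c("ttest_raw", "benchmark", "one_step", "combat_naive", "combatcor")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method tag(s): ", paste(bad, collapse = ", "))
  lapply(seq_len(n_reps), function(r) {
    sr <- s
    sr$seed <- child_seed(s$seed, r)
    sim <- simulate_dataset(sr)
    results <- lapply(methods, function(m) run_method(sim, m, zeta = zeta))
    names(results) <- methods
    list(sim = sim, results = results)
  })
}
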