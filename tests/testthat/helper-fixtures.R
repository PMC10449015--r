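# shared fixtures: small scenarios built in code

# tiny scenario (a few hundred genes) on a chosen built-in layout
small_scenario <- function(design = "unbalanced", n_genes = 200L, seed = 101L,
                           mean_level = "small", var_level = "small") {
  sim_scenario(design = design, mean_level = mean_level, var_level = var_level,
               n_genes = n_genes,
               de_spec = cbind(effect = c(2, -1), count = c(15, 15)),
               seed = seed)
}

# random non-confounded design: every batch gets samples from both groups
random_design <- function(B, per_batch = 4L) {
  groups <- batches <- character(0)
  for (i in seq_len(B)) {
    k <- sample(seq_len(per_batch - 1L), 1L)
    groups <- c(groups, rep("case", k), rep("control", per_batch - k))
    batches <- c(batches, rep(as.character(i), per_batch))
  }
  build_design(groups, batches, reference_group = "control")
}
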