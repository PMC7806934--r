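# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# AUC as the concordance probability over all case-control pairs
# (ties count 1/2).
concordance_auc <- function(scores, labels) {
  cs <- scores[labels]; ns <- scores[!labels]
  tot <- 0
  for (a in cs) for (b in ns)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ns))
}

# Two-sided Fisher exact p by exhaustive enumeration over the
# hypergeometric support of a 2x2 table (a b / c d), summing the
# probabilities of all tables no more likely than the observed one.
fisher_enum_p <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Posterior probability in plain probability form (no odds-space path).
posterior_prob_form <- function(prev, sens, spec, result) {
  if (result == "positive")
    sens * prev / (sens * prev + (1 - spec) * (1 - prev))
  else
    (1 - sens) * prev / ((1 - sens) * prev + spec * (1 - prev))
}

# One noiseless field config with constant grey values so every planted
# blob is analytically known and inside all filter ranges. Any
# image_sim_config() argument can be overridden through `...`.
clean_field_config <- function(..., grey = 200) {
  defaults <- list(
    n_cells = 40, positive_fraction = 0.4, seed = 1,
    radius_range_um = c(5, 10),
    intensity_law_red = intensity_law("constant", value = grey),
    intensity_law_green = intensity_law("constant", value = grey),
    intensity_law_blue = intensity_law("constant", value = grey),
    background_noise_sd = 0)
  do.call(image_sim_config, utils::modifyList(defaults, list(...)))
}

# Build a per-gene call table directly (for small intersection instances).
make_calls <- function(genes, direction) {
  data.frame(gene = genes, mean_case = 0, mean_control = 0,
             t_statistic = 0, p_value = 0, direction = direction)
}
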