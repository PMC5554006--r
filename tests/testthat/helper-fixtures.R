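# Shared fixtures, all generated in code under fixed seeds.

# small genotype panel + map for unit tests
small_sim <- function(n = 60, m = 300, seed = 101, ...) {
  simulate_genotypes(n, m, seed = seed, ...)
}

# balanced plot-level records drawn from the fully random model
# value = genotype + experiment + genotype:experiment + error
vc_records <- function(V_G, V_GE, V_e, n_gen = 100, O = 3, R = 5, seed = 1,
                       trait = "y") {
  set.seed(seed)
  gen <- sprintf("G%03d", seq_len(n_gen))
  exps <- paste0("E", seq_len(O))
  g <- stats::setNames(rnorm(n_gen, 0, sqrt(V_G)), gen)
  ge <- matrix(rnorm(n_gen * O, 0, sqrt(V_GE)), n_gen, O,
               dimnames = list(gen, exps))
  e_eff <- stats::setNames(rnorm(O, 0, 1), exps)
  df <- tidyr::expand_grid(genotype = gen, experiment = exps,
                           replicate = seq_len(R))
  df$day <- 1
  df$trait <- trait
  df$value <- g[df$genotype] + e_eff[df$experiment] +
    ge[cbind(match(df$genotype, gen), match(df$experiment, exps))] +
    rnorm(nrow(df), 0, sqrt(V_e))
  df
}

# stacked per-experiment BLUEs with one additive marker effect and an
# optional kinship-distributed polygenic background
marker_blues <- function(panel, marker_idx, beta, K = NULL, sigma_g = 0,
                         sigma_e = 1, n_experiments = 3, seed = 1) {
  set.seed(seed)
  gids <- panel$genotype_ids
  n <- length(gids)
  x <- panel$calls[, marker_idx]
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  u <- if (sigma_g > 0) {
    L <- t(chol(2 * K$K + diag(1e-6, n)))
    sigma_g * drop(L %*% rnorm(n)) / sqrt(2)
  } else rep(0, n)
  exps <- paste0("E", seq_len(n_experiments))
  bl <- tidyr::expand_grid(genotype = gids, experiment = exps)
  e_eff <- stats::setNames(rnorm(n_experiments, 0, 0.3), exps)
  bl$blue <- beta * x[match(bl$genotype, gids)] + u[match(bl$genotype, gids)] +
    e_eff[bl$experiment] + rnorm(nrow(bl), 0, sigma_e)
  bl
}
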