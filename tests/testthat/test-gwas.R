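test_that("marker filter applies strict MAF and missingness thresholds", {
  calls <- cbind(
    m1 = c(rep(0, 19), 1),                     # MAF 0.05 exactly
    m2 = c(rep(0, 17), 1, 1, 1),               # MAF 0.15
    m3 = c(rep(0, 19), NA),                    # MAF 0, 5% missing
    m4 = c(rep(c(0, 1), 10)),                  # MAF 0.5
    m5 = c(rep(NA, 2), rep(c(0, 1), 9))        # 10% missing
  )
  rownames(calls) <- sprintf("G%02d", 1:20)
  panel <- genotype_panel(calls)
  kept <- filter_markers(panel, maf_min = 0.05, missing_max = 0.05)
  expect_identical(kept$marker_ids, c("m2", "m4"))

  # no-op bounds keep every polymorphic marker (m3 is monomorphic)
  all_kept <- filter_markers(panel, maf_min = 0, missing_max = 1)
  expect_identical(all_kept$marker_ids, c("m1", "m2", "m4", "m5"))
  expect_error(filter_markers(panel, maf_min = 0.5, missing_max = 1),
               "no markers")
})

test_that("kinship matches the naive double-loop oracle", {
  sim <- small_sim(n = 25, m = 80, seed = 31, missing_rate = 0.03)
  K <- compute_kinship(sim$panel)
  X <- sim$panel$calls
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  W <- scale(X)
  m <- ncol(W)
  K_naive <- matrix(0, nrow(W), nrow(W))
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W))) {
    K_naive[i, j] <- sum(W[i, ] * W[j, ]) / m
  }
  expect_equal(unname(K$K), K_naive, tolerance = 1e-10)
})

test_that("kinship of duplicated genotypes and large panels behaves", {
  sim <- small_sim(n = 20, m = 100, seed = 7)
  calls <- sim$panel$calls
  calls[2, ] <- calls[1, ]  # make genotype 2 a copy of genotype 1
  K <- compute_kinship(genotype_panel(calls))
  expect_equal(K$K[1, 2], K$K[1, 1], tolerance = 1e-10)
  expect_equal(K$K[1, 2], K$K[2, 2], tolerance = 1e-10)

  big <- simulate_genotypes(99, 1000, ld_block_size = 1, seed = 13)
  Kb <- compute_kinship(big$panel)
  expect_equal(mean(diag(Kb$K)), 1, tolerance = 0.05)
  expect_equal(Kb$K, t(Kb$K), tolerance = 1e-12)
  ev <- eigen(Kb$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("scan with zero genetic variance equals the OLS F-test", {
  sim <- small_sim(n = 50, m = 120, seed = 17)
  K <- compute_kinship(sim$panel)
  bl <- marker_blues(sim$panel, 5, beta = 0.8, sigma_e = 1, seed = 3)
  sc <- scan_trait(bl, sim$panel, K, fix_lambda = 0)

  X <- sim$panel$calls
  for (m in sample(sc$marker_id, 20)) {
    x <- X[bl$genotype, m]
    fit <- lm(bl$blue ~ factor(bl$experiment) + x)
    p_ols <- anova(fit)["x", "Pr(>F)"]
    expect_equal(sc$p_value[sc$marker_id == m], p_ols, tolerance = 1e-6)
  }
})

test_that("a strong planted QTL is the top hit in most scans", {
  sim <- simulate_genotypes(99, 500, seed = 23)
  panel <- filter_markers(sim$panel)
  K <- compute_kinship(panel)
  top <- vapply(1:50, function(s) {
    bl <- marker_blues(panel, 50, beta = 0, K = K, sigma_g = 0.8,
                       sigma_e = 0.5, seed = s)
    # beta calibrated to ~25% of phenotypic line variance
    x <- panel$calls[, 50]
    vx <- var(x)
    tot <- 0.8^2 + 0.5^2 / 3
    beta <- sqrt(0.25 * tot / (0.75 * vx))
    bl$blue <- bl$blue + beta * x[match(bl$genotype, panel$genotype_ids)]
    sc <- scan_trait(bl, panel, K)
    sc$marker_id[which.min(sc$p_value)]
  }, "")
  # count hits on the causal marker or its immediate LD neighbours
  idx <- match(top, panel$marker_ids)
  expect_gte(mean(abs(idx - 50) <= 3), 0.9)
})

test_that("scan p-values are invariant to allele swap and experiment labels", {
  sim <- small_sim(n = 40, m = 60, seed = 19)
  K <- compute_kinship(sim$panel)
  bl <- marker_blues(sim$panel, 7, beta = 0.5, K = K, sigma_g = 0.4, seed = 5)
  sc1 <- scan_trait(bl, sim$panel, K)

  swapped <- sim$panel$calls
  swapped[, 7] <- 1 - swapped[, 7]
  sc2 <- scan_trait(bl, genotype_panel(swapped), K)
  expect_equal(sc2$neg_log10_p, sc1$neg_log10_p, tolerance = 1e-6)
  expect_equal(sc2$effect[7], -sc1$effect[7], tolerance = 1e-8)

  relab <- bl
  relab$experiment <- c(E1 = "EB", E2 = "EC", E3 = "EA")[relab$experiment]
  sc3 <- scan_trait(relab, sim$panel, K)
  expect_equal(sc3$neg_log10_p, sc1$neg_log10_p, tolerance = 1e-6)
})

test_that("P3D reuse and per-marker REML agree on null data", {
  sim <- small_sim(n = 99, m = 150, seed = 29)
  K <- compute_kinship(sim$panel)
  bl <- marker_blues(sim$panel, 1, beta = 0, K = K, sigma_g = 1,
                     sigma_e = 0.6, seed = 4)
  p3d <- scan_trait(bl, sim$panel, K, mode = "null_varcomp_reuse")
  full <- scan_trait(bl, sim$panel, K, mode = "full_reml_per_marker")
  common <- p3d$maf > 0.1
  expect_lt(max(abs(p3d$neg_log10_p[common] - full$neg_log10_p[common])), 0.2)
})

test_that("Benjamini-Hochberg flags match the step-up rule", {
  tests <- tibble::tibble(marker_id = c("a", "b", "c"), trait = "t", day = 1,
                          p_value = c(0.001, 0.02, 0.8))
  out <- apply_fdr(tests, q = 0.1)
  expect_identical(out$significant, c(TRUE, TRUE, FALSE))

  all_one <- tibble::tibble(marker_id = letters[1:4], trait = "t", day = 1,
                            p_value = rep(1, 4))
  expect_false(any(apply_fdr(all_one, 0.1)$significant))

  empty <- tibble::tibble(marker_id = character(), p_value = numeric())
  expect_equal(nrow(apply_fdr(empty, 0.1)), 0)
})

test_that("variance explained uses adjusted R2 standardized by heritability", {
  sim <- small_sim(n = 40, m = 50, seed = 37)
  panel <- sim$panel
  x <- panel$calls[, 3]
  bl <- tibble::tibble(genotype = panel$genotype_ids, blue = x)
  ve <- suppressWarnings(
    variance_explained(bl, panel, panel$marker_ids[3], h2 = 1)
  )
  expect_equal(ve$individual$var_explained, 1)

  set.seed(9)
  bl2 <- tibble::tibble(genotype = panel$genotype_ids,
                        blue = 0.7 * x + rnorm(40))
  mk <- panel$marker_ids[c(3, 10, 20)]
  ve2 <- variance_explained(bl2, panel, mk, h2 = 0.8)
  n <- 40
  for (j in seq_along(mk)) {
    r2 <- summary(lm(bl2$blue ~ panel$calls[, mk[j]]))$r.squared
    adj <- 1 - (1 - r2) * (n - 1) / (n - 1 - 1)
    expect_equal(ve2$individual$adj_r2[j], adj, tolerance = 1e-10)
  }
  r2j <- summary(lm(bl2$blue ~ panel$calls[, mk]))$r.squared
  adjj <- 1 - (1 - r2j) * (n - 1) / (n - 3 - 1)
  expect_equal(ve2$combined_adj_r2, adjj, tolerance = 1e-10)

  # nesting: joint (unadjusted) R2 >= best single-marker R2
  best <- max(vapply(mk, function(m) {
    summary(lm(bl2$blue ~ panel$calls[, m]))$r.squared
  }, 0))
  expect_gte(r2j, best)

  expect_error(variance_explained(bl2, panel, panel$marker_ids[1:39], 0.8),
               "rank")
})

test_that("trajectory assembly keeps hits and labels constructed patterns", {
  mk_scan <- function(marker, nlp, sig) {
    tibble::tibble(marker_id = marker, day = seq_along(nlp),
                   neg_log10_p = nlp, significant = sig)
  }
  scans <- dplyr::bind_rows(
    mk_scan("up", c(0.2, 0.5, 1.0, 2.0, 3.0, 4.0),
            c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)),
    mk_scan("down", c(4.0, 3.0, 2.0, 1.0, 0.5, 0.2),
            c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    mk_scan("peak", c(0.5, 1.5, 4.0, 4.2, 1.5, 0.4),
            c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)),
    mk_scan("never", c(0.1, 0.2, 0.1, 0.2, 0.1, 0.2), rep(FALSE, 6))
  )
  traj <- qtl_trajectories(scans)
  expect_setequal(traj$marker_id, c("up", "down", "peak"))
  expect_equal(traj$pattern[traj$marker_id == "up"], "increasing")
  expect_equal(traj$pattern[traj$marker_id == "down"], "decreasing")
  expect_equal(traj$pattern[traj$marker_id == "peak"], "peaked")
  expect_equal(traj$peak_day[traj$marker_id == "peak"], 4)
  expect_error(qtl_trajectories(scans[scans$day < 3, ]), "3 days")
})
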