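test_that("outlier screen flags under 1% of clean Gaussian data", {
  rates <- vapply(1:100, function(s) {
    set.seed(s)
    df <- tidyr::expand_grid(genotype = sprintf("G%02d", 1:30),
                             experiment = paste0("E", 1:3),
                             replicate = 1:5)
    df$day <- 20; df$trait <- "digital_biomass"
    df$value <- rnorm(nrow(df), 100, 10)
    mean(detect_outliers(df, threshold_sd = 3.5)$outlier)
  }, 0)
  expect_lt(mean(rates), 0.01)
})

test_that("a gross error is flagged and clean values are not deleted", {
  set.seed(2)
  df <- tidyr::expand_grid(genotype = sprintf("G%02d", 1:20),
                           experiment = "E1", replicate = 1:5)
  df$day <- 20; df$trait <- "digital_biomass"
  df$value <- rnorm(nrow(df), 100, 5)
  sd_grp <- sd(df$value)
  df$value[7] <- df$value[7] + 10 * sd_grp
  out <- detect_outliers(df, threshold_sd = 3.5)
  hit <- out[out$genotype == df$genotype[7] & out$replicate == df$replicate[7], ]
  expect_true(hit$outlier)
  expect_equal(nrow(out), nrow(df))  # flagged, not deleted
})

test_that("outlier screen is silent on zero-dispersion and tiny groups", {
  df <- tidyr::expand_grid(genotype = sprintf("G%02d", 1:10),
                           experiment = "E1", replicate = 1:5)
  df$day <- 1; df$trait <- "t"; df$value <- 42
  expect_equal(sum(detect_outliers(df)$outlier), 0)
  tiny <- df[1:3, ]
  expect_warning(out <- detect_outliers(tiny), "skipped")
  expect_equal(sum(out$outlier), 0)
})

test_that("step-1 BLUEs are replicate means and match the OLS solver", {
  df <- tibble::tibble(genotype = "A", experiment = "E1", replicate = 1:3,
                       day = 5, trait = "t", value = c(2, 4, 6))
  expect_equal(compute_blues_step1(df)$blue, 4)

  df5 <- tibble::tibble(genotype = "A", experiment = "E1", replicate = 1:5,
                        day = 5, trait = "t", value = c(1, 2, 3, 4, 100),
                        outlier = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(compute_blues_step1(df5)$blue, 2.5)

  set.seed(3)
  many <- tidyr::expand_grid(genotype = sprintf("G%02d", 1:15),
                             experiment = "E1", replicate = 1:4)
  many$day <- 1; many$trait <- "t"; many$value <- rnorm(nrow(many), 50, 8)
  b1 <- compute_blues_step1(many)
  fit <- lm(value ~ 0 + genotype, data = many)
  expect_equal(b1$blue[match(sprintf("genotype%s", b1$genotype),
                             names(coef(fit)))],
               unname(coef(fit)), tolerance = 1e-10)
})

test_that("step-2 BLUEs reduce to means on balanced data", {
  s1 <- tibble::tibble(trait = "t", day = 1, experiment = paste0("E", 1:3),
                       genotype = "A", blue = c(10, 12, 14), n_obs = 5)
  expect_equal(compute_blues_step2(s1)$blue, 12)
})

test_that("step-2 with zero experiment variance equals plain OLS", {
  set.seed(1)
  gen <- sprintf("G%02d", 1:12)
  s1 <- tidyr::expand_grid(trait = "t", day = 1, experiment = paste0("E", 1:3),
                           genotype = gen)
  mu <- stats::setNames(rnorm(12, 100, 10), gen)
  # no experiment effect at all, unbalanced to force the GLS path
  s1$blue <- mu[s1$genotype] + rnorm(nrow(s1), 0, 1)
  s1 <- s1[-1, ]
  b2 <- compute_blues_step2(s1)
  ols <- coef(lm(blue ~ 0 + genotype, data = s1))
  expect_equal(b2$blue, unname(ols[paste0("genotype", b2$genotype)]),
               tolerance = 1e-6)
})

test_that("unbalanced step-2 BLUEs match a brute-force GLS oracle", {
  set.seed(5)
  gen <- c("A", "B", "C")
  s1 <- tidyr::expand_grid(trait = "t", day = 1, experiment = paste0("E", 1:3),
                           genotype = gen)
  eff <- c(E1 = -2, E2 = 0, E3 = 2)
  mu <- c(A = 10, B = 20, C = 30)
  s1$blue <- mu[s1$genotype] + eff[s1$experiment] + rnorm(nrow(s1), 0, 0.5)
  s1 <- s1[-4, ]  # drop one cell
  b2 <- compute_blues_step2(s1)

  # oracle: GLS with V built from the REML variance components of the
  # same random-experiment model
  fit <- lme4::lmer(blue ~ 0 + genotype + (1 | experiment), data = s1)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_exp <- vc$vcov[vc$grp == "experiment"]
  s2_res <- vc$vcov[vc$grp == "Residual"]
  Zb <- model.matrix(~ 0 + experiment, data = s1)
  V <- Zb %*% t(Zb) * s2_exp + diag(s2_res, nrow(s1))
  X <- model.matrix(~ 0 + genotype, data = s1)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% s1$blue)
  expect_equal(b2$blue, unname(beta[paste0("genotype", b2$genotype), 1]),
               tolerance = 1e-6)
})

test_that("balanced REML variance components equal ANOVA estimators", {
  df <- vc_records(V_G = 4, V_GE = 1, V_e = 2, n_gen = 25, O = 3, R = 4,
                   seed = 10)
  vc <- estimate_variance_components(df, "y", day = 1)

  # expected-mean-squares oracle on the balanced two-way layout
  O <- 3; R <- 4
  fit <- aov(value ~ genotype * experiment, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  v_e <- ms[["Residuals"]]
  v_ge <- (ms[["genotype:experiment"]] - v_e) / R
  v_g <- (ms[["genotype"]] - ms[["genotype:experiment"]]) / (O * R)
  expect_equal(vc$V_e, v_e, tolerance = 1e-6)
  expect_equal(vc$V_GE, v_ge, tolerance = 1e-6)
  expect_equal(vc$V_G, v_g, tolerance = 1e-6)
})

test_that("variance components are recovered across seeds and a grid", {
  grid <- list(c(4, 1, 2), c(1, 1, 1))
  for (tv in grid) {
    est <- vapply(1:30, function(s) {
      df <- vc_records(tv[1], tv[2], tv[3], n_gen = 60, O = 3, R = 5, seed = s)
      vc <- estimate_variance_components(df, "y", day = 1)
      c(vc$V_G, vc$V_GE, vc$V_e)
    }, numeric(3))
    m <- rowMeans(est)
    expect_equal(m[1], tv[1], tolerance = 0.1 * tv[1] + 0.05)
    expect_equal(m[2], tv[2], tolerance = 0.1 * tv[2] + 0.05)
    expect_equal(m[3], tv[3], tolerance = 0.1 * tv[3] + 0.05)
  }
})

test_that("pure-noise data gives a near-zero genotypic variance", {
  df <- vc_records(V_G = 0, V_GE = 0, V_e = 4, n_gen = 50, O = 3, R = 5,
                   seed = 77)
  vc <- estimate_variance_components(df, "y", day = 1)
  expect_lt(vc$V_G, 0.05 * vc$V_e)
})

test_that("broad-sense heritability evaluates the formula exactly", {
  h <- function(vg, vge, ve, O = 3, R = 5) {
    broad_sense_heritability(list(V_G = vg, V_GE = vge, V_e = ve,
                                  O = O, R = R, trait = "t", day = 1))$H2
  }
  expect_equal(h(1, 0, 0), 1)
  expect_equal(h(1, 3, 15), 1 / 3)
  expect_equal(h(0, 1, 1), 0)
  expect_error(h(0, 0, 0), "undefined")
  expect_error(broad_sense_heritability(list(V_G = -1, V_GE = 0, V_e = 1,
                                             O = 3, R = 5)),
               "non-negative")
})

test_that("heritability is bounded and monotone in V_G", {
  vg_grid <- seq(0, 10, by = 0.5)
  h2 <- vapply(vg_grid, function(vg) {
    broad_sense_heritability(list(V_G = vg, V_GE = 2, V_e = 3, O = 3, R = 5,
                                  trait = "t", day = 1))$H2
  }, 0)
  expect_true(all(h2 >= 0 & h2 <= 1))
  expect_true(all(diff(h2) > 0))
})

test_that("two-step BLUEs conserve grand genotype means on balanced data", {
  df <- vc_records(V_G = 2, V_GE = 0.5, V_e = 1, n_gen = 20, O = 3, R = 4,
                   seed = 21)
  s2 <- compute_blues_step2(compute_blues_step1(df))
  grand <- tapply(df$value, df$genotype, mean)
  expect_equal(s2$blue, as.numeric(grand[s2$genotype]), tolerance = 1e-10)
})

test_that("Kendall matrix matches a brute-force pair-count oracle", {
  set.seed(6)
  blues <- tidyr::expand_grid(genotype = sprintf("G%d", 1:6), day = c(1, 2, 3))
  blues$blue <- rnorm(nrow(blues))
  tau <- kendall_correlation_matrix(blues)
  expect_equal(unname(diag(tau)), rep(1, 3))
  expect_equal(tau, t(tau))
  expect_true(all(tau >= -1 & tau <= 1))

  brute_tau <- function(x, y) {
    s <- 0; n <- length(x)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
    s / (n * (n - 1) / 2)
  }
  wide <- tidyr::pivot_wider(blues, names_from = day, values_from = blue)
  expect_equal(tau["1", "3"], brute_tau(wide$`1`, wide$`3`), tolerance = 1e-12)

  # antitone ranking gives -1
  rev_blues <- tibble::tibble(
    genotype = rep(sprintf("G%d", 1:6), 2),
    day = rep(c(1, 2), each = 6),
    blue = c(1:6, 6:1)
  )
  expect_equal(kendall_correlation_matrix(rev_blues)["1", "2"], -1)
})

test_that("entries with too few shared genotypes are missing", {
  blues <- tibble::tibble(
    genotype = c("A", "B", "C", "A", "B"),
    day = c(1, 1, 1, 2, 2),
    blue = c(1, 2, 3, 2, 1)
  )
  tau <- kendall_correlation_matrix(blues, min_shared = 3)
  expect_true(is.na(tau["1", "2"]))
  expect_equal(tau["1", "1"], 1)
})

test_that("trait correlation matches the textbook formula and edge cases", {
  a <- tibble::tibble(genotype = sprintf("G%d", 1:5), blue = c(1, 2, 4, 7, 11))
  b <- tibble::tibble(genotype = sprintf("G%d", 1:5), blue = 2 * a$blue + 1)
  expect_equal(correlate_traits(a, b)$r, 1, tolerance = 1e-12)

  set.seed(8)
  b2 <- tibble::tibble(genotype = a$genotype, blue = c(3, 1, 4, 1, 5))
  res <- correlate_traits(a, b2)
  x <- a$blue; y <- b2$blue
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)

  const <- tibble::tibble(genotype = a$genotype, blue = rep(1, 5))
  expect_error(correlate_traits(a, const), "zero variance")
  expect_error(correlate_traits(a[1:2, ], b[1:2, ]), "shared genotypes")
})

test_that("independent traits rarely show |r| above 0.25 at n = 99", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    a <- tibble::tibble(genotype = sprintf("G%03d", 1:99), blue = rnorm(99))
    b <- tibble::tibble(genotype = sprintf("G%03d", 1:99), blue = rnorm(99))
    abs(correlate_traits(a, b)$r) < 0.25
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
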