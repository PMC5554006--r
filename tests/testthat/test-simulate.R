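test_that("genotype simulation is deterministic under a fixed seed", {
  a <- simulate_genotypes(30, 100, seed = 1)
  b <- simulate_genotypes(30, 100, seed = 1)
  expect_identical(a$panel$calls, b$panel$calls)
  expect_identical(a$map, b$map)
  c <- simulate_genotypes(30, 100, seed = 2)
  expect_false(identical(a$panel$calls, c$panel$calls))
})

test_that("panel respects MAF bounds, inbred coding and map invariants", {
  sim <- simulate_genotypes(99, 1000, maf_low = 0.05, seed = 7)
  expect_true(all(sim$panel$calls %in% c(0, 1)))
  st <- marker_stats(sim$panel)
  expect_true(all(st$maf >= 0.025))            # resampling floor maf_low/2
  expect_true(all(st$maf <= 0.5))
  expect_setequal(unique(sim$map$chromosome), paste0(1:7, "H"))
  expect_false(any(duplicated(sim$map$marker_id)))
  expect_true(all(sim$map$position_cM >= 0 & is.finite(sim$map$position_cM)))
})

test_that("study-scale panel passes the published MAF filter", {
  sim <- simulate_genotypes(99, 4866, maf_low = 0.05, seed = 3)
  filtered <- filter_markers(sim$panel, maf_min = 0.05, missing_max = 0.05)
  st <- marker_stats(filtered)
  expect_true(all(st$maf > 0.05))
  # nearly all simulated markers survive: the generator targets MAF > 0.05
  expect_gt(ncol(filtered$calls), 0.95 * 4866)
})

test_that("ld_block_size = 1 gives independent adjacent markers", {
  sim <- simulate_genotypes(99, 1000, ld_block_size = 1, seed = 5)
  x <- sim$panel$calls
  r <- vapply(seq_len(ncol(x) - 1),
              function(j) suppressWarnings(cor(x[, j], x[, j + 1])), 0)
  r <- r[!is.na(r)]
  expect_lt(abs(mean(r)), 0.02)
  # E|r| under independence is sqrt(2/(pi*n)) ~ 0.08 for n = 99
  expect_lt(mean(abs(r)), 0.12)
  # and blocked markers are clearly correlated by contrast
  sim2 <- simulate_genotypes(99, 1000, ld_block_size = 10, seed = 5)
  x2 <- sim2$panel$calls
  r2 <- vapply(seq_len(ncol(x2) - 1),
               function(j) suppressWarnings(cor(x2[, j], x2[, j + 1])), 0)
  expect_gt(mean(abs(r2), na.rm = TRUE), 0.4)
})

test_that("invalid simulation requests are rejected", {
  expect_error(simulate_genotypes(10, 3, n_chromosomes = 7), "n_chromosomes")
  expect_error(simulate_genotypes(10, 100, maf_low = 0.4, maf_high = 0.2),
               "maf_low")
  expect_error(simulate_genotypes(10, 100, maf_low = 0, maf_high = 0.5),
               "maf_low")
})

test_that("noise-free phenotypes with zero CVs are exactly logistic and identical", {
  sim <- small_sim(n = 12, m = 50)
  ph <- simulate_growth_phenotypes(
    sim$panel,
    base_params = list(a = 50, b = 320, c = 0.18, cv_a = 0, cv_b = 0, cv_c = 0),
    gxe_sd = 0, experiment_sd = 0, outlier_rate = 0,
    h2_schedule = c("10" = 0.5), days = 10:30, seed = 9
  )
  db <- ph[ph$trait == "digital_biomass", ]
  expected <- 50 / (1 + 320 * exp(-0.18 * db$day))
  expect_equal(db$value, expected, tolerance = 1e-12)
  one <- db[db$genotype == db$genotype[1] & db$experiment == "E1" &
              db$replicate == 1, ]
  for (g in unique(db$genotype)) {
    series <- db[db$genotype == g & db$experiment == "E2" & db$replicate == 3, ]
    expect_equal(series$value, one$value, tolerance = 1e-12)
  }
})

test_that("planted QTL effects hit their variance fraction on latent values", {
  sim <- small_sim(n = 99, m = 200, seed = 42)
  r2 <- vapply(1:50, function(s) {
    ph <- simulate_growth_phenotypes(
      sim$panel, qtl = list(qtl_spec("M0010", "a", 0.15)),
      days = c(10, 30), seed = s
    )
    lat <- attr(ph, "latent_params")
    x <- sim$panel$calls[, "M0010"]
    summary(lm(log(lat$a) ~ x))$r.squared
  }, 0)
  expect_lt(abs(mean(r2) - 0.15), 0.03)
})

test_that("heritability targets propagate to downstream REML estimates", {
  sim <- small_sim(n = 99, m = 150, seed = 11)
  h2_hat <- sapply(1:3, function(s) {
    ph <- simulate_growth_phenotypes(
      sim$panel, h2_schedule = c("10" = 0.62, "54" = 0.91),
      days = c(10, 54), seed = 100 + s
    )
    h <- heritability_by_day(ph, "digital_biomass", days = c(10, 54))
    h$H2
  })
  expect_lt(abs(mean(h2_hat[1, ]) - 0.62), 0.07)
  expect_lt(abs(mean(h2_hat[2, ]) - 0.91), 0.07)
})

test_that("noise-free growth curves are non-decreasing for b, c > 0", {
  sim <- small_sim(n = 20, m = 60, seed = 8)
  ph <- simulate_growth_phenotypes(sim$panel, gxe_sd = 0, experiment_sd = 0,
                                   outlier_rate = 0,
                                   h2_schedule = c("10" = 0.9),
                                   days = 10:40, seed = 2)
  g <- attr(ph, "genetic_values")
  expect_true(all(diff(t(g)) >= -1e-12))
})

test_that("unknown QTL markers and invalid schedules are rejected", {
  sim <- small_sim(n = 15, m = 40)
  expect_error(
    simulate_growth_phenotypes(sim$panel, qtl = list(qtl_spec("nope", "a", 0.1)),
                               days = 10:20, seed = 1),
    "not present"
  )
  expect_error(
    simulate_growth_phenotypes(sim$panel, h2_schedule = c("10" = 1),
                               days = 10:20, seed = 1),
    "h2_schedule"
  )
  expect_error(
    simulate_growth_phenotypes(
      sim$panel, qtl = list(qtl_spec("M0001", "a", 0.7),
                            qtl_spec("M0002", "a", 0.6)),
      days = 10:20, seed = 1),
    "sum"
  )
})

test_that("phenotype records have at most one value per design cell", {
  sim <- small_sim(n = 10, m = 30)
  ph <- simulate_growth_phenotypes(sim$panel, days = 10:15, seed = 4)
  key <- ph[, c("genotype", "experiment", "replicate", "day", "trait")]
  expect_false(any(duplicated(key)))
  expect_true(all(ph$value[ph$trait == "digital_biomass"] >= 0))
})

test_that("day masking drops the masked biomass days only", {
  sim <- small_sim(n = 10, m = 30)
  ph <- simulate_growth_phenotypes(sim$panel, days = 10:20,
                                   mask_days = c(12, 13), seed = 4)
  db_days <- unique(ph$day[ph$trait == "digital_biomass"])
  expect_false(any(c(12, 13) %in% db_days))
  expect_true(all(setdiff(10:20, c(12, 13)) %in% db_days))
})
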