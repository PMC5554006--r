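#' Specify a planted QTL for phenotype simulation
#'
#' Describes a causal marker acting on one logistic growth parameter (or an
#' endpoint trait), the window of days over which its effect is expressed,
#' and the share of genetic variance it should explain.
#'
#' Effects are additive on the log scale of the targeted parameter so that
#' parameters stay positive. The effect size is calibrated against the
#' realized marker variance in the panel so that the marker explains
#' `variance_fraction` of the latent genetic variance of the target.
#'
#' @param marker_id Causal marker identifier (must exist in the panel).
#' @param target_parameter One of `"a"` (asymptote), `"b"` (shape),
#'   `"c"` (rate), or an endpoint trait name (`"fresh_weight"`,
#'   `"tipping_time"`, `"tiller_number"`).
#' @param variance_fraction Intended share of genetic variance in \[0, 1\].
#' @param effect_window Length-2 numeric `(start_day, end_day)` over which
#'   the effect is expressed in the growth curve; `NULL` means the whole
#'   observation window.
#' @return A list of class `qtl_spec`.
#' @export
qtl_spec <- function(marker_id, target_parameter = "a", variance_fraction = 0.1,
                     effect_window = NULL) {
  stopifnot(length(marker_id) == 1, variance_fraction >= 0, variance_fraction <= 1)
  target_parameter <- match.arg(
    target_parameter,
    c("a", "b", "c", "fresh_weight", "tipping_time", "tiller_number")
  )
  if (!is.null(effect_window)) {
    stopifnot(length(effect_window) == 2, effect_window[1] <= effect_window[2])
  }
  structure(
    list(marker_id = as.character(marker_id), target_parameter = target_parameter,
         variance_fraction = variance_fraction, effect_window = effect_window),
    class = "qtl_spec"
  )
}

#' Simulate an inbred biallelic genotype panel with block-structured LD
#'
#' Markers are laid out chromosome by chromosome at positions drawn
#' uniformly and sorted. Consecutive markers form haplotype blocks: the
#' first marker of a block is drawn independently with an allele frequency
#' sampled between `maf_low` and `maf_high`, and each subsequent marker in
#' the block copies its predecessor with a per-genotype flip probability
#' `mutation_rate`. This yields squared correlations that decay with
#' genetic distance without requiring a coalescent model. Markers whose
#' realized minor allele frequency falls below `maf_low / 2` (including
#' monomorphic markers) are redrawn independently.
#'
#' @param n_genotypes,n_markers Panel dimensions.
#' @param maf_low,maf_high Bounds for the sampled allele frequency,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param n_chromosomes Number of chromosomes (labelled `"1H"`, `"2H"`, ...).
#' @param chrom_length_cM Genetic length of each chromosome in centimorgan.
#' @param ld_block_size Number of consecutive markers per haplotype block;
#'   `1` gives independent markers.
#' @param mutation_rate Per-marker, per-genotype allele flip probability
#'   within a block.
#' @param missing_rate Fraction of calls masked to `NA` at random.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list with elements `panel` (a [genotype_panel()]) and
#'   `map` (a [genetic_map()] tibble).
#' @export
simulate_genotypes <- function(n_genotypes, n_markers,
                               maf_low = 0.05, maf_high = 0.5,
                               n_chromosomes = 7, chrom_length_cM = 150,
                               ld_block_size = 20, mutation_rate = 0.06,
                               missing_rate = 0, seed = NULL) {
  if (n_markers < n_chromosomes) {
    stop("n_markers must be at least n_chromosomes", call. = FALSE)
  }
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  }
  stopifnot(n_genotypes > 0, ld_block_size >= 1)
  if (!is.null(seed)) set.seed(seed)

  per_chrom <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
  chrom_labels <- paste0(seq_len(n_chromosomes), "H")

  draw_marker <- function() {
    p <- stats::runif(1, maf_low, maf_high)
    stats::rbinom(n_genotypes, 1, p)
  }

  calls <- matrix(NA_real_, n_genotypes, n_markers)
  chrom <- character(n_markers)
  pos <- numeric(n_markers)
  idx <- 0L
  for (ch in seq_len(n_chromosomes)) {
    m <- per_chrom[ch]
    if (m == 0L) next
    positions <- sort(stats::runif(m, 0, chrom_length_cM))
    block_pos <- 0L
    for (j in seq_len(m)) {
      idx <- idx + 1L
      if (block_pos == 0L || block_pos >= ld_block_size) {
        calls[, idx] <- draw_marker()
        block_pos <- 1L
      } else {
        flip <- stats::rbinom(n_genotypes, 1, mutation_rate) == 1
        calls[, idx] <- ifelse(flip, 1 - calls[, idx - 1L], calls[, idx - 1L])
        block_pos <- block_pos + 1L
      }
      chrom[idx] <- chrom_labels[ch]
      pos[idx] <- positions[j]
    }
  }

  # redraw markers that came out (nearly) monomorphic
  maf <- function(x) { p <- mean(x); min(p, 1 - p) }
  for (j in seq_len(n_markers)) {
    tries <- 0L
    while (maf(calls[, j]) < maf_low / 2 && tries < 100L) {
      calls[, j] <- draw_marker()
      tries <- tries + 1L
    }
  }

  if (missing_rate > 0) {
    mask <- stats::runif(length(calls)) < missing_rate
    calls[mask] <- NA_real_
  }

  marker_ids <- sprintf("M%04d", seq_len(n_markers))
  genotype_ids <- sprintf("G%03d", seq_len(n_genotypes))
  dimnames(calls) <- list(genotype_ids, marker_ids)
  list(
    panel = genotype_panel(calls),
    map = genetic_map(tibble::tibble(
      marker_id = marker_ids, chromosome = chrom, position_cM = pos,
      mapped = TRUE
    ))
  )
}

# Linear interpolation of a target-heritability schedule over days.
interp_h2 <- function(h2_schedule, days) {
  sched_days <- as.numeric(names(h2_schedule))
  if (length(h2_schedule) == 1L) return(rep(unname(h2_schedule), length(days)))
  stats::approx(sched_days, unname(h2_schedule), xout = days, rule = 2)$y
}

logistic_curve <- function(t, a, b, c) a / (1 + b * exp(-c * t))

#' Simulate longitudinal growth phenotypes with planted QTL
#'
#' Each genotype receives latent logistic growth parameters
#' `(a, b, c)`: on the log scale, a population base value plus planted QTL
#' effects (calibrated so each QTL explains its `variance_fraction` of the
#' latent genetic variance of its target) plus a polygenic deviation
#' absorbing the remainder. Daily digital biomass per plant is the logistic
#' curve evaluated at the day, multiplied by `(1 + experiment effect +
#' genotype-by-experiment effect)` and by a multiplicative log-normal
#' residual (voxel volumes are positive and their measurement error scales
#' with plant size) whose day-specific variance is solved from the target
#' heritability schedule via
#' \eqn{H^2 = V_G / (V_G + V_{GE}/O + V_e/(O R))}. QTL with an
#' `effect_window` express their parameter effect only on days inside the
#' window, producing early-only, late-only, or mid-peak association
#' signals.
#'
#' Endpoint traits are emitted alongside the daily biomass: fresh weight
#' (proportional to final biomass, observed one day after the last imaging
#' day), tiller counts at days 27, 45 and 58 (when inside the observation
#' window), and tipping time (a phenology trait proportional to the
#' genotype's inflection point).
#'
#' @param panel A [genotype_panel()].
#' @param qtl List of [qtl_spec()] objects; per target the variance
#'   fractions must sum to at most 1.
#' @param base_params Named list with population means `a`, `b`, `c` and
#'   genetic coefficients of variation `cv_a`, `cv_b`, `cv_c`.
#' @param h2_schedule Named numeric vector mapping day to target
#'   broad-sense heritability (values in \[0, 1)); linearly interpolated.
#' @param n_experiments,n_replicates Design size.
#' @param days Integer vector of observation days (days after sowing).
#' @param gxe_sd SD of multiplicative genotype-by-experiment deviations.
#' @param experiment_sd SD of multiplicative experiment main effects.
#' @param outlier_rate Fraction of observations replaced by gross errors
#'   (at least 6 residual SD away from the true value).
#' @param mask_days Optional integer vector of days dropped from the
#'   output (emulating lost imaging days); default none.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `genotype`, `experiment`, `replicate`,
#'   `day`, `trait`, `value`. Attributes: `latent_params` (per-genotype
#'   tibble of a, b, c and inflection point t0 with all QTL effects
#'   active), `genetic_values` (genotype x day matrix of noise-free
#'   biomass), `residual_sd` (per-day residual SD used), and `qtl`.
#' @export
simulate_growth_phenotypes <- function(panel, qtl = list(),
                                       base_params = list(a = 50, b = 320, c = 0.18,
                                                          cv_a = 0.25, cv_b = 0.30, cv_c = 0.08),
                                       h2_schedule = c("10" = 0.62, "58" = 0.91),
                                       n_experiments = 3, n_replicates = 5,
                                       days = 10:58,
                                       gxe_sd = 0.04, experiment_sd = 0.05,
                                       outlier_rate = 0.002,
                                       mask_days = NULL, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (inherits(qtl, "qtl_spec")) qtl <- list(qtl)
  if (any(days < 1 | days > 200)) stop("days must lie within [1, 200]", call. = FALSE)
  h2_days <- interp_h2(h2_schedule, days)
  if (any(h2_days < 0 | h2_days >= 1)) {
    stop("h2_schedule values must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  ids <- panel$genotype_ids
  n <- length(ids)
  for (q in qtl) {
    if (!q$marker_id %in% panel$marker_ids) {
      stop("QTL marker not present in panel: ", q$marker_id, call. = FALSE)
    }
  }
  by_target <- split(qtl, vapply(qtl, `[[`, "", "target_parameter"))
  for (tgt in names(by_target)) {
    tot <- sum(vapply(by_target[[tgt]], `[[`, 0, "variance_fraction"))
    if (tot > 1) stop("QTL variance fractions for '", tgt, "' sum to > 1", call. = FALSE)
  }

  # centered, mean-imputed dosage for each causal marker
  dosage <- function(marker_id) {
    x <- panel$calls[, marker_id]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x - mean(x)
  }

  # latent log-scale effects per growth parameter
  growth_pars <- c("a", "b", "c")
  log_base <- stats::setNames(log(c(base_params$a, base_params$b, base_params$c)), growth_pars)
  cv <- stats::setNames(c(base_params$cv_a, base_params$cv_b, base_params$cv_c), growth_pars)
  sigma2_log <- log(1 + cv^2)

  qtl_effects <- list()  # per-QTL genotype-level effect vectors (log scale)
  poly_dev <- sapply(growth_pars, function(p) {
    qs <- by_target[[p]]
    fsum <- if (is.null(qs)) 0 else sum(vapply(qs, `[[`, 0, "variance_fraction"))
    stats::rnorm(n, 0, sqrt(pmax(0, (1 - fsum) * sigma2_log[p])))
  })
  rownames(poly_dev) <- ids
  for (k in seq_along(qtl)) {
    q <- qtl[[k]]
    if (!q$target_parameter %in% growth_pars) next
    x <- dosage(q$marker_id)
    vx <- stats::var(x)
    beta <- if (vx > 0) sqrt(q$variance_fraction * sigma2_log[q$target_parameter] / vx) else 0
    qtl_effects[[k]] <- beta * x
  }

  # latent parameters with every QTL effect active (calibration reference)
  latent_log <- sapply(growth_pars, function(p) {
    eff <- log_base[p] + poly_dev[, p]
    for (k in seq_along(qtl)) {
      if (qtl[[k]]$target_parameter == p) eff <- eff + qtl_effects[[k]]
    }
    eff
  })
  latent <- exp(latent_log)
  colnames(latent) <- growth_pars
  latent_params <- tibble::tibble(
    genotype = ids, a = latent[, "a"], b = latent[, "b"], c = latent[, "c"],
    t0 = log(latent[, "b"]) / latent[, "c"]
  )

  # genotype x day noise-free genetic values, with window-gated QTL effects
  g_mat <- matrix(0, n, length(days), dimnames = list(ids, as.character(days)))
  for (di in seq_along(days)) {
    d <- days[di]
    par_log <- sapply(growth_pars, function(p) log_base[p] + poly_dev[, p])
    for (k in seq_along(qtl)) {
      q <- qtl[[k]]
      if (!q$target_parameter %in% growth_pars) next
      active <- is.null(q$effect_window) ||
        (d >= q$effect_window[1] && d <= q$effect_window[2])
      if (active) par_log[, q$target_parameter] <- par_log[, q$target_parameter] + qtl_effects[[k]]
    }
    pars <- exp(par_log)
    g_mat[, di] <- logistic_curve(d, pars[, "a"], pars[, "b"], pars[, "c"])
  }

  experiments <- paste0("E", seq_len(n_experiments))
  exp_eff <- stats::setNames(stats::rnorm(n_experiments, 0, experiment_sd), experiments)
  gxe <- matrix(stats::rnorm(n * n_experiments, 0, gxe_sd), n, n_experiments,
                dimnames = list(ids, experiments))

  # day-specific residual SD solved from the heritability identity
  O <- n_experiments; R <- n_replicates
  v_g <- apply(g_mat, 2, stats::var)
  v_ge <- gxe_sd^2 * colMeans(g_mat^2)
  v_e <- O * R * v_g * (1 - h2_days) / h2_days - R * v_ge
  v_e <- pmax(v_e, 0)
  sd_e <- sqrt(v_e)

  grid <- tidyr::expand_grid(
    genotype = ids, experiment = experiments, replicate = seq_len(n_replicates)
  )
  n_plants <- nrow(grid)
  records <- tidyr::expand_grid(grid, day = days)
  gi <- match(records$genotype, ids)
  ei <- match(records$experiment, experiments)
  di <- match(records$day, days)
  mu <- unname(g_mat[cbind(gi, di)] * (1 + exp_eff[ei] + gxe[cbind(gi, ei)]))
  # Residual noise is multiplicative log-normal: voxel volumes are positive
  # and their measurement error scales with plant size. The log-scale SD is
  # solved per day so the mean within-cell residual variance equals v_e:
  # Var(m e^{tau z - tau^2/2}) = m^2 (e^{tau^2} - 1).
  em2 <- as.numeric(tapply(mu^2, di, mean))
  tau2 <- log(1 + v_e / em2)
  z <- stats::rnorm(nrow(records))
  value <- unname(mu * exp(sqrt(tau2[di]) * z - tau2[di] / 2))
  if (outlier_rate > 0) {
    out_idx <- which(stats::runif(nrow(records)) < outlier_rate)
    if (length(out_idx)) {
      sign <- sample(c(-1, 1), length(out_idx), replace = TRUE)
      value[out_idx] <- value[out_idx] +
        sign * stats::runif(length(out_idx), 6, 10) * sd_e[di[out_idx]]
    }
  }
  records$trait <- "digital_biomass"
  records$value <- pmax(value, 0)

  # --- endpoint traits -------------------------------------------------
  endpoint <- list()
  h2_last <- h2_days[length(h2_days)]
  endpoint_latent <- function(tgt, base_latent, cv_t) {
    # base_latent: genotype-level latent values before endpoint-specific QTL
    s2 <- stats::var(log(pmax(base_latent, 1e-8)))
    val <- log(pmax(base_latent, 1e-8))
    qs <- by_target[[tgt]]
    if (!is.null(qs)) {
      fsum <- sum(vapply(qs, `[[`, 0, "variance_fraction"))
      extra <- cv_t^2  # extra trait-specific log-variance budget
      for (q in qs) {
        x <- dosage(q$marker_id)
        beta <- sqrt(q$variance_fraction * (s2 + extra) / stats::var(x))
        val <- val + beta * x
      }
    }
    exp(val)
  }
  emit_endpoint <- function(trait, day, latent_g, h2_target) {
    vg <- stats::var(latent_g)
    vge <- gxe_sd^2 * mean(latent_g^2)
    ve <- max(O * R * vg * (1 - h2_target) / h2_target - R * vge, 0)
    gi <- match(grid$genotype, ids)
    ei <- match(grid$experiment, experiments)
    mu <- unname(latent_g[gi] * (1 + exp_eff[ei] + gxe[cbind(gi, ei)]))
    tau2 <- log(1 + ve / mean(mu^2))
    value <- mu * exp(sqrt(tau2) * stats::rnorm(n_plants) - tau2 / 2)
    tibble::tibble(
      genotype = grid$genotype, experiment = grid$experiment,
      replicate = grid$replicate, day = day, trait = trait,
      value = pmax(value, 0)
    )
  }
  last_day <- max(days)
  fw_latent <- endpoint_latent("fresh_weight", 0.002 * g_mat[, ncol(g_mat)], 0.1)
  endpoint$fw <- emit_endpoint("fresh_weight", last_day + 1, fw_latent, min(h2_last, 0.9))
  tip_latent <- endpoint_latent("tipping_time", latent_params$t0 + 24, 0.02)
  endpoint$tip <- emit_endpoint("tipping_time", last_day, tip_latent, 0.96)
  tiller_days <- intersect(c(27, 45, 58), days)
  for (d in tiller_days) {
    tl <- endpoint_latent("tiller_number", 2 + 20 * g_mat[, as.character(d)] / base_params$a, 0.1)
    tn <- emit_endpoint("tiller_number", d, tl, 0.85)
    tn$value <- round(tn$value)
    endpoint[[paste0("tn", d)]] <- tn
  }

  out <- dplyr::bind_rows(records[, c("genotype", "experiment", "replicate",
                                      "day", "trait", "value")],
                          dplyr::bind_rows(endpoint))
  if (!is.null(mask_days)) {
    out <- out[!(out$trait == "digital_biomass" & out$day %in% mask_days), ]
  }
  out <- tibble::as_tibble(out)
  attr(out, "latent_params") <- latent_params
  attr(out, "genetic_values") <- g_mat
  attr(out, "residual_sd") <- tibble::tibble(day = days, sd = sd_e, h2_target = h2_days)
  attr(out, "qtl") <- qtl
  out
}
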