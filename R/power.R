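#' QTL detection-power simulation
#'
#' Repeats, `n_reps` times: draw one marker per requested variance
#' fraction (distinct, uniformly at random); build genetic values
#' \eqn{g = \sum_k \beta_k x_k + u}, with each \eqn{\beta_k} calibrated
#' against the realized marker variance so that QTL `k` explains its
#' fraction of the total genetic variance, and a polygenic term `u` drawn
#' with covariance proportional to `2K` and scaled to the remaining
#' share; add experiment effects and residual noise sized so the
#' broad-sense heritability of the per-experiment values equals `h2`; run
#' [scan_trait()] and [apply_fdr()]; and score each QTL as detected when
#' its own marker, or any marker within `detection_window_cM` of it on
#' the same chromosome, is significant.
#'
#' @param panel A [genotype_panel()] (already MAF/missingness filtered).
#' @param map A [genetic_map()] for the panel's markers.
#' @param K A `kinship_matrix` from [compute_kinship()].
#' @param variance_fractions Shares of genetic variance for the planted
#'   QTL (defaults 15% and 10%); must sum to < 1.
#' @param h2 Broad-sense heritability of the simulated trait.
#' @param n_experiments Number of experiments (stacked BLUE replicates).
#' @param n_reps Number of simulation repetitions.
#' @param q FDR level for [apply_fdr()].
#' @param detection_window_cM Window around the causal marker within which
#'   a significant marker counts as detection; `0` requires the causal
#'   marker itself.
#' @param mode Scan mode, see [scan_trait()].
#' @param seed Integer seed.
#' @return A `power_result`: list with `per_qtl` (tibble
#'   `variance_fraction`, `n_reps`, `n_detected`, `detection_rate`),
#'   `per_rep` (tibble of individual outcomes) and `settings`.
#' @export
run_power_simulation <- function(panel, map, K,
                                 variance_fractions = c(0.15, 0.10),
                                 h2 = 0.8, n_experiments = 3, n_reps = 100,
                                 q = 0.1, detection_window_cM = 8,
                                 mode = "null_varcomp_reuse", seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(K, "kinship_matrix"))
  stopifnot(sum(variance_fractions) < 1, h2 > 0, h2 < 1)
  map <- genetic_map(map)
  set.seed(seed)

  gids <- panel$genotype_ids
  n <- length(gids)
  X <- panel$calls
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  mvar <- apply(X, 2, stats::var)
  eligible <- which(mvar > 1e-6)
  L <- t(chol(2 * K$K[gids, gids] + diag(1e-6, n)))
  experiments <- paste0("E", seq_len(n_experiments))
  n_qtl <- length(variance_fractions)
  v_e <- n_experiments * (1 - h2) / h2  # residual variance for V_G = 1

  per_rep <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    # draw causal markers; redraw near-monomorphic picks
    picks <- integer(0)
    while (length(picks) < n_qtl) {
      cand <- sample(eligible, 1)
      if (mvar[cand] < 1e-6 || cand %in% picks) next
      picks <- c(picks, cand)
    }
    g <- rep(0, n)
    for (k in seq_len(n_qtl)) {
      x <- X[, picks[k]]
      beta <- sqrt(variance_fractions[k] / mvar[picks[k]])
      g <- g + beta * (x - mean(x))
    }
    u <- drop(L %*% stats::rnorm(n))
    f_rem <- 1 - sum(variance_fractions)
    su <- stats::sd(u)
    if (su > 0) u <- u * sqrt(f_rem) / su
    g <- g + u
    vg <- stats::var(g)

    blues <- tidyr::expand_grid(genotype = gids, experiment = experiments)
    exp_eff <- stats::setNames(stats::rnorm(n_experiments, 0, 0.5), experiments)
    blues$blue <- g[match(blues$genotype, gids)] +
      exp_eff[blues$experiment] +
      stats::rnorm(nrow(blues), 0, sqrt(v_e * vg))

    scan <- scan_trait(blues, panel, K, mode = mode)
    scan <- apply_fdr(scan, q = q)
    sig <- scan$marker_id[scan$significant]

    detected <- logical(n_qtl)
    for (k in seq_len(n_qtl)) {
      mk <- panel$marker_ids[picks[k]]
      if (mk %in% sig) { detected[k] <- TRUE; next }
      row <- map[map$marker_id == mk & map$mapped, , drop = FALSE]
      if (nrow(row) && detection_window_cM > 0 && length(sig)) {
        near <- map[map$marker_id %in% sig & map$mapped &
                      map$chromosome == row$chromosome[1] &
                      abs(map$position_cM - row$position_cM[1]) <= detection_window_cM, ]
        detected[k] <- nrow(near) > 0
      }
    }
    per_rep[[rep_i]] <- tibble::tibble(
      rep = rep_i, qtl = seq_len(n_qtl),
      variance_fraction = variance_fractions,
      marker_id = panel$marker_ids[picks],
      detected = detected, n_significant = length(sig)
    )
  }
  per_rep <- dplyr::bind_rows(per_rep)
  per_qtl <- per_rep |>
    dplyr::group_by(.data$qtl, .data$variance_fraction) |>
    dplyr::summarise(n_reps = dplyr::n(), n_detected = sum(.data$detected),
                     detection_rate = mean(.data$detected), .groups = "drop")
  structure(
    list(per_qtl = per_qtl, per_rep = per_rep,
         settings = list(h2 = h2, n_experiments = n_experiments, q = q,
                         detection_window_cM = detection_window_cM,
                         mode = mode, seed = seed, n_reps = n_reps)),
    class = "power_result"
  )
}

#' @exportS3Method base::print
print.power_result <- function(x, ...) {
  cat("<power_result> over", x$settings$n_reps, "repetitions\n")
  df <- x$per_qtl
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  QTL %d (%.0f%% of genetic variance): detected %d/%d (%.0f%%)\n",
                df$qtl[i], 100 * df$variance_fraction[i], df$n_detected[i],
                df$n_reps[i], 100 * df$detection_rate[i]))
  }
  invisible(x)
}
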