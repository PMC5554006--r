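#' Kinship mixed-model marker scan for one trait-day
#'
#' Fits, for every marker, the mixed linear model
#' \deqn{Y = \mu + E + S + G + e}
#' on stacked per-experiment BLUEs: fixed intercept, experiment
#' indicators and marker dosage `S`; a random genotype effect `G` with
#' covariance \eqn{2 K \sigma^2_G}; and iid residuals. The observation
#' covariance \eqn{Z (2K) Z' \sigma^2_G + I \sigma^2_e} is diagonalized by
#' a single eigendecomposition, and the variance ratio
#' \eqn{\lambda = \sigma^2_G / \sigma^2_e} is profiled out by 1-D bounded
#' REML optimization. Any rescaling of the kinship (such as the factor 2)
#' is absorbed into the profiled ratio, so results do not depend on it.
#'
#' With the default mode `"null_varcomp_reuse"` the variance components
#' are estimated once under the no-marker null model and reused for every
#' marker (the P3D approximation); `"full_reml_per_marker"` re-estimates
#' the ratio for each marker. The marker term is tested with a Wald test
#' referred to an F(1, n - p) distribution, which reduces exactly to the
#' ordinary fixed-effects F-test when the genetic variance is zero.
#'
#' Missing marker calls are mean-imputed; markers constant over the
#' scanned genotypes are skipped.
#'
#' @param blues Step-1 BLUE tibble with columns `experiment`, `genotype`,
#'   `blue` (one trait-day slice; see [compute_blues_step1()]).
#' @param panel A [genotype_panel()] (typically after [filter_markers()]).
#' @param K A `kinship_matrix` from [compute_kinship()].
#' @param mode `"null_varcomp_reuse"` (default) or `"full_reml_per_marker"`.
#' @param fix_lambda Optional fixed variance ratio \eqn{\sigma^2_G /
#'   \sigma^2_e}; `0` gives the ordinary fixed-effects scan.
#' @param trait,day Optional labels copied into the output.
#' @return A `gwas_scan` tibble with columns `marker_id`, `trait`, `day`,
#'   `maf`, `effect`, `se`, `p_value`, `neg_log10_p`. Attributes `lambda`,
#'   `sigma2_g`, `sigma2_e`, `mode`, `n_obs`.
#' @export
scan_trait <- function(blues, panel, K, mode = c("null_varcomp_reuse",
                                                 "full_reml_per_marker"),
                       fix_lambda = NULL, trait = NA_character_, day = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "genotype_panel"), inherits(K, "kinship_matrix"))
  blues <- tibble::as_tibble(blues)
  stopifnot(all(c("experiment", "genotype", "blue") %in% names(blues)))
  blues <- blues[!is.na(blues$blue), , drop = FALSE]
  gids <- intersect(intersect(unique(blues$genotype), panel$genotype_ids),
                    K$genotype_ids)
  if (length(gids) < 10) stop("fewer than 10 genotypes align across inputs",
                              call. = FALSE)
  blues <- blues[blues$genotype %in% gids, , drop = FALSE]
  dup <- duplicated(blues[, c("genotype", "experiment")])
  if (any(dup)) stop("blues must hold one value per genotype per experiment",
                     call. = FALSE)

  n <- nrow(blues)
  gi <- match(blues$genotype, gids)
  y <- blues$blue
  X0 <- stats::model.matrix(~ factor(blues$experiment))
  colnames(X0) <- sub("factor\\(blues\\$experiment\\)", "exp_", colnames(X0))

  G2 <- 2 * K$K[gids, gids]
  ev_min <- min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    stop("kinship is not positive semidefinite; apply ridge repair", call. = FALSE)
  }
  Z <- matrix(0, n, length(gids)); Z[cbind(seq_len(n), gi)] <- 1
  eg <- eigen(Z %*% G2 %*% t(Z), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  X0s <- crossprod(U, X0)

  # REML criterion (up to constants) for variance ratio lambda at design Xs
  reml_nll <- function(log10_lambda, Xs) {
    lam <- 10^log10_lambda
    v <- lam * d + 1
    sw <- 1 / sqrt(v)
    Xt <- Xs * sw; yt <- ys * sw
    qrX <- qr(Xt)
    rss <- sum(qr.resid(qrX, yt)^2)
    p <- ncol(Xs)
    Rd <- abs(diag(qr.R(qrX)))
    0.5 * ((n - p) * log(rss / (n - p)) + sum(log(v)) + 2 * sum(log(Rd)))
  }
  est_lambda <- function(Xs) {
    opt <- stats::optimize(reml_nll, interval = c(-8, 8), Xs = Xs, tol = 1e-8)
    10^opt$minimum
  }

  # centered genotype-level dosages, expanded to observations and rotated
  Xg <- panel$calls[gids, , drop = FALSE]
  mu <- colMeans(Xg, na.rm = TRUE)
  idx <- which(is.na(Xg), arr.ind = TRUE)
  if (nrow(idx)) Xg[idx] <- mu[idx[, 2]]
  usable <- apply(Xg, 2, function(v) stats::var(v) > 0)
  Xg <- Xg[, usable, drop = FALSE]
  if (ncol(Xg) == 0) stop("no polymorphic markers among scanned genotypes",
                          call. = FALSE)
  maf <- pmin(colMeans(Xg), 1 - colMeans(Xg))
  M <- crossprod(U, Xg[gi, , drop = FALSE])

  wald_given_lambda <- function(lambda) {
    v <- lambda * d + 1
    sw <- 1 / sqrt(v)
    X0t <- X0s * sw; yt <- ys * sw; Mt <- M * sw
    qr0 <- qr(X0t)
    ry <- qr.resid(qr0, yt)
    RM <- qr.resid(qr0, Mt)
    sxx <- colSums(RM^2)
    sxy <- colSums(RM * ry)
    beta <- sxy / sxx
    rss0 <- sum(ry^2)
    df <- n - ncol(X0) - 1
    rss_m <- pmax(rss0 - sxy^2 / sxx, 0)
    sigma2 <- rss_m / df
    se <- sqrt(sigma2 / sxx)
    fstat <- (beta / se)^2
    list(beta = beta, se = se,
         p = stats::pf(fstat, 1, df, lower.tail = FALSE),
         sigma2 = sigma2)
  }

  if (!is.null(fix_lambda)) {
    lambda <- fix_lambda
    res <- wald_given_lambda(lambda)
  } else if (mode == "null_varcomp_reuse") {
    lambda <- est_lambda(X0s)
    res <- wald_given_lambda(lambda)
  } else {
    lambda <- est_lambda(X0s)
    beta <- se <- p <- numeric(ncol(M))
    for (j in seq_len(ncol(M))) {
      lam_j <- est_lambda(cbind(X0s, M[, j]))
      rj <- wald_given_lambda(lam_j)
      beta[j] <- rj$beta[j]; se[j] <- rj$se[j]; p[j] <- rj$p[j]
    }
    res <- list(beta = beta, se = se, p = p)
  }

  p_val <- pmin(pmax(res$p, .Machine$double.xmin), 1)
  out <- tibble::tibble(
    marker_id = colnames(Xg), trait = trait, day = day, maf = unname(maf),
    effect = unname(res$beta), se = unname(res$se),
    p_value = unname(p_val), neg_log10_p = -log10(unname(p_val))
  )
  v_null <- wald_given_lambda(lambda)  # residual scale under reused ratio
  attr(out, "lambda") <- lambda
  attr(out, "sigma2_e") <- stats::median(v_null$sigma2)
  attr(out, "sigma2_g") <- lambda * stats::median(v_null$sigma2)
  attr(out, "mode") <- if (!is.null(fix_lambda)) "fixed_lambda" else mode
  attr(out, "n_obs") <- n
  class(out) <- c("gwas_scan", class(out))
  out
}

#' Benjamini-Hochberg FDR flags for a marker scan
#'
#' Applies the Benjamini-Hochberg step-up procedure at level `q` across
#' the markers of one trait-day scan and adds `p_adj` and `significant`
#' columns. When the input holds several trait-day scans (distinct
#' `trait`/`day` values), the correction is applied within each scan
#' separately.
#'
#' @param tests A `gwas_scan` tibble (or any tibble with `p_value`).
#' @param q FDR level.
#' @return The input with `p_adj` and `significant` columns.
#' @export
apply_fdr <- function(tests, q = 0.1) {
  tests <- tibble::as_tibble(tests)
  if (nrow(tests) == 0) {
    tests$p_adj <- numeric(0); tests$significant <- logical(0)
    return(tests)
  }
  grp <- c("trait", "day")[c("trait", "day") %in% names(tests)]
  tests |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, method = "BH"),
                  significant = .data$p_adj <= q) |>
    dplyr::ungroup()
}

#' Proportion of genetic variance explained by detected QTL
#'
#' For each marker, the adjusted R-squared of a single-marker fixed
#' regression on across-experiment BLUEs, standardized by the trait's
#' broad-sense heritability (and clipped to \[0, 1\]); and, for the set,
#' the adjusted R-squared of the joint multi-marker regression,
#' standardized the same way.
#'
#' @param blues_across Tibble with columns `genotype`, `blue`
#'   (across-experiment BLUEs of one trait-day).
#' @param panel A [genotype_panel()].
#' @param markers Character vector of marker ids.
#' @param h2 Broad-sense heritability of the trait-day (scalar in (0, 1\]).
#' @return A list of class `variance_explained`: `individual` (tibble
#'   `marker_id`, `adj_r2`, `var_explained`), `combined`, `combined_adj_r2`,
#'   `h2`, `n`.
#' @export
variance_explained <- function(blues_across, panel, markers, h2) {
  stopifnot(h2 > 0, length(markers) >= 1)
  blues_across <- tibble::as_tibble(blues_across)
  gids <- intersect(blues_across$genotype, panel$genotype_ids)
  y <- blues_across$blue[match(gids, blues_across$genotype)]
  X <- panel$calls[gids, markers, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  if (any(apply(X, 2, stats::var) == 0)) {
    stop("constant marker among the requested set", call. = FALSE)
  }
  n <- length(y)
  if (length(markers) > n - 2) {
    stop("rank deficiency: more markers than genotypes - 2", call. = FALSE)
  }
  adj_r2 <- function(Xm) summary(stats::lm(y ~ Xm))$adj.r.squared
  indiv <- vapply(seq_along(markers), function(j) adj_r2(X[, j, drop = FALSE]), 0)
  comb <- adj_r2(X)
  clip <- function(v) pmin(pmax(v, 0), 1)
  structure(
    list(
      individual = tibble::tibble(marker_id = markers, adj_r2 = indiv,
                                  var_explained = clip(indiv / h2)),
      combined = clip(comb / h2), combined_adj_r2 = comb, h2 = h2, n = n
    ),
    class = "variance_explained"
  )
}

#' @exportS3Method base::print
print.variance_explained <- function(x, ...) {
  cat(sprintf("<variance_explained> %d marker(s), H2 = %.3f\n",
              nrow(x$individual), x$h2))
  cat(sprintf("  combined share of genetic variance: %.3f\n", x$combined))
  invisible(x)
}

#' Temporal QTL trajectories from per-day scans
#'
#' Retains markers significant (after [apply_fdr()]) on at least one day
#' and assembles their per-day significance series. The temporal pattern
#' is labelled by comparing the mean `-log10(p)` of the first and last
#' third of days; a marker whose interior maximum exceeds both end means
#' by at least 20% is labelled `"peaked"`, otherwise it is `"increasing"`
#' or `"decreasing"` according to the end comparison, and `"other"` on
#' ties.
#'
#' @param daily_scans A tibble of stacked per-day scans with `marker_id`,
#'   `day`, `neg_log10_p`, `significant` (from [apply_fdr()]); an optional
#'   `var_explained` column is carried through.
#' @return A `qtl_trajectories` tibble: `marker_id`, `pattern`, `n_days`,
#'   `days_significant`, `peak_day`, and a nested `series` list-column of
#'   per-day tibbles.
#' @export
qtl_trajectories <- function(daily_scans) {
  daily_scans <- tibble::as_tibble(daily_scans)
  stopifnot(all(c("marker_id", "day", "neg_log10_p", "significant") %in%
                  names(daily_scans)))
  if (length(unique(daily_scans$day)) < 3) {
    stop("need scans over >= 3 days", call. = FALSE)
  }
  hits <- unique(daily_scans$marker_id[daily_scans$significant])
  keep_cols <- intersect(c("day", "neg_log10_p", "p_value", "significant",
                           "var_explained", "effect"), names(daily_scans))
  if (!length(hits)) {
    out <- tibble::tibble(marker_id = character(), pattern = character(),
                          n_days = integer(), days_significant = integer(),
                          peak_day = numeric(), series = list())
    class(out) <- c("qtl_trajectories", class(out))
    return(out)
  }
  out <- purrr::map_dfr(hits, function(m) {
    ser <- daily_scans[daily_scans$marker_id == m, keep_cols, drop = FALSE]
    ser <- ser[order(ser$day), , drop = FALSE]
    tibble::tibble(
      marker_id = m,
      pattern = label_pattern(ser$neg_log10_p),
      n_days = nrow(ser),
      days_significant = sum(ser$significant),
      peak_day = ser$day[which.max(ser$neg_log10_p)],
      series = list(ser)
    )
  })
  class(out) <- c("qtl_trajectories", class(out))
  out
}

# Pattern label for a -log10(p) series ordered by day.
label_pattern <- function(nlp) {
  n <- length(nlp)
  k <- ceiling(n / 3)
  m_first <- mean(nlp[seq_len(k)])
  m_last <- mean(nlp[seq(n - k + 1, n)])
  interior <- setdiff(seq_len(n), c(seq_len(k), seq(n - k + 1, n)))
  if (length(interior)) {
    m_int <- max(nlp[interior])
    if (m_int > max(m_first, m_last) &&
        m_int >= 1.2 * m_first && m_int >= 1.2 * m_last) {
      return("peaked")
    }
  }
  if (m_last > m_first) "increasing"
  else if (m_first > m_last) "decreasing"
  else "other"
}

#' Scan a trait across days and control FDR per day
#'
#' Convenience wrapper running [scan_trait()] for every day of a step-1
#' BLUE table and applying [apply_fdr()] within each day.
#'
#' @param step1 Step-1 BLUE tibble with `trait`, `day`, `experiment`,
#'   `genotype`, `blue`.
#' @param panel,K,mode,fix_lambda Passed to [scan_trait()].
#' @param trait Trait to scan.
#' @param days Days to scan; default all days present for the trait.
#' @param q FDR level per day.
#' @return A stacked tibble of per-day scans with FDR flags.
#' @export
scan_days <- function(step1, panel, K, trait = "digital_biomass", days = NULL,
                      q = 0.1, mode = "null_varcomp_reuse", fix_lambda = NULL) {
  step1 <- tibble::as_tibble(step1)
  step1 <- step1[step1$trait == trait, , drop = FALSE]
  if (is.null(days)) days <- sort(unique(step1$day))
  scans <- purrr::map_dfr(days, function(d) {
    sl <- step1[step1$day == d, , drop = FALSE]
    scan_trait(sl, panel, K, mode = mode, fix_lambda = fix_lambda,
               trait = trait, day = d)
  })
  apply_fdr(scans, q = q)
}
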