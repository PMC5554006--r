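#' Filter markers on minor allele frequency and missingness
#'
#' Keeps markers with `MAF > maf_min` (strict) and
#' `missing_rate < missing_max` (strict), preserving marker order.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min,missing_max Thresholds.
#' @return A filtered [genotype_panel()].
#' @export
filter_markers <- function(panel, maf_min = 0.05, missing_max = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  stats <- marker_stats(panel)
  keep <- !is.na(stats$maf) & stats$maf > maf_min & stats$missing_rate < missing_max
  if (!any(keep)) stop("no markers pass the MAF/missingness filter", call. = FALSE)
  subset_panel(panel, markers = which(keep))
}

#' Realized kinship matrix from standardized marker scores
#'
#' Missing calls are mean-imputed per marker; the 0/1 scores are then
#' column-standardized (mean 0, unit variance) into a matrix `W`, and the
#' kinship is `K = W W' / m` over the `m` markers. Markers with zero
#' variance after imputation are dropped with a warning. A small ridge is
#' added to the diagonal if numerical noise makes the smallest eigenvalue
#' negative.
#'
#' @param panel A [genotype_panel()].
#' @return A `kinship_matrix` object: list with `K` (named symmetric
#'   matrix), `genotype_ids`, `n_markers`.
#' @export
compute_kinship <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$calls
  if (any(colSums(!is.na(X)) == 0)) {
    stop("panel contains fully missing markers", call. = FALSE)
  }
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  s <- apply(X, 2, stats::sd)
  zero <- s == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance marker(s) dropped from the kinship",
            call. = FALSE)
    X <- X[, !zero, drop = FALSE]
    mu <- mu[!zero]; s <- s[!zero]
  }
  W <- scale(X, center = mu, scale = s)
  m <- ncol(W)
  K <- tcrossprod(W) / m
  K <- (K + t(K)) / 2
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) K <- K + diag(abs(ev_min) + 1e-10, nrow(K))
  dimnames(K) <- list(panel$genotype_ids, panel$genotype_ids)
  structure(
    list(K = K, genotype_ids = panel$genotype_ids, n_markers = m),
    class = "kinship_matrix"
  )
}

#' @exportS3Method base::print
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d genotypes from %d markers; mean diagonal %.3f\n",
              nrow(x$K), x$n_markers, mean(diag(x$K))))
  invisible(x)
}
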