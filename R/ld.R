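#' Pairwise linkage disequilibrium (r-squared) for mapped markers
#'
#' Computes, within each chromosome, the squared Pearson correlation of
#' the 0/1 allele codes over genotypes non-missing at both markers, for
#' every pair of mapped markers. In an inbred panel the genotype
#' correlation equals the haplotype correlation, so no phasing is needed.
#' Pairs involving a monomorphic marker are skipped. If the total number
#' of pairs exceeds `max_pairs`, a seeded uniform subsample is returned.
#'
#' @param panel A [genotype_panel()].
#' @param map A [genetic_map()] tibble.
#' @param max_pairs Upper bound on the number of pairs returned.
#' @param seed Seed for the subsample draw (only used when subsampling).
#' @return A tibble with columns `marker_i`, `marker_j`, `chromosome`,
#'   `distance_cM`, `r2`.
#' @export
pairwise_r2 <- function(panel, map, max_pairs = 500000, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  map <- genetic_map(map)
  map <- map[map$mapped & map$marker_id %in% panel$marker_ids, , drop = FALSE]
  res <- list()
  for (ch in unique(map$chromosome)) {
    sub <- map[map$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$position_cM), , drop = FALSE]
    if (nrow(sub) < 2) next
    x <- panel$calls[, sub$marker_id, drop = FALSE]
    poly <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
    sub <- sub[poly, , drop = FALSE]
    if (nrow(sub) < 2) next
    x <- x[, sub$marker_id, drop = FALSE]
    r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    ut <- upper.tri(r)
    ij <- which(ut, arr.ind = TRUE)
    d <- abs(outer(sub$position_cM, sub$position_cM, "-"))[ut]
    res[[ch]] <- tibble::tibble(
      marker_i = sub$marker_id[ij[, 1]],
      marker_j = sub$marker_id[ij[, 2]],
      chromosome = ch,
      distance_cM = d,
      r2 = r[ut]^2
    )
  }
  if (!length(res)) stop("need >= 2 mapped polymorphic markers on some chromosome",
                         call. = FALSE)
  pairs <- dplyr::bind_rows(res)
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  if (nrow(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[sort(sample.int(nrow(pairs), max_pairs)), , drop = FALSE]
  }
  pairs
}

#' Population-specific background LD threshold
#'
#' The 95th percentile (linear-interpolation definition, R quantile
#' type 7) of r-squared over unlinked intrachromosomal pairs, defined as
#' pairs more than `unlinked_cM` apart.
#'
#' @param pairs Pair tibble from [pairwise_r2()].
#' @param unlinked_cM Distance beyond which pairs count as unlinked.
#' @param probs Percentile to take (default 0.95).
#' @param min_pairs Minimum number of unlinked pairs required.
#' @return The threshold r-squared (scalar).
#' @export
ld_threshold <- function(pairs, unlinked_cM = 50, probs = 0.95, min_pairs = 20) {
  r2 <- pairs$r2[pairs$distance_cM > unlinked_cM]
  if (length(r2) < min_pairs) {
    stop("insufficient unlinked pairs (> ", unlinked_cM, " cM): ",
         length(r2), " found, ", min_pairs, " required", call. = FALSE)
  }
  unname(stats::quantile(r2, probs = probs, type = 7))
}

#' Extent of linkage disequilibrium from the LOESS decay curve
#'
#' Fits a degree-1 LOESS (tricube weights) of r-squared on genetic
#' distance and returns the smallest distance at which the fitted curve
#' first drops to or below `threshold_r2`, located by bisection between
#' grid points. Returns 0 (with a warning) when the curve starts below
#' the threshold, and `NA` (with a warning) when it never crosses.
#'
#' @param pairs Pair tibble from [pairwise_r2()] (at least 50 rows).
#' @param threshold_r2 Background threshold, e.g. from [ld_threshold()].
#' @param loess_span LOESS span (fraction of points in each local fit).
#' @param grid_n Number of grid points used to bracket the crossing.
#' @param max_fit_points Pair count above which a seeded subsample is used
#'   for the LOESS fit (local regression cost grows steeply with n).
#' @return The LD extent in cM (scalar), or `NA` if no crossing.
#' @export
ld_extent <- function(pairs, threshold_r2, loess_span = 0.3, grid_n = 1000,
                      max_fit_points = 50000) {
  if (nrow(pairs) < 50) stop("need >= 50 pairs for the LOESS fit", call. = FALSE)
  if (nrow(pairs) > max_fit_points) {
    idx <- withr::with_seed(1, sort(sample.int(nrow(pairs), max_fit_points)))
    pairs <- pairs[idx, , drop = FALSE]
  }
  surface <- if (nrow(pairs) > 5000) "interpolate" else "direct"
  fit <- stats::loess(r2 ~ distance_cM, data = pairs, span = loess_span,
                      degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = surface))
  d_min <- min(pairs$distance_cM); d_max <- max(pairs$distance_cM)
  grid <- seq(d_min, d_max, length.out = grid_n)
  yhat <- stats::predict(fit, newdata = data.frame(distance_cM = grid))
  below <- yhat <= threshold_r2
  if (below[1]) {
    warning("LOESS curve starts at or below the threshold; extent set to 0",
            call. = FALSE)
    return(0)
  }
  if (!any(below)) {
    warning("LOESS curve never crosses the threshold; extent undefined",
            call. = FALSE)
    return(NA_real_)
  }
  i <- which(below)[1]
  f <- function(d) {
    stats::predict(fit, newdata = data.frame(distance_cM = d)) - threshold_r2
  }
  stats::uniroot(f, lower = grid[i - 1], upper = grid[i], tol = 1e-4)$root
}

#' Full LD-decay characterization
#'
#' Runs [pairwise_r2()], [ld_threshold()] and [ld_extent()] and returns
#' pairs, threshold and extent (genome-wide, over all intrachromosomal
#' pairs pooled) in one object.
#'
#' @inheritParams pairwise_r2
#' @inheritParams ld_extent
#' @param unlinked_cM Distance defining unlinked pairs for the threshold.
#' @return A list of class `ld_decay` with `pairs`, `threshold_r2`,
#'   `extent_cM`, `loess_span`.
#' @export
ld_decay <- function(panel, map, loess_span = 0.3, unlinked_cM = 50,
                     max_pairs = 500000, seed = 1) {
  pairs <- pairwise_r2(panel, map, max_pairs = max_pairs, seed = seed)
  thr <- ld_threshold(pairs, unlinked_cM = unlinked_cM)
  ext <- ld_extent(pairs, thr, loess_span = loess_span)
  structure(
    list(pairs = pairs, threshold_r2 = thr, extent_cM = ext,
         loess_span = loess_span),
    class = "ld_decay"
  )
}

#' @exportS3Method base::print
print.ld_decay <- function(x, ...) {
  cat(sprintf("<ld_decay> %d pairs; background r2 threshold %.4f; extent %s cM\n",
              nrow(x$pairs), x$threshold_r2,
              if (is.na(x$extent_cM)) "NA" else sprintf("%.2f", x$extent_cM)))
  invisible(x)
}
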