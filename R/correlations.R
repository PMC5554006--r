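#' Day-by-day Kendall rank correlation matrix of BLUEs
#'
#' Computes Kendall's tau between genotype BLUEs of every pair of days,
#' using pairwise-complete genotypes. Entries backed by fewer than
#' `min_shared` shared genotypes are set to `NA`.
#'
#' @param blues Tibble with columns `genotype`, `day`, `blue` (e.g. the
#'   output of [compute_blues_step2()] for one trait).
#' @param min_shared Minimum number of shared genotypes per day pair.
#' @return A symmetric day-by-day matrix of Kendall tau with unit diagonal.
#' @export
kendall_correlation_matrix <- function(blues, min_shared = 3) {
  blues <- tibble::as_tibble(blues)
  wide <- blues |>
    dplyr::select("genotype", "day", "blue") |>
    tidyr::pivot_wider(names_from = "day", values_from = "blue") |>
    tibble::column_to_rownames("genotype") |>
    as.matrix()
  wide <- wide[, order(as.numeric(colnames(wide))), drop = FALSE]
  tau <- suppressWarnings(
    stats::cor(wide, method = "kendall", use = "pairwise.complete.obs")
  )
  shared <- crossprod(!is.na(wide))
  tau[shared < min_shared] <- NA_real_
  diag(tau) <- 1
  tau
}

#' Pearson correlation between two trait BLUE sets
#'
#' Joins two genotype-level BLUE tables on genotype and computes Pearson's
#' r with a two-sided t-test on the shared genotypes.
#'
#' @param a,b Tibbles with columns `genotype` and `blue` (or `value`).
#' @return A one-row tibble with `r`, `p_value`, `n`.
#' @export
correlate_traits <- function(a, b) {
  val_col <- function(df) {
    df <- tibble::as_tibble(df)
    col <- intersect(c("blue", "value"), names(df))[1]
    if (is.na(col)) stop("need a 'blue' or 'value' column", call. = FALSE)
    dplyr::select(df, "genotype", value = dplyr::all_of(col))
  }
  joined <- dplyr::inner_join(val_col(a), val_col(b), by = "genotype",
                              suffix = c("_a", "_b")) |>
    dplyr::filter(!is.na(.data$value_a), !is.na(.data$value_b))
  if (nrow(joined) < 3) stop("need >= 3 shared genotypes", call. = FALSE)
  if (stats::sd(joined$value_a) == 0 || stats::sd(joined$value_b) == 0) {
    stop("correlation undefined: zero variance in one trait", call. = FALSE)
  }
  ct <- stats::cor.test(joined$value_a, joined$value_b, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(joined))
}
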