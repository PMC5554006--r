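#' Robust outlier screen for longitudinal phenotype records
#'
#' Within each (experiment, day, trait) group, each observation's residual
#' from its genotype mean is compared against a robust scale estimate
#' (median absolute deviation of the group's residuals, scaled to be
#' consistent with the Gaussian SD). Observations whose absolute residual
#' exceeds `threshold_sd` robust SDs are flagged, never deleted; downstream
#' steps skip flagged records. The default threshold of 3.5 keeps the flag
#' rate on clean Gaussian data well below 1%.
#'
#' Groups with fewer than `min_group` observations are skipped with a
#' warning and nothing in them is flagged.
#'
#' @param records Phenotype tibble with columns `genotype`, `experiment`,
#'   `replicate`, `day`, `trait`, `value`.
#' @param threshold_sd Flagging threshold in robust SD units.
#' @param min_group Minimum group size required to attempt screening.
#' @return The input tibble with a logical `outlier` column added.
#' @export
detect_outliers <- function(records, threshold_sd = 3.5, min_group = 5) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("genotype", "experiment", "day", "trait", "value") %in% names(records)))
  skipped <- 0L
  out <- records |>
    dplyr::group_by(.data$experiment, .data$day, .data$trait) |>
    dplyr::group_modify(function(df, key) {
      df$outlier <- FALSE
      obs <- !is.na(df$value)
      if (sum(obs) < min_group) {
        skipped <<- skipped + 1L
        return(df)
      }
      resid <- df$value - stats::ave(df$value, df$genotype,
                                     FUN = function(v) mean(v, na.rm = TRUE))
      scale <- stats::mad(resid[obs])
      df$outlier[obs] <- abs(resid[obs]) > threshold_sd * scale
      df
    }) |>
    dplyr::ungroup()
  if (skipped > 0L) {
    warning(skipped, " group(s) smaller than ", min_group,
            " observations were skipped (nothing flagged)", call. = FALSE)
  }
  # restore original column order with outlier appended
  dplyr::relocate(out, dplyr::all_of(names(records)))
}
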