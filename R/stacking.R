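#' Standardize daily biomass against the population average
#'
#' Expresses each genotype's BLUE as a relative deviation from the day's
#' population mean, `(value - mean) / mean`, so that values below zero
#' mark genotypes below the population average. A z-score alternative
#' (`(value - mean) / sd`) is available via `method`.
#'
#' @param blues Tibble with columns `genotype`, `day`, `blue`
#'   (across-experiment BLUEs of digital biomass).
#' @param method `"relative"` (default) or `"zscore"`.
#' @return A tibble `genotype`, `day`, `std_biomass`.
#' @export
standardize_daily_biomass <- function(blues, method = c("relative", "zscore")) {
  method <- match.arg(method)
  blues <- tibble::as_tibble(blues)
  blues |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) stop("need >= 2 genotypes per day", call. = FALSE)
      m <- mean(df$blue)
      if (method == "relative") {
        if (m == 0) stop("day mean is zero: standardization undefined",
                         call. = FALSE)
        s <- (df$blue - m) / m
      } else {
        sdev <- stats::sd(df$blue)
        if (sdev == 0) stop("zero SD: standardization undefined", call. = FALSE)
        s <- (df$blue - m) / sdev
      }
      tibble::tibble(genotype = df$genotype, std_biomass = s)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("genotype", "day", "std_biomass")
}

#' Determine the favorable allele of each QTL marker
#'
#' For each marker, at its day of peak significance (largest `-log10(p)`
#' in the supplied scans), the allele class whose carriers have the higher
#' mean across-experiment BLUE is declared favorable. Ties go to allele 1
#' and are reported.
#'
#' @param scans Stacked per-day scan tibble (see [scan_days()]) covering
#'   the markers of interest.
#' @param blues_by_day Tibble `genotype`, `day`, `blue` of across-experiment
#'   BLUEs for the scanned trait.
#' @param panel A [genotype_panel()].
#' @param qtl_markers Character vector of marker ids.
#' @return A tibble `marker_id`, `favorable_allele` (0 or 1), `peak_day`,
#'   `mean_allele0`, `mean_allele1`, `tie`.
#' @export
assign_favorable_alleles <- function(scans, blues_by_day, panel, qtl_markers) {
  scans <- tibble::as_tibble(scans)
  blues_by_day <- tibble::as_tibble(blues_by_day)
  purrr::map_dfr(qtl_markers, function(m) {
    ser <- scans[scans$marker_id == m, , drop = FALSE]
    if (nrow(ser) == 0) stop("marker not present in scans: ", m, call. = FALSE)
    peak_day <- ser$day[which.max(ser$neg_log10_p)]
    bl <- blues_by_day[blues_by_day$day == peak_day, , drop = FALSE]
    x <- panel$calls[bl$genotype, m]
    if (all(is.na(x)) || stats::var(x, na.rm = TRUE) == 0) {
      stop("marker is monomorphic: ", m, call. = FALSE)
    }
    m0 <- mean(bl$blue[!is.na(x) & x == 0])
    m1 <- mean(bl$blue[!is.na(x) & x == 1])
    tie <- isTRUE(all.equal(m0, m1))
    fav <- if (tie) 1 else if (m1 > m0) 1 else 0
    if (tie) message("tie in allele means for ", m, "; favorable set to allele 1")
    tibble::tibble(marker_id = m, favorable_allele = fav, peak_day = peak_day,
                   mean_allele0 = m0, mean_allele1 = m1, tie = tie)
  })
}

#' Allele-stacking groups and their standardized biomass trajectories
#'
#' For each named subset of QTL markers, assigns every genotype to
#' `all_favorable` (favorable allele at every member marker),
#' `all_unfavorable` (unfavorable at every member marker) or `other`
#' (mixed or missing calls), and attaches the per-day standardized biomass
#' so the groups can be tracked over time.
#'
#' @param standardized Output of [standardize_daily_biomass()].
#' @param panel A [genotype_panel()].
#' @param favorable Output of [assign_favorable_alleles()] (or a tibble
#'   `marker_id`, `favorable_allele`).
#' @param qtl_subsets Named list of character vectors of marker ids, e.g.
#'   `list(early = ..., late = ..., early_late = ...)`.
#' @return A `stacking_groups` list with `membership` (tibble `subset`,
#'   `genotype`, `group`), `trajectories` (per-genotype standardized
#'   series with group labels) and `group_means` (per subset, group and
#'   day).
#' @export
stacking_trajectories <- function(standardized, panel, favorable, qtl_subsets) {
  stopifnot(is.list(qtl_subsets), !is.null(names(qtl_subsets)))
  favorable <- tibble::as_tibble(favorable)
  membership <- purrr::imap_dfr(qtl_subsets, function(markers, name) {
    fav <- favorable$favorable_allele[match(markers, favorable$marker_id)]
    if (anyNA(fav)) stop("favorable allele missing for some subset markers",
                         call. = FALSE)
    calls <- panel$calls[, markers, drop = FALSE]
    hit <- sweep(calls, 2, fav, `==`)
    all_fav <- apply(hit, 1, function(r) all(!is.na(r)) && all(r))
    all_unf <- apply(hit, 1, function(r) all(!is.na(r)) && all(!r))
    tibble::tibble(
      subset = name, genotype = panel$genotype_ids,
      group = dplyr::case_when(all_fav ~ "all_favorable",
                               all_unf ~ "all_unfavorable",
                               TRUE ~ "other")
    )
  })
  trajectories <- dplyr::inner_join(membership, tibble::as_tibble(standardized),
                                    by = "genotype",
                                    relationship = "many-to-many")
  group_means <- trajectories |>
    dplyr::group_by(.data$subset, .data$group, .data$day) |>
    dplyr::summarise(mean_std_biomass = mean(.data$std_biomass),
                     n_genotypes = dplyr::n(), .groups = "drop")
  empty <- membership |>
    dplyr::count(.data$subset, .data$group) |>
    tidyr::complete(subset = names(qtl_subsets),
                    group = c("all_favorable", "all_unfavorable", "other"),
                    fill = list(n = 0L))
  structure(
    list(membership = membership, trajectories = trajectories,
         group_means = group_means, group_sizes = empty),
    class = "stacking_groups"
  )
}

#' @exportS3Method base::print
print.stacking_groups <- function(x, ...) {
  cat("<stacking_groups>\n")
  sz <- tidyr::pivot_wider(x$group_sizes, names_from = "group", values_from = "n")
  print(as.data.frame(sz), row.names = FALSE)
  invisible(x)
}
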