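#' Per-experiment BLUEs (step 1 of the two-step analysis)
#'
#' Fits the fixed-genotype model `value = genotype + error` separately
#' within each experiment, trait and day. Under the completely randomized
#' single-factor design this best linear unbiased estimate equals the
#' arithmetic mean of the genotype's unflagged replicate values, which is
#' what is computed. Records flagged by [detect_outliers()] (an `outlier`
#' column) and missing values are skipped; genotypes without any usable
#' observation in an experiment are absent from the output.
#'
#' @param records Phenotype tibble (`genotype`, `experiment`, `replicate`,
#'   `day`, `trait`, `value`, optional `outlier`).
#' @param traits,days Optional filters; default all traits/days present.
#' @return A tibble with columns `experiment`, `trait`, `day`, `genotype`,
#'   `blue`, `n_obs`.
#' @export
compute_blues_step1 <- function(records, traits = NULL, days = NULL) {
  records <- tibble::as_tibble(records)
  if (!"outlier" %in% names(records)) records$outlier <- FALSE
  if (!is.null(traits)) records <- dplyr::filter(records, .data$trait %in% traits)
  if (!is.null(days)) records <- dplyr::filter(records, .data$day %in% days)
  records |>
    dplyr::filter(!.data$outlier, !is.na(.data$value)) |>
    dplyr::group_by(.data$experiment, .data$trait, .data$day, .data$genotype) |>
    dplyr::summarise(blue = mean(.data$value), n_obs = dplyr::n(), .groups = "drop")
}

#' Across-experiment BLUEs (step 2 of the two-step analysis)
#'
#' Combines per-experiment BLUEs with the model
#' `blue = genotype (fixed) + experiment (random) + error`, estimating the
#' experiment variance by REML and returning the generalized-least-squares
#' genotype estimates. With balanced data (every genotype observed in
#' every experiment) these equal the plain genotype means of the step-1
#' BLUEs, and that fast path is used; unbalanced trait-days are fitted
#' with [lme4::lmer()]. A single experiment passes through unchanged with
#' a warning.
#'
#' @param step1 Output of [compute_blues_step1()].
#' @return A tibble with columns `trait`, `day`, `genotype`, `blue`,
#'   `n_experiments`.
#' @export
compute_blues_step2 <- function(step1) {
  step1 <- tibble::as_tibble(step1)
  single_warned <- FALSE
  fit_one <- function(df, key) {
    n_exp <- length(unique(df$experiment))
    if (n_exp < 2) {
      if (!single_warned) {
        warning("only one experiment supplies values; returning step-1 BLUEs",
                call. = FALSE)
        single_warned <<- TRUE
      }
      return(tibble::tibble(genotype = df$genotype, blue = df$blue,
                            n_experiments = 1L))
    }
    counts <- table(df$genotype, df$experiment)
    balanced <- all(counts == 1)
    if (balanced) {
      res <- df |>
        dplyr::group_by(.data$genotype) |>
        dplyr::summarise(blue = mean(.data$blue), .groups = "drop")
      return(tibble::tibble(genotype = res$genotype, blue = res$blue,
                            n_experiments = n_exp))
    }
    df$genotype <- factor(df$genotype)
    fit <- suppressMessages(lme4::lmer(
      blue ~ 0 + genotype + (1 | experiment), data = df,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)
    ))
    est <- lme4::fixef(fit)
    tibble::tibble(
      genotype = sub("^genotype", "", names(est)),
      blue = unname(est),
      n_experiments = n_exp
    )
  }
  step1 |>
    dplyr::group_by(.data$trait, .data$day) |>
    dplyr::group_modify(fit_one) |>
    dplyr::ungroup()
}

#' One-step variance components for a trait-day
#'
#' Fits the fully random model
#' `value = genotype + experiment + genotype:experiment + error` by REML
#' on the (unflagged) plot-level records of one trait and day, and returns
#' the genotypic, genotype-by-experiment and residual variance components
#' together with the design constants entering the heritability formula:
#' `O`, the number of experiments observed for that day, and `R`, the
#' median number of replicates per genotype-experiment cell.
#'
#' @param records Phenotype tibble; an `outlier` column is honoured.
#' @param trait,day Trait label and day to analyse (`day = NULL` pools all
#'   days present for the trait, for endpoint traits stored on one day).
#' @return A `variance_components` list with elements `V_G`, `V_GE`,
#'   `V_e`, `O`, `R`, `trait`, `day`, `n_genotypes`.
#' @export
estimate_variance_components <- function(records, trait, day = NULL) {
  records <- tibble::as_tibble(records)
  if (!"outlier" %in% names(records)) records$outlier <- FALSE
  df <- dplyr::filter(records, .data$trait == !!trait, !.data$outlier,
                      !is.na(.data$value))
  if (!is.null(day)) df <- dplyr::filter(df, .data$day == !!day)
  n_exp <- length(unique(df$experiment))
  n_gen <- length(unique(df$genotype))
  if (n_exp < 2) stop("need >= 2 experiments to separate V_GE", call. = FALSE)
  if (n_gen < 10) stop("need >= 10 genotypes for variance components", call. = FALSE)
  cell <- dplyr::count(df, .data$genotype, .data$experiment)
  if (stats::median(cell$n) < 2) stop("need >= 2 replicates per cell", call. = FALSE)
  form <- value ~ 1 + (1 | genotype) + (1 | experiment) +
    (1 | genotype:experiment)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(lme4::lmer(form, data = df, control = ctrl))
  # polish the REML optimum: the profiled deviance is re-minimized from the
  # lmer solution at tight tolerance so balanced fits agree with the
  # closed-form ANOVA estimators to high precision
  devfun <- suppressMessages(lme4::lmer(form, data = df, control = ctrl,
                                        devFunOnly = TRUE))
  theta <- lme4::getME(fit, "theta")
  opt <- stats::optim(theta, devfun, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 10000))
  theta <- abs(opt$par)
  devfun(theta)
  rho <- environment(devfun)
  sigma2 <- (rho$resp$wrss() + rho$pp$sqrL(1)) / (nrow(df) - 1L)
  vcs <- theta^2 * sigma2
  pick <- function(g) {
    v <- vcs[startsWith(names(vcs), paste0(g, "."))]
    if (length(v)) max(v, 0) else 0
  }
  structure(
    list(
      V_G = pick("genotype"), V_GE = pick("genotype:experiment"),
      V_e = sigma2, O = n_exp, R = stats::median(cell$n),
      trait = trait, day = day, n_genotypes = n_gen
    ),
    class = "variance_components"
  )
}

#' @exportS3Method base::print
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> trait=%s day=%s\n", x$trait,
              if (is.null(x$day)) "all" else x$day))
  cat(sprintf("  V_G=%.4g V_GE=%.4g V_e=%.4g (O=%d experiments, R=%g replicates)\n",
              x$V_G, x$V_GE, x$V_e, x$O, x$R))
  invisible(x)
}

#' Broad-sense heritability from variance components
#'
#' Computes \eqn{H^2 = V_G / (V_G + V_{GE}/O + V_e/(O R))}, the share of
#' the variance of a genotype mean (over `O` experiments and `R`
#' replicates each) attributable to genotype.
#'
#' @param vc A `variance_components` object from
#'   [estimate_variance_components()], or a list with fields `V_G`,
#'   `V_GE`, `V_e`, `O`, `R`.
#' @return A tibble with columns `trait`, `day`, `V_G`, `V_GE`, `V_e`,
#'   `O`, `R`, `H2`.
#' @export
broad_sense_heritability <- function(vc) {
  stopifnot(all(c("V_G", "V_GE", "V_e", "O", "R") %in% names(vc)))
  if (any(c(vc$V_G, vc$V_GE, vc$V_e) < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  denom <- vc$V_G + vc$V_GE / vc$O + vc$V_e / (vc$O * vc$R)
  if (denom <= 0) stop("heritability undefined: all variance components zero",
                       call. = FALSE)
  tibble::tibble(
    trait = vc$trait %||% NA_character_,
    day = if (is.null(vc$day)) NA_real_ else vc$day,
    V_G = vc$V_G, V_GE = vc$V_GE, V_e = vc$V_e, O = vc$O, R = vc$R,
    H2 = vc$V_G / denom
  )
}

#' Heritability trajectory over days
#'
#' Convenience wrapper running [estimate_variance_components()] and
#' [broad_sense_heritability()] for each requested day of a trait.
#'
#' @inheritParams estimate_variance_components
#' @param days Days to analyse; default all days present for the trait.
#' @return A tibble, one row per day, as in [broad_sense_heritability()].
#' @export
heritability_by_day <- function(records, trait, days = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(days)) {
    days <- sort(unique(records$day[records$trait == trait]))
  }
  purrr::map_dfr(days, function(d) {
    broad_sense_heritability(estimate_variance_components(records, trait, d))
  })
}
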