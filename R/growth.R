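#' Fit the three-parameter logistic growth law to a biomass series
#'
#' Fits \eqn{f(t) = a / (1 + b e^{-c t})} by nonlinear least squares
#' (Levenberg-Marquardt via [minpack.lm::nlsLM()], parameters bounded
#' below at `1e-8`, up to 500 iterations). Starting values are
#' self-determined: `a0 = 1.05 * max(value)`, `(b0, c0)` from an ordinary
#' regression of `log(a0 / value - 1)` on day (the log-linearization of
#' the logistic).
#'
#' @param day,value Numeric vectors of observation days and non-negative
#'   biomass values (at least 5 points spanning at least 10 days).
#' @return A `logistic_fit` list: `a`, `b`, `c`, `t0` (inflection point
#'   `log(b)/c` in days), `rss`, `converged`, `n`.
#' @export
fit_logistic <- function(day, value) {
  keep <- !is.na(day) & !is.na(value)
  day <- as.numeric(day[keep]); value <- as.numeric(value[keep])
  if (length(day) < 5) stop("insufficient data: need >= 5 points", call. = FALSE)
  if (diff(range(day)) < 10) stop("series must span >= 10 days", call. = FALSE)
  if (any(value < 0)) stop("biomass values must be >= 0", call. = FALSE)
  if (stats::sd(value) == 0) {
    stop("degenerate series: constant values, logistic parameters not identifiable",
         call. = FALSE)
  }

  a0 <- 1.05 * max(value)
  z <- a0 / pmax(value, 1e-12) - 1
  ok <- z > 0 & is.finite(log(z))
  if (sum(ok) >= 2) {
    lin <- stats::lm(log(z[ok]) ~ day[ok])
    c0 <- max(-unname(stats::coef(lin)[2]), 1e-3)
    b0 <- max(exp(unname(stats::coef(lin)[1])), 1e-3)
  } else {
    c0 <- 0.1
    b0 <- max(a0 / max(value[1], 1e-8) - 1, 1e-3)
  }

  df <- data.frame(day = day, value = value)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ a / (1 + b * exp(-c * day)), data = df,
      start = list(a = a0, b = b0, c = c0),
      lower = rep(1e-8, 3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    stop("logistic fit failed: optimizer did not produce a solution", call. = FALSE)
  }
  cf <- stats::coef(fit)
  converged <- fit$convInfo$isConv %||% TRUE
  structure(
    list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
         t0 = log(unname(cf["b"])) / unname(cf["c"]),
         rss = sum(stats::resid(fit)^2), converged = isTRUE(converged),
         n = length(day)),
    class = "logistic_fit"
  )
}

#' @exportS3Method base::print
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> a=%.4g b=%.4g c=%.4g  t0=%.2f days  rss=%.3g (%s)\n",
    x$a, x$b, x$c, x$t0, x$rss, if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Inflection point of a fitted logistic curve
#'
#' The day of maximum growth rate, \eqn{t_0 = \ln(b) / c} (natural
#' logarithm), which is the analytic argmax of the derivative of
#' \eqn{a / (1 + b e^{-c t})}.
#'
#' @param fit A `logistic_fit`, or a list with positive elements `b`, `c`.
#' @return The inflection point in days.
#' @export
inflection_point <- function(fit) {
  if (is.null(fit$b) || is.null(fit$c) || fit$b <= 0 || fit$c <= 0) {
    stop("invalid parameters: b and c must be positive", call. = FALSE)
  }
  log(fit$b) / fit$c
}

#' Fit logistic growth curves to every series in a BLUE or phenotype table
#'
#' Groups the table by the identifier columns present (any of `genotype`,
#' `experiment`, `replicate`) and fits [fit_logistic()] to each series.
#' Series that fail (too short, constant) are reported with `NA`
#' parameters and `converged = FALSE`.
#'
#' @param data Tibble with a `day` column and a `blue` or `value` column;
#'   typically step-1 BLUEs of digital biomass.
#' @param trait If a `trait` column is present, which trait to fit.
#' @return A tibble with one row per series: identifier columns plus
#'   `a`, `b`, `c`, `t0`, `rss`, `converged`, `n`.
#' @export
fit_growth <- function(data, trait = "digital_biomass") {
  data <- tibble::as_tibble(data)
  if ("trait" %in% names(data)) data <- dplyr::filter(data, .data$trait == !!trait)
  val_col <- intersect(c("blue", "value"), names(data))[1]
  if (is.na(val_col)) stop("need a 'blue' or 'value' column", call. = FALSE)
  id_cols <- intersect(c("genotype", "experiment", "replicate"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::group_modify(function(df, key) {
      res <- tryCatch(fit_logistic(df$day, df[[val_col]]), error = function(e) NULL)
      if (is.null(res)) {
        tibble::tibble(a = NA_real_, b = NA_real_, c = NA_real_, t0 = NA_real_,
                       rss = NA_real_, converged = FALSE, n = nrow(df))
      } else {
        tibble::tibble(a = res$a, b = res$b, c = res$c, t0 = res$t0,
                       rss = res$rss, converged = res$converged, n = res$n)
      }
    }) |>
    dplyr::ungroup()
}
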