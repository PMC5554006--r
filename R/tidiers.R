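#' Tidy a logistic growth fit
#'
#' @param x A `logistic_fit` from [fit_logistic()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`a`, `b`, `c`, `t0`).
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "t0"),
                 estimate = c(x$a, x$b, x$c, x$t0))
}

#' @rdname tidy.logistic_fit
#' @return `glance()`: a one-row tibble with `rss`, `converged`, `n`.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n = x$n)
}

#' Tidy variance components
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @return A tibble with one row per component.
#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(
    component = c("V_G", "V_GE", "V_e"),
    variance = c(x$V_G, x$V_GE, x$V_e)
  )
}

#' @rdname tidy.variance_components
#' @export
glance.variance_components <- function(x, ...) {
  broad_sense_heritability(x)
}

#' Tidy a power-simulation result
#'
#' @param x A `power_result` from [run_power_simulation()].
#' @param ... Unused.
#' @return The per-QTL detection-rate tibble.
#' @export
tidy.power_result <- function(x, ...) x$per_qtl

#' @rdname tidy.power_result
#' @export
glance.power_result <- function(x, ...) {
  tibble::tibble(
    n_reps = x$settings$n_reps, q = x$settings$q, h2 = x$settings$h2,
    detection_window_cM = x$settings$detection_window_cM,
    mean_detection_rate = mean(x$per_qtl$detection_rate)
  )
}

#' Tidy a variance-explained result
#'
#' @param x A `variance_explained` object.
#' @param ... Unused.
#' @return The per-marker tibble with the combined row appended.
#' @export
tidy.variance_explained <- function(x, ...) {
  dplyr::bind_rows(
    x$individual,
    tibble::tibble(marker_id = "(combined)", adj_r2 = x$combined_adj_r2,
                   var_explained = x$combined)
  )
}
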