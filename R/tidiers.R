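#' @importFrom generics tidy glance
NULL

#' Tidy and glance methods for invaderkit result objects
#'
#' Broom-style accessors: `tidy()` returns a tibble with one row per
#' component of the result; `glance()` returns a one-row summary.
#'
#' @param x An `invasion_result`, `es_rate` or `resident_cycle` object.
#' @param ... Unused.
#' @return A tibble.
#' @name invaderkit-tidiers
NULL

#' @rdname invaderkit-tidiers
#' @export
tidy.invasion_result <- function(x, ...) {
  k <- seq_along(x$u)
  tibble::tibble(mutants = k, u = x$u, q = x$q, omega = x$omega)
}

#' @rdname invaderkit-tidiers
#' @export
glance.invasion_result <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, lineage_fitness = x$lineage_fitness,
                 relatedness = x$relatedness,
                 n = x$spec$n, m = x$spec$m, delta = x$spec$delta)
}

#' @rdname invaderkit-tidiers
#' @export
tidy.es_rate <- function(x, ...) x$gradient

#' @rdname invaderkit-tidiers
#' @export
glance.es_rate <- function(x, ...) {
  tibble::tibble(mu_star = x$mu_star, method = x$method,
                 uninvadable = x$uninvadable, max_lambda = x$max_lambda)
}

#' @rdname invaderkit-tidiers
#' @export
tidy.resident_cycle <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$states), freq_A1 = x$states)
}

#' @rdname invaderkit-tidiers
#' @export
glance.resident_cycle <- function(x, ...) {
  tibble::tibble(period = length(x$states), residual = x$residual,
                 converged = x$converged, mu = x$mu)
}

#' @export
print.invasion_result <- function(x, ...) {
  cat("<invasion_result>\n")
  cat(sprintf("  lambda      = %.8g\n", x$lambda))
  cat(sprintf("  relatedness = %s\n",
              ifelse(is.finite(x$relatedness),
                     sprintf("%.6g", x$relatedness), "undefined (n = 1)")))
  invisible(x)
}

#' @export
print.es_rate <- function(x, ...) {
  cat("<es_rate>\n")
  cat(sprintf("  mu_star = %.6g (%s)\n", x$mu_star, x$method))
  cat(sprintf("  uninvadable over scanned grid: %s (max lambda %.8g)\n",
              x$uninvadable, x$max_lambda))
  invisible(x)
}

#' @importFrom rlang .data
NULL
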