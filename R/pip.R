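#' Build a pairwise invasibility plot grid
#'
#' Evaluates an invasion-fitness function `lambda(mutant, resident)` over the
#' product of a resident and a mutant grid. Invasion fitness is the
#' per-generation geometric growth rate of a rare mutant lineage; the mutant
#' can invade where `lambda > 1` and cannot where `lambda < 1`, and the
#' diagonal (mutant equal to resident) is neutral, `lambda = 1`.
#'
#' @param fitness_fn Function of `(mutant, resident)` returning a single
#'   finite positive invasion fitness.
#' @param resident_values,mutant_values Ordered numeric grids.
#' @param tol Neutrality tolerance used for the `invades` mask on the
#'   diagonal.
#' @return A tibble of class `pip_grid` with columns `resident`, `mutant`,
#'   `lambda` and `invades` (`lambda > 1 + tol`), one row per grid point.
#' @examples
#' W <- payoff_matrix(1, 3, 4, 0)  # Hawk-Dove, interior ESS at 0.5
#' g <- pip(function(y, x) relative_fitness(y, x, W),
#'          seq(0, 1, length.out = 11), seq(0, 1, length.out = 11))
#' @export
pip <- function(fitness_fn, resident_values, mutant_values = resident_values,
                tol = 1e-9) {
  stopifnot(is.function(fitness_fn), length(resident_values) > 0,
            length(mutant_values) > 0)
  grid <- tidyr::expand_grid(resident = as.double(resident_values),
                             mutant = as.double(mutant_values))
  lam <- purrr::map2_dbl(grid$mutant, grid$resident, fitness_fn)
  bad <- !is.finite(lam)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("non-finite invasion fitness at mutant = %g, resident = %g",
                 grid$mutant[i], grid$resident[i]), call. = FALSE)
  }
  out <- dplyr::mutate(grid, lambda = lam, invades = lam > 1 + tol)
  class(out) <- c("pip_grid", class(out))
  out
}

#' Plot a pairwise invasibility grid
#'
#' Renders the classic black/white pairwise invasibility plot: white where the
#' mutant invades (`lambda > 1`) and black where it cannot.
#'
#' @param object A `pip_grid` from [pip()] or [modifier_pip()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pip_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resident, y = .data$mutant,
                                       fill = .data$invades)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "white", `FALSE` = "black"),
                               name = expression(lambda > 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "resident", y = "mutant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write / read a pairwise invasibility grid as TSV
#'
#' The on-disk layout is a matrix block: the first row holds the resident grid
#' values, the first column the mutant grid values, and the body the
#' invasion-fitness values (rows = mutant, columns = resident), written to 15
#' significant digits (round-trips are lossless well beyond 12). Header comment lines (prefixed `#`) carry provenance
#' such as model parameters and the seed.
#'
#' @param grid A `pip_grid` tibble.
#' @param path Output file path.
#' @param header Named character or numeric vector written as `# key: value`
#'   comment lines.
#' @return `write_pip()` returns `path` invisibly; `read_pip()` returns a
#'   `pip_grid` tibble with the header stored in attribute `"header"`.
#' @export
write_pip <- function(grid, path, header = NULL) {
  stopifnot(inherits(grid, "pip_grid"), nrow(grid) > 0)
  if (any(!is.finite(grid$lambda))) {
    stop("grid contains non-finite invasion-fitness values", call. = FALSE)
  }
  res <- sort(unique(grid$resident))
  mut <- sort(unique(grid$mutant))
  lam <- matrix(NA_real_, length(mut), length(res))
  lam[cbind(match(grid$mutant, mut), match(grid$resident, res))] <- grid$lambda
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  lines <- character(0)
  header <- c(package = paste0("invaderkit ",
                               as.character(utils::packageVersion("invaderkit"))),
              header)
  lines <- c(lines, sprintf("# %s: %s", names(header), as.character(header)))
  lines <- c(lines, paste(c("", fmt(res)), collapse = "\t"))
  body <- vapply(seq_along(mut), function(i) {
    paste(c(fmt(mut[i]), fmt(lam[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_pip
#' @export
read_pip <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(body) < 2L) stop("malformed PIP file: no matrix block", call. = FALSE)
  parse_row <- function(ln, i) {
    x <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v[-1L])) {
      stop(sprintf("malformed PIP file at line %d", i), call. = FALSE)
    }
    v
  }
  res <- parse_row(body[1L], length(hdr) + 1L)[-1L]
  rows <- lapply(seq_along(body[-1L]), function(i) {
    parse_row(body[i + 1L], length(hdr) + 1L + i)
  })
  mut <- vapply(rows, `[`, numeric(1), 1L)
  lam <- do.call(rbind, lapply(rows, `[`, -1L))
  out <- tidyr::expand_grid(resident = res, mutant = mut)
  out$lambda <- as.vector(lam[cbind(match(out$mutant, mut),
                                    match(out$resident, res))])
  out$invades <- out$lambda > 1 + 1e-9
  class(out) <- c("pip_grid", class(out))
  attr(out, "header") <- sub("^# ", "", hdr)
  out
}
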