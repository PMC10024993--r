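#' Random model fixtures
#'
#' Deterministic (seeded) generators for random test models: 2x2 games with a
#' prescribed pay-off ordering, symmetric genotype-phenotype maps for the
#' one- and two-locus models, and random island-model kernels. Generation
#' uses the current RNG state; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @param class Ordering class of the game: `"prisoners_dilemma"`
#'   (w01 > w11 > w00 > w10), `"hawk_dove"` (w01 > w11 > w10 > w00) or
#'   `"any"` (unconstrained positive pay-offs).
#' @param seed Optional integer seed applied before drawing.
#' @return `random_game()`: a [payoff_matrix()] satisfying the requested
#'   ordering.
#' @export
random_game <- function(class = c("any", "prisoners_dilemma", "hawk_dove"),
                        seed = NULL) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  v <- sort(stats::runif(4, 0.1, 10))  # ascending distinct positive values
  switch(class,
         any = {
           v <- stats::runif(4, 0.1, 10)
           payoff_matrix(v[1], v[2], v[3], v[4])
         },
         # w01 > w11 > w00 > w10
         prisoners_dilemma = payoff_matrix(w11 = v[3], w10 = v[1],
                                           w01 = v[4], w00 = v[2]),
         # w01 > w11 > w10 > w00
         hawk_dove = payoff_matrix(w11 = v[3], w10 = v[2],
                                   w01 = v[4], w00 = v[1]))
}

#' @rdname random_game
#' @param a,b Allele counts at the two loci.
#' @param R Recombination rate for the two-locus map; drawn uniformly on
#'   (0, 0.5] when `NULL`.
#' @param W Pay-off matrix; a random game of class `class` when `NULL`.
#' @return `random_gp_map()`: a [two_locus_model()] with a symmetric random
#'   phenotype tensor.
#' @export
random_gp_map <- function(a = 2, b = 2, R = NULL, W = NULL,
                          class = "any", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(W)) W <- random_game(class)
  if (is.null(R)) R <- stats::runif(1, 0.01, 0.5)
  xg <- array(stats::runif(a * b * a * b), dim = c(a, b, a, b))
  xg <- (xg + aperm(xg, c(3, 4, 1, 2))) / 2  # impose genotype symmetry
  two_locus_model(xg, R, W)
}

#' @rdname random_game
#' @return `random_diploid_model()`: a [diploid_locus_model()] with a random
#'   symmetric genotype-phenotype matrix.
#' @export
random_diploid_model <- function(a = 2, W = NULL, class = "any", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(W)) W <- random_game(class)
  x <- matrix(stats::runif(a * a), a, a)
  diploid_locus_model((x + t(x)) / 2, W)
}

#' @rdname random_game
#' @param n Group size.
#' @return `random_group_kernel()`: a [group_model()] with the linear kernel
#'   and random coefficients, phenotypes and demography.
#' @export
random_group_kernel <- function(n = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- sample(1:4, 1)
  group_model(n = n,
              m = stats::runif(1, 0.1, 1),
              delta = stats::runif(1, 0, 0.2),
              y = stats::runif(1), xhat = stats::runif(1),
              kernel = "linear",
              alpha = stats::runif(1, -1, 1),
              beta = stats::runif(1, -1, 1))
}
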