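#' Construct a 2x2 pay-off matrix for a two-strategy game
#'
#' Collects the four pay-offs of a symmetric pairwise game between the pure
#' strategies "always C" (phenotype 1) and "always D" (phenotype 0).
#' `wIJ` is the pay-off to an individual playing pure strategy I against a
#' partner playing pure strategy J.
#'
#' @param w11,w10,w01,w00 Finite real pay-offs; `w10` is the pay-off to a
#'   C-player meeting a D-player, and so on.
#' @return An object of class `payoff_matrix` (a named numeric vector).
#' @examples
#' W <- payoff_matrix(w11 = 3, w10 = 0, w01 = 5, w00 = 1)  # Prisoner's Dilemma
#' classify_game(W)
#' @export
payoff_matrix <- function(w11, w10, w01, w00) {
  w <- c(w11 = w11, w10 = w10, w01 = w01, w00 = w00)
  if (!is.numeric(w) || length(w) != 4L || any(!is.finite(w))) {
    stop("all four pay-offs must be finite numbers", call. = FALSE)
  }
  structure(as.double(w), names = names(w), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  m <- matrix(x[c("w11", "w10", "w01", "w00")], 2, 2, byrow = TRUE,
              dimnames = list(self = c("C", "D"), partner = c("C", "D")))
  cat("<payoff_matrix> (", classify_game(x), ")\n", sep = "")
  print(m)
  invisible(x)
}

as_payoff_matrix <- function(W) {
  if (inherits(W, "payoff_matrix")) return(W)
  if (is.numeric(W) && length(W) == 4L) {
    return(payoff_matrix(W[[1L]], W[[2L]], W[[3L]], W[[4L]]))
  }
  stop("`W` must be a payoff_matrix or a numeric vector (w11, w10, w01, w00)",
       call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  as.double(x)
}

#' Expected pay-off between two mixed strategies
#'
#' A mixed strategy `x` plays C with probability `x` and D otherwise. Fitness
#' is assumed linear in the behavioural probabilities, so the pay-off of `x`
#' against `y` is the bilinear extension
#' `w(x, y) = x*y*w11 + x*(1-y)*w10 + (1-x)*y*w01 + (1-x)*(1-y)*w00`.
#'
#' @param x,y Probabilities of choosing C (vectorised).
#' @param W A [payoff_matrix()].
#' @return Numeric pay-off(s) of `x` against `y`.
#' @export
payoff <- function(x, y, W) {
  W <- as_payoff_matrix(W)
  x <- check_prob(x, "x")
  y <- check_prob(y, "y")
  x * y * W[["w11"]] + x * (1 - y) * W[["w10"]] +
    (1 - x) * y * W[["w01"]] + (1 - x) * (1 - y) * W[["w00"]]
}

#' Relative fitness of a rare mutant strategy
#'
#' The relative fitness `omega(y, x) = w(y, x) / w(x, x)` of a rare mutant
#' playing `y` in a resident population playing `x`. The resident mean
#' pay-off `w(x, x)` must be positive for the ratio to be interpretable as a
#' geometric growth rate; a strategy `x` is a strict ESS exactly when
#' `omega(y, x) < 1` for every `y != x`.
#'
#' @inheritParams payoff
#' @param y Mutant strategy; `x` resident strategy.
#' @return Numeric relative fitness.
#' @export
relative_fitness <- function(y, x, W) {
  W <- as_payoff_matrix(W)
  wres <- payoff(x, x, W)
  if (any(wres <= 0)) {
    stop("resident mean pay-off w(x, x) must be positive", call. = FALSE)
  }
  payoff(y, x, W) / wres
}

#' Classify the ordering of a 2x2 game
#'
#' Labels `prisoners_dilemma` when w01 > w11 > w00 > w10, `hawk_dove` when
#' w01 > w11 > w10 > w00, and `other` otherwise.
#'
#' @inheritParams payoff
#' @return A string label.
#' @export
classify_game <- function(W) {
  W <- as_payoff_matrix(W)
  if (W[["w01"]] > W[["w11"]] && W[["w11"]] > W[["w00"]] && W[["w00"]] > W[["w10"]]) {
    "prisoners_dilemma"
  } else if (W[["w01"]] > W[["w11"]] && W[["w11"]] > W[["w10"]] && W[["w10"]] > W[["w00"]]) {
    "hawk_dove"
  } else {
    "other"
  }
}
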