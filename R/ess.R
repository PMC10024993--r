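#' Classify a strategy as a strict ESS, weak ESS, or neither
#'
#' A resident strategy `x*` is evolutionarily stable when every rare
#' alternative `y` does worse against the resident than the resident does
#' against itself (`w(x*, x*) > w(y, x*)`, strict ESS), or ties against the
#' resident but loses against itself (`w(x*, x*) = w(y, x*)` and
#' `w(x*, y) > w(y, y)`, weak ESS). Because pay-off is linear in the mutant
#' strategy, it suffices to check the pure alternatives `y = 0` and `y = 1`:
#' the first-order margin `w(x*, x*) - w(y, x*)` is linear in `y`, so its sign
#' over all of [0, 1] is determined at the endpoints, and the same holds for
#' the tie-breaking margin restricted to the tying face.
#'
#' @param x Resident strategy, probability of choosing C.
#' @param W A [payoff_matrix()].
#' @param tol Equality tolerance: margins with absolute value at most `tol`
#'   count as ties.
#' @return A tibble (class `ess_report`) with one row per checked alternative
#'   `y`: columns `x`, `y`, `margin1` (`w(x,x) - w(y,x)`), `margin2`
#'   (`w(x,y) - w(y,y)`) and the overall `ess_class` (one of `"strict"`,
#'   `"weak"`, `"none"`), repeated on every row.
#' @examples
#' classify_strategy(0, payoff_matrix(3, 0, 5, 1))  # PD: defection is strict
#' @export
classify_strategy <- function(x, W, tol = 1e-9) {
  W <- as_payoff_matrix(W)
  x <- check_prob(x, "x")
  stopifnot(length(x) == 1L, tol > 0)
  y <- c(0, 1)
  y <- y[abs(y - x) > tol]  # alternatives distinct from the resident
  if (length(y) == 0L) y <- c(0, 1)[which.max(abs(c(0, 1) - x))]
  margin1 <- payoff(x, x, W) - payoff(y, x, W)
  margin2 <- payoff(x, y, W) - payoff(y, y, W)
  # A pure alternative equal to x itself is vacuously non-invading.
  self <- abs(y - x) <= tol
  strict_ok <- self | (margin1 > tol)
  weak_ok <- self | (margin1 > tol) | (abs(margin1) <= tol & margin2 > tol)
  ess_class <- if (all(strict_ok)) "strict" else if (all(weak_ok)) "weak" else "none"
  out <- tibble::tibble(x = x, y = y, margin1 = margin1, margin2 = margin2,
                        ess_class = ess_class)
  class(out) <- c("ess_report", class(out))
  out
}

#' Find all evolutionarily stable strategies of a 2x2 game
#'
#' Evaluates the two pure strategies and, when it lies strictly inside (0, 1),
#' the interior candidate `x* = (w10 - w00) / (w10 - w00 + w01 - w11)` (the
#' mixed strategy at which both behaviours earn equal pay-off against the
#' resident). Candidates classifying as strict or weak ESS are returned.
#'
#' @inheritParams classify_strategy
#' @return A tibble with columns `x` (the ESS strategy), `ess_class`, and
#'   `interior` (logical). Zero rows when the game has no ESS among the
#'   candidates (e.g. a fully neutral game). When the interior candidate's
#'   denominator is degenerate (within `tol` of zero) the candidate is skipped
#'   and the result carries attribute `degenerate_interior = TRUE`.
#' @examples
#' find_ess(payoff_matrix(3, 0, 5, 1))   # PD: x* = 0
#' find_ess(payoff_matrix(1, 3, 4, 0))   # Hawk-Dove: x* = 0.5
#' @export
find_ess <- function(W, tol = 1e-9) {
  W <- as_payoff_matrix(W)
  denom <- (W[["w10"]] - W[["w00"]]) + (W[["w01"]] - W[["w11"]])
  degenerate <- abs(denom) <= tol
  candidates <- c(0, 1)
  interior <- logical(2)
  if (!degenerate) {
    xi <- (W[["w10"]] - W[["w00"]]) / denom
    # interior candidates within tol of a corner merge with that corner
    if (xi > tol && xi < 1 - tol) {
      candidates <- c(candidates, xi)
      interior <- c(interior, TRUE)
    }
  }
  cls <- vapply(candidates, function(x) {
    classify_strategy(x, W, tol = tol)$ess_class[1L]
  }, character(1))
  keep <- cls %in% c("strict", "weak")
  out <- tibble::tibble(x = candidates[keep], ess_class = cls[keep],
                        interior = interior[keep])
  attr(out, "degenerate_interior") <- degenerate
  out
}
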