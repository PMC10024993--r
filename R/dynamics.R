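#' Haploid two-genotype selection step
#'
#' One generation of selection in a haploid asexual population with two
#' genotypes: phenotype 1 (always C, frequency `p`) and phenotype 0 (always
#' D). Pairs form at random, so a genotype's marginal fitness is its pay-off
#' against the population mean phenotype, which equals `p` itself:
#' `p' = p * w(1, p) / wbar` with `wbar = p*w(1,p) + (1-p)*w(0,p)`.
#'
#' @param p Frequency of the always-C genotype.
#' @param W A [payoff_matrix()].
#' @return Updated frequency `p'`.
#' @export
haploid_step <- function(p, W) {
  W <- as_payoff_matrix(W)
  p <- check_prob(p, "p")
  w1 <- payoff(1, p, W)
  w0 <- payoff(0, p, W)
  wbar <- p * w1 + (1 - p) * w0
  if (any(wbar <= 0)) stop("mean fitness must be positive", call. = FALSE)
  clip_freq(p * w1 / wbar)
}

clip_freq <- function(p, tol = 1e-10) {
  lo <- pmin(p, 0); hi <- pmax(p - 1, 0)
  if (any(lo < -tol) || any(hi > tol)) {
    warning("frequencies clipped by more than 1e-10", call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Specify a diploid one-locus game model
#'
#' A single autosomal locus with `a` alleles controls a mixed strategy:
#' genotype `A_i A_j` chooses behaviour C with probability `xij[i, j]`.
#' Individuals interact in randomly formed pairs and mate at random.
#'
#' @param xij Symmetric `a x a` matrix of genotype phenotypes in [0, 1].
#' @param W A [payoff_matrix()].
#' @return An object of class `diploid_locus_model`.
#' @export
diploid_locus_model <- function(xij, W) {
  xij <- as.matrix(xij)
  if (nrow(xij) != ncol(xij) || !isTRUE(all.equal(xij, t(xij)))) {
    stop("`xij` must be a symmetric square matrix", call. = FALSE)
  }
  if (any(xij < 0 | xij > 1)) stop("genotype phenotypes must lie in [0, 1]",
                                   call. = FALSE)
  structure(list(a = nrow(xij), xij = xij, W = as_payoff_matrix(W)),
            class = "diploid_locus_model")
}

check_simplex <- function(p, n = NULL, tol = 1e-12) {
  if (!is.null(n) && length(p) != n) stop("allele-frequency vector has wrong length",
                                          call. = FALSE)
  if (any(p < -1e-14) || abs(sum(p) - 1) > 1e-8) {
    stop("frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  p
}

#' Mean phenotype under random mating
#'
#' The population mean probability of choosing C after random mating,
#' `x(p) = sum_ij p_i p_j x_ij`.
#'
#' @param p Allele-frequency vector.
#' @param model A [diploid_locus_model()].
#' @return Mean phenotype in [0, 1].
#' @export
mean_phenotype <- function(p, model) {
  stopifnot(inherits(model, "diploid_locus_model"))
  p <- check_simplex(p, model$a)
  as.numeric(t(p) %*% model$xij %*% p)
}

#' Diploid one-locus selection step
#'
#' One generation of the allele-frequency recursion under random mating
#' (Hardy-Weinberg genotype proportions each generation) and random pairwise
#' interactions: allele `A_i` has marginal fitness
#' `w_i = sum_j p_j w(x_ij, x(p))` and updates as `p_i' = p_i w_i / wbar`.
#'
#' @inheritParams mean_phenotype
#' @return Updated allele-frequency vector.
#' @export
diploid_step <- function(p, model) {
  stopifnot(inherits(model, "diploid_locus_model"))
  p <- check_simplex(p, model$a)
  xbar <- mean_phenotype(p, model)
  wgt <- payoff(as.vector(model$xij), xbar, model$W)
  wmat <- matrix(wgt, model$a, model$a)
  wi <- as.vector(wmat %*% p)
  wbar <- sum(p * wi)
  if (wbar <= 0) stop("mean fitness must be positive", call. = FALSE)
  out <- clip_freq(p * wi / wbar)
  out / sum(out)
}

#' Iterate a map to a fixed point
#'
#' Fixed-point iteration of a one-step map until the sup-norm change drops
#' below `tol` or `max_iter` is reached.
#'
#' @param step Function mapping a state to the next state.
#' @param start Initial state (numeric vector).
#' @param tol Convergence tolerance on the sup-norm change per step.
#' @param max_iter Iteration cap.
#' @return A list with elements `state`, `converged` (logical) and
#'   `iterations`.
#' @export
iterate_to_equilibrium <- function(step, start, tol = 1e-12, max_iter = 1e6) {
  stopifnot(tol > 0)
  state <- start
  for (i in seq_len(max_iter)) {
    nxt <- step(state)
    if (max(abs(nxt - state)) < tol) {
      return(list(state = nxt, converged = TRUE, iterations = i))
    }
    state <- nxt
  }
  warning("iteration did not converge within max_iter", call. = FALSE)
  list(state = state, converged = FALSE, iterations = max_iter)
}

#' Internal stability of an equilibrium (spectral radius of the Jacobian)
#'
#' Linearizes `step` at a fixed point by central finite differences,
#' restricted to the simplex tangent space (perturbations that keep the
#' frequency sum constant), and returns the spectral radius of the restricted
#' Jacobian. A value below 1 means the equilibrium is internally stable:
#' stable under the dynamics of the alleles already present.
#'
#' @param step One-step map on the frequency simplex (or on [0, 1] for the
#'   scalar haploid map).
#' @param equilibrium A fixed point of `step`.
#' @param h Finite-difference step.
#' @param fixed_point_tol Tolerance on `step(eq) - eq`.
#' @return The spectral radius (numeric scalar).
#' @export
internal_stability <- function(step, equilibrium, h = 1e-6,
                               fixed_point_tol = 1e-8) {
  stopifnot(h > 0)
  eq <- equilibrium
  if (max(abs(step(eq) - eq)) > fixed_point_tol) {
    stop("`equilibrium` is not a fixed point of `step`", call. = FALSE)
  }
  n <- length(eq)
  if (n == 1L) {
    lo <- max(eq - h, 0); hi <- min(eq + h, 1)
    return(abs((step(hi) - step(lo)) / (hi - lo)))
  }
  # tangent basis e_i - e_n, i = 1..n-1; a tangent vector v (sum 0) has
  # coordinates v_1, ..., v_{n-1} in this basis
  J <- matrix(0, n, n - 1L)
  for (i in seq_len(n - 1L)) {
    d <- rep(0, n); d[i] <- 1; d[n] <- -1
    # largest symmetric step keeping both perturbed points in the simplex
    room <- min(eq[i], 1 - eq[i], eq[n], 1 - eq[n])
    if (room >= h) {
      J[, i] <- (step(eq + h * d) - step(eq - h * d)) / (2 * h)
    } else {
      # boundary equilibrium: one-sided difference into the simplex
      s <- if (eq[i] <= eq[n]) 1 else -1
      J[, i] <- s * (step(eq + s * h * d) - step(eq)) / h
    }
  }
  Jt <- J[seq_len(n - 1L), , drop = FALSE]
  max(Mod(eigen(Jt, only.values = TRUE)$values))
}
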