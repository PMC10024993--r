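#' Enumerate group states for a class-structured group
#'
#' All vectors `k = (k_1, ..., k_c)` of per-class mutant counts with
#' `0 <= k_s <= n_s`, excluding the all-zero state, in lexicographic order
#' (last class varying fastest). The count is `prod(n_s + 1) - 1`.
#'
#' @param n_s Integer vector of residents per class per group.
#' @param cap Error when the state count exceeds this cap.
#' @return An integer matrix with one row per state.
#' @export
enumerate_group_states <- function(n_s, cap = 1e4) {
  stopifnot(all(n_s >= 1), all(n_s == round(n_s)))
  n_states <- prod(n_s + 1) - 1
  if (n_states > cap) {
    stop(sprintf("state space has %g states (cap %g); coarsen the classes",
                 n_states, cap), call. = FALSE)
  }
  grid <- do.call(expand.grid, rev(lapply(n_s, function(n) 0:n)))
  grid <- as.matrix(grid[, rev(seq_along(n_s)), drop = FALSE])
  dimnames(grid) <- NULL
  grid <- grid[order(apply(grid, 1, paste, collapse = ",")), , drop = FALSE]
  # lexicographic order on (k_1, ..., k_c)
  ord <- do.call(order, lapply(seq_along(n_s), function(j) grid[, j]))
  grid <- grid[ord, , drop = FALSE]
  grid[rowSums(grid) > 0, , drop = FALSE]
}

#' Specify a group-structured (island model) invasion problem
#'
#' An infinite-island Wright-Fisher model: infinitely many groups of `n`
#' haploid individuals, non-overlapping generations, fecundity selection with
#' intensity `delta` (fecundity `1 + delta * payoff`), juvenile migration at
#' probability `m` after reproduction, and competition for the `n` adult
#' slots of each group among philopatric juveniles (weight `1 - m`) and
#' immigrant juveniles (weight `m`, drawn from the global, effectively
#' all-resident pool while the mutant is globally rare).
#'
#' Two built-in payoff kernels are available: `"game"`, where an individual's
#' payoff is the average of a 2x2 matrix game [payoff()] against its
#' groupmates (against the resident population when `n = 1`), and
#' `"linear"`, where payoff is `alpha * own + beta * mean(groupmates)`.
#'
#' @param n Group size (single demographic class).
#' @param m Migration probability in (0, 1].
#' @param delta Selection intensity, `delta >= 0`.
#' @param y,xhat Mutant and resident phenotypes in [0, 1].
#' @param W A [payoff_matrix()] (kernel `"game"`).
#' @param kernel `"game"` or `"linear"`.
#' @param alpha,beta Linear-kernel coefficients (kernel `"linear"`).
#' @return An object of class `group_model`.
#' @examples
#' spec <- group_model(n = 2, m = 0.5, delta = 0.01, y = 1, xhat = 0,
#'                     W = payoff_matrix(3, 0, 5, 1))
#' invasion_analysis(spec)$lambda
#' @export
group_model <- function(n, m, delta, y, xhat, W = NULL, kernel = c("game", "linear"),
                        alpha = NULL, beta = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(n >= 1, n == round(n), m > 0, m <= 1, delta >= 0)
  y <- check_prob(y, "y"); xhat <- check_prob(xhat, "xhat")
  if (kernel == "game") {
    W <- as_payoff_matrix(W)
  } else if (is.null(alpha) || is.null(beta)) {
    stop("linear kernel requires `alpha` and `beta`", call. = FALSE)
  }
  structure(list(n = as.integer(n), m = m, delta = delta, y = y, xhat = xhat,
                 W = W, kernel = kernel, alpha = alpha, beta = beta),
            class = "group_model")
}

# payoff of an individual with phenotype z against groupmates with phenotypes
# zmates (length n - 1); for n = 1 the partner pool is the resident population
group_payoff <- function(z, zmates, spec) {
  if (length(zmates) == 0L) {
    partner <- spec$xhat
    if (spec$kernel == "game") return(payoff(z, partner, spec$W))
    return(spec$alpha * z + spec$beta * partner)
  }
  if (spec$kernel == "game") mean(payoff(z, zmates, spec$W))
  else spec$alpha * z + spec$beta * mean(zmates)
}

# relative fitness (expected adult offspring) of a focal individual with
# phenotype zf in a group whose other members have phenotypes zmates, in an
# otherwise-resident population; returns the philopatric + emigrant total
group_omega <- function(zf, zmates, spec) {
  n <- spec$n; m <- spec$m; delta <- spec$delta
  f <- function(z, mates) 1 + delta * group_payoff(z, mates, spec)
  all_z <- c(zf, zmates)
  fec <- vapply(seq_along(all_z), function(i) {
    f(all_z[i], all_z[-i])
  }, numeric(1))
  f0 <- 1 + delta * group_payoff(spec$xhat, rep(spec$xhat, n - 1L), spec)
  if (any(fec <= 0) || f0 <= 0) stop("kernel produced non-positive fecundity",
                                     call. = FALSE)
  denom <- (1 - m) * sum(fec) + m * n * f0
  n * (1 - m) * fec[1L] / denom + m * fec[1L] / f0
}

# per-state quantities of the built-in single-class island kernel
island_state <- function(k, spec) {
  n <- spec$n; m <- spec$m; delta <- spec$delta
  zmut <- c(rep(spec$y, k - 1L), rep(spec$xhat, n - k))
  f_mut <- 1 + delta * group_payoff(spec$y, zmut, spec)
  f_res <- if (k < n) {
    zres <- c(rep(spec$y, k), rep(spec$xhat, n - k - 1L))
    1 + delta * group_payoff(spec$xhat, zres, spec)
  } else NA_real_
  f0 <- 1 + delta * group_payoff(spec$xhat, rep(spec$xhat, n - 1L), spec)
  if (f_mut <= 0 || f0 <= 0 || (k < n && f_res <= 0)) {
    stop("kernel produced non-positive fecundity", call. = FALSE)
  }
  denom <- (1 - m) * (k * f_mut + (n - k) * ifelse(k < n, f_res, 0)) + m * n * f0
  phi <- (1 - m) * k * f_mut / denom          # mutant win prob per local slot
  emig <- m * k * f_mut / f0                  # expected emigrant settlers
  omega <- (n * phi + emig) / k               # per-capita mutant fitness
  list(phi = phi, emig = emig, omega = omega)
}

#' Build the rare-mutant projection matrix for the island model
#'
#' For each group state `k` (number of mutants, `1..n`), the next generation
#' of the same group has `Binomial(n, phi_k)` mutants, where `phi_k` is the
#' probability a local slot is won by a mutant juvenile, and the group's
#' mutant emigrants found an expected `m * k * f_mut / f0` new singleton
#' groups elsewhere (immigrants into any focal group are never mutants: the
#' mutant is globally rare in an infinite population). Entry `A[k', k]` is
#' the expected number of state-`k'` groups descending from one state-`k`
#' group.
#'
#' @param spec A [group_model()].
#' @return A list with the `n x n` matrix `A`, the per-state per-capita
#'   fitness `omega` (a vector over `k = 1..n`), and the state labels.
#' @export
build_projection <- function(spec) {
  stopifnot(inherits(spec, "group_model"))
  n <- spec$n
  A <- matrix(0, n, n)
  omega <- numeric(n)
  for (k in seq_len(n)) {
    st <- island_state(k, spec)
    A[, k] <- stats::dbinom(seq_len(n), n, st$phi)
    A[1L, k] <- A[1L, k] + st$emig
    omega[k] <- st$omega
  }
  list(A = A, omega = omega, states = seq_len(n))
}

#' Leading eigenpair of a non-negative matrix
#'
#' Perron root (largest-magnitude eigenvalue) and its non-negative right
#' eigenvector normalized to sum 1, computed by dense eigen-decomposition
#' with a power-iteration fallback when the leading pair is complex or the
#' eigenvector is not sign-consistent (reducible or defective matrices).
#' Ties are broken by magnitude, then by the lexicographically smallest
#' support.
#'
#' @param A Square non-negative matrix.
#' @param tol Power-iteration convergence tolerance.
#' @param max_iter Power-iteration cap.
#' @return A list with `lambda` (magnitude of the leading eigenvalue) and
#'   `u` (non-negative, sums to 1).
#' @export
leading_eigenpair <- function(A, tol = 1e-13, max_iter = 1e5) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), all(A >= 0), all(is.finite(A)))
  ee <- eigen(A)
  lead <- which(abs(Mod(ee$values) - max(Mod(ee$values))) < 1e-12 * max(1, max(Mod(ee$values))))
  use_power <- TRUE
  if (length(lead) >= 1L) {
    i <- lead[which.min(abs(Im(ee$values[lead])))]
    if (abs(Im(ee$values[i])) < 1e-10 * max(1, Mod(ee$values[i]))) {
      v <- Re(ee$vectors[, i])
      if (all(v >= -1e-10) || all(v <= 1e-10)) {
        v <- abs(v)
        if (sum(v) > 0) {
          return(list(lambda = Mod(ee$values[i]), u = v / sum(v)))
        }
      }
      use_power <- TRUE
    }
  }
  if (use_power) {
    n <- nrow(A)
    v <- rep(1 / n, n)
    lam <- NA_real_
    for (it in seq_len(max_iter)) {
      w <- as.vector(A %*% v)
      s <- sum(w)
      if (s == 0) return(list(lambda = 0, u = v))
      w <- w / s
      if (max(abs(w - v)) < tol && it > 1L) {
        lam <- s
        v <- w
        break
      }
      v <- w
      lam <- s
    }
    list(lambda = lam, u = v / sum(v))
  }
}

#' Full invasion analysis of a group model
#'
#' Builds the projection matrix, solves for the leading eigenpair, and
#' derives the stabilized lineage quantities: the distribution `q_k` of the
#' group state containing a randomly sampled mutant allele, the within-group
#' relatedness `r` (expected fraction of a mutant's groupmates carrying the
#' mutant allele), and the lineage fitness (the `q`-weighted mean individual
#' fitness, identical to the eigenvalue).
#'
#' @param spec A [group_model()].
#' @return A list of class `invasion_result` with `lambda`, `u`, `q`,
#'   `relatedness` (NA when `n = 1`), `omega`, `lineage_fitness` and the
#'   projection matrix `A`.
#' @export
invasion_analysis <- function(spec) {
  proj <- build_projection(spec)
  ep <- leading_eigenpair(proj$A)
  k <- seq_len(spec$n)
  q <- k * ep$u / sum(k * ep$u)
  relatedness <- if (spec$n >= 2L) sum(q * (k - 1) / (spec$n - 1)) else NA_real_
  structure(list(lambda = ep$lambda, u = ep$u, q = q,
                 relatedness = relatedness, omega = proj$omega,
                 lineage_fitness = sum(q * proj$omega), A = proj$A,
                 spec = spec),
            class = "invasion_result")
}

#' Lineage fitness from the stabilized group-state distribution
#'
#' The invasion fitness expressed as the average number of offspring of a
#' mutant allele sampled from the stabilized invasion process:
#' `lambda = sum_k omega_k q_k` with `q_k = k u_k / sum_k k u_k`. Identical
#' to the leading eigenvalue of the projection matrix.
#'
#' @param spec A [group_model()].
#' @param u Optional eigenvector from [leading_eigenpair()]; computed if
#'   missing.
#' @return The lineage fitness (numeric scalar).
#' @export
lineage_fitness <- function(spec, u = NULL) {
  proj <- build_projection(spec)
  if (is.null(u)) u <- leading_eigenpair(proj$A)$u
  k <- seq_len(spec$n)
  q <- k * u / sum(k * u)
  sum(q * proj$omega)
}

#' Cost and benefit coefficients of the mutant phenotype
#'
#' Decomposes the fitness of a mutant individual into a direct cost of its
#' own expression and an aggregate benefit received from expressing
#' groupmates, in the exact neighbour-modulated (Price-regression) form: the
#' per-state fitness `omega_k` is regressed on the mutant fraction among the
#' focal's groupmates, `(k - 1) / (n - 1)`, with weights given by the
#' stabilized lineage distribution `q_k`. The slope is the aggregate benefit
#' `b` (the fitness increase when all groupmates carry the mutant), and the
#' intercept defines the cost `c = 1 - intercept` (the fitness decrease from
#' own expression with all-resident groupmates). Because a weighted
#' regression passes through the weighted means, `1 - c + b * r` with
#' `r = E_q[(k-1)/(n-1)]` reconstructs the lineage fitness exactly; the
#' coefficients absorb kin competition and payoff synergy rather than
#' ignoring them.
#'
#' @param spec A [group_model()].
#' @param summaries Optional [invasion_analysis()] result reused for `q` and
#'   `omega`.
#' @return A list with `cost`, `benefit` (aggregate over groupmates; 0 when
#'   `n = 1`) and the per-state inputs `omega`, `q`.
#' @export
decompose_costs_benefits <- function(spec, summaries = NULL) {
  stopifnot(inherits(spec, "group_model"))
  if (is.null(summaries)) summaries <- invasion_analysis(spec)
  n <- spec$n
  omega <- summaries$omega
  q <- summaries$q
  if (!all(is.finite(omega))) stop("non-finite fitness values", call. = FALSE)
  if (n == 1L) {
    return(list(cost = 1 - omega[1L], benefit = 0, omega = omega, q = q))
  }
  mfrac <- (seq_len(n) - 1) / (n - 1)
  mbar <- sum(q * mfrac)
  varm <- sum(q * (mfrac - mbar)^2)
  if (varm < 1e-14) {
    b <- 0
    a0 <- sum(q * omega)
  } else {
    b <- sum(q * (mfrac - mbar) * (omega - sum(q * omega))) / varm
    a0 <- sum(q * omega) - b * mbar
  }
  list(cost = 1 - a0, benefit = b, omega = omega, q = q)
}

#' Inclusive-fitness (actor-modulated) expression of invasion fitness
#'
#' `lambda_if = 1 - c + b * r`: the mutant's direct cost plus the
#' relatedness-weighted benefit it confers on groupmates (for the
#' single-class island kernels the benefit conferred equals the benefit
#' received, by exchange symmetry). With the exact regression coefficients of
#' [decompose_costs_benefits()] this reconstructs the eigenvalue invasion
#' fitness.
#'
#' @param spec A [group_model()].
#' @param summaries Optional [invasion_analysis()] result (for `r`).
#' @param partition Optional [decompose_costs_benefits()] result.
#' @return A list with `lambda_if`, `cost`, `benefit`, `relatedness`.
#' @export
inclusive_fitness <- function(spec, summaries = NULL, partition = NULL) {
  if (is.null(summaries)) summaries <- invasion_analysis(spec)
  if (is.null(partition)) partition <- decompose_costs_benefits(spec, summaries)
  r <- summaries$relatedness
  if (!is.finite(r)) {
    if (abs(partition$benefit) > 0) {
      stop("relatedness undefined (no groupmates) but benefit is non-zero",
           call. = FALSE)
    }
    r <- 0
  }
  list(lambda_if = 1 - partition$cost + partition$benefit * r,
       cost = partition$cost, benefit = partition$benefit, relatedness = r)
}

#' Group-selection (between/within group) partition of invasion fitness
#'
#' Splits the same cost, benefit and relatedness quantities into a
#' between-group component
#' `omega_G = (b - c) * (1/n + ((n-1)/n) * r)` and a within-group component
#' `omega_dG = -(b + (n-1) c) * (1 - r) / n` (where `b` is the aggregate
#' benefit), so that `lambda_gs = 1 + omega_G + omega_dG` coincides exactly
#' with the inclusive-fitness value. A costly helping trait (`c > 0`,
#' `b > c`) is positively selected between groups and negatively selected
#' within groups; in the clonal-group limit `r = 1` the within-group
#' component vanishes.
#'
#' @inheritParams inclusive_fitness
#' @return A list with `omega_G`, `omega_dG` and `lambda_gs`.
#' @export
group_partition <- function(spec, summaries = NULL, partition = NULL) {
  if (is.null(summaries)) summaries <- invasion_analysis(spec)
  if (is.null(partition)) partition <- decompose_costs_benefits(spec, summaries)
  n <- spec$n
  r <- summaries$relatedness
  if (!is.finite(r)) {
    if (abs(partition$benefit) > 0) {
      stop("relatedness undefined (no groupmates) but benefit is non-zero",
           call. = FALSE)
    }
    r <- 0
  }
  b <- partition$benefit; cc <- partition$cost
  omega_G <- (b - cc) * (1 / n + (n - 1) / n * r)
  omega_dG <- -(b + (n - 1) * cc) * (1 - r) / n
  list(omega_G = omega_G, omega_dG = omega_dG,
       lambda_gs = 1 + omega_G + omega_dG)
}

#' Stochastic multitype branching simulation of the mutant group process
#'
#' Simulates the branching process defined by the projection matrix of a
#' [group_model()]: each group in state `k` independently leaves its own
#' group in state `Binomial(n, phi_k)` and founds `Poisson(emig_k)` singleton
#' groups. Used as an independent check that the deterministic eigenvalue
#' matches the realized growth of the mutant lineage.
#'
#' @param spec A [group_model()].
#' @param generations Number of generations simulated.
#' @param replicates Number of independent lineages (each started from one
#'   singleton-mutant group).
#' @return A list with `mean_final` (mean total mutant count), `se`,
#'   `growth_rate` (per-generation, from the last half of the run via the
#'   mean counts) and the per-generation mean counts.
#' @export
simulate_group_branching <- function(spec, generations = 20L,
                                     replicates = 1e4L) {
  stopifnot(inherits(spec, "group_model"))
  n <- spec$n
  st <- lapply(seq_len(n), island_state, spec = spec)
  phi <- vapply(st, `[[`, numeric(1), "phi")
  emig <- vapply(st, `[[`, numeric(1), "emig")
  counts <- matrix(0L, replicates, n)
  counts[, 1L] <- 1L
  mean_counts <- numeric(generations)
  for (g in seq_len(generations)) {
    new_counts <- matrix(0L, replicates, n)
    singles <- integer(replicates)
    for (k in seq_len(n)) {
      nk <- counts[, k]
      tot <- sum(nk)
      if (tot == 0L) next
      # own-group transitions: aggregate the Binomial(n, phi_k) draws
      draws <- stats::rbinom(tot, n, phi[k])
      rep_id <- rep.int(seq_len(replicates), nk)
      for (kp in seq_len(n)) {
        hits <- draws == kp
        if (any(hits)) {
          tab <- tabulate(rep_id[hits], nbins = replicates)
          new_counts[, kp] <- new_counts[, kp] + tab
        }
      }
      singles <- singles + stats::rpois(replicates, emig[k] * nk)
    }
    new_counts[, 1L] <- new_counts[, 1L] + singles
    counts <- new_counts
    mean_counts[g] <- mean(as.vector(counts %*% seq_len(n)))
  }
  final <- as.vector(counts %*% seq_len(n))
  half <- max(2L, floor(generations / 2L))
  gr <- (mean_counts[generations] / mean_counts[half])^(1 / (generations - half))
  list(mean_final = mean(final), se = stats::sd(final) / sqrt(replicates),
       growth_rate = gr, mean_counts = mean_counts,
       final_totals = final, counts_by_state = colSums(counts))
}

#' Invasion fitness of a rare sex-ratio mutant
#'
#' The two-class (female/male) panmictic specialization: a rare autosomal
#' mutant allele whose female carriers produce a fraction `y` of daughters in
#' a resident population producing a fraction `xhat`. Transmission to the
#' next generation runs through daughters (in proportion `y / xhat`, the
#' mutant female's share of the daughter pool) and through sons (in
#' proportion `(1 - y) / (1 - xhat)`), each discounted by the Mendelian
#' factor 1/2; mutant males transmit at the resident ratio. The invasion
#' fitness is the leading eigenvalue of the resulting 2x2 class projection
#' matrix.
#'
#' @param y Mutant proportion of daughters, in (0, 1).
#' @param xhat Resident proportion of daughters, strictly inside (0, 1).
#' @return The invasion fitness `lambda`.
#' @examples
#' sex_ratio_invasion(0.5, 0.3)  # > 1: a move toward 1:1 invades
#' @export
sex_ratio_invasion <- function(y, xhat) {
  y <- check_prob(y, "y")
  if (!(xhat > 0 && xhat < 1)) {
    stop("resident sex ratio must be strictly inside (0, 1)", call. = FALSE)
  }
  A <- matrix(c(y / (2 * xhat), (1 - y) / (2 * (1 - xhat)),
                1 / 2, 1 / 2), 2, 2)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Scan resident sex ratios for the uninvadable value
#'
#' Computes `max_y lambda(y, xhat)` over a mutant grid for each resident on a
#' grid and reports the resident(s) that no mutant can invade.
#'
#' @param resident_grid,mutant_grid Grids strictly inside (0, 1).
#' @param tol Invasion tolerance on `lambda - 1`.
#' @return A tibble with `resident`, `max_lambda` and `uninvadable`.
#' @export
sex_ratio_scan <- function(resident_grid = seq(0.05, 0.95, by = 0.05),
                           mutant_grid = seq(0.02, 0.98, by = 0.02),
                           tol = 1e-9) {
  purrr::map_dfr(resident_grid, function(xh) {
    lam <- vapply(mutant_grid, sex_ratio_invasion, numeric(1), xhat = xh)
    tibble::tibble(resident = xh, max_lambda = max(lam),
                   uninvadable = max(lam) <= 1 + tol)
  })
}
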