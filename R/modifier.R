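#' Specify the mutation-rate-modifier model
#'
#' A haploid two-locus system: a major locus with alleles `A1`/`A2` under
#' environment-dependent selection, and a neutral modifier locus that sets the
#' symmetric mutation rate `A1 <-> A2` at the major locus. The environment
#' alternates deterministically between two states every `T` generations
#' (period `2T`), starting in environment 1. In environment 1 allele `A1` is
#' matched (fitness 1) and `A2` mismatched (fitness `1 - s1`); in environment
#' 2 the roles reverse with cost `s2`. The life cycle is selection, then
#' mutation at the rate set by the chromosome's own modifier allele, then
#' recombination (rate `r`) between the two loci, with census after
#' recombination.
#'
#' @param T Generations per environmental epoch (integer >= 1).
#' @param s1,s2 Fitness costs of carrying the mismatched major-locus allele in
#'   environments 1 and 2; in [0, 1).
#' @param r Recombination rate between major and modifier locus, in [0, 0.5].
#' @param mu_res Resident modifier's mutation rate, in [0, 0.5].
#' @param mu_mut Mutant modifier's mutation rate, in [0, 0.5].
#' @param constant_env When `TRUE`, the environment never switches: every
#'   generation uses environment 1 (selection against `A2` at cost `s1`).
#'   This is the constant-environment regime in which the reduction principle
#'   applies: the only uninvadable mutation rate is the lowest available one.
#' @return An object of class `modifier_model`.
#' @examples
#' spec <- modifier_model(T = 50, s1 = 0.01, s2 = 0.015, r = 0,
#'                        mu_res = 0.02, mu_mut = 0.01)
#' invasion_eigenvalue(spec)$lam_cycle
#' @export
modifier_model <- function(T, s1, s2, r = 0, mu_res = 0.01, mu_mut = mu_res,
                           constant_env = FALSE) {
  stopifnot(T >= 1, T == round(T),
            s1 >= 0, s1 < 1, s2 >= 0, s2 < 1,
            r >= 0, r <= 0.5,
            mu_res >= 0, mu_res <= 0.5, mu_mut >= 0, mu_mut <= 0.5)
  structure(list(T = as.integer(T), s1 = s1, s2 = s2, r = r,
                 mu_res = mu_res, mu_mut = mu_mut,
                 constant_env = isTRUE(constant_env)),
            class = "modifier_model")
}

env_fitness <- function(env, spec) {
  # fitness of (A1, A2) in the given environment
  if (env == 1L) c(1, 1 - spec$s1) else c(1 - spec$s2, 1)
}

env_schedule <- function(spec) {
  if (spec$constant_env) rep(1L, 2L * spec$T) else rep(c(1L, 2L), each = spec$T)
}

#' One generation of the resident major-locus recursion
#'
#' Selection in the given environment (matched allele fitness 1, mismatched
#' `1 - s_env`), followed by symmetric mutation at rate `mu`.
#'
#' @param freqA1 Frequency of allele `A1` on the resident background.
#' @param env Environment state, 1 or 2.
#' @param mu Mutation rate applied.
#' @param spec A [modifier_model()].
#' @return Updated `A1` frequency.
#' @export
resident_step <- function(freqA1, env, mu, spec) {
  stopifnot(inherits(spec, "modifier_model"))
  p <- check_prob(freqA1, "freqA1")
  w <- env_fitness(env, spec)
  ps <- p * w[1] / (p * w[1] + (1 - p) * w[2])
  ps * (1 - mu) + (1 - ps) * mu
}

#' Find the resident limit cycle
#'
#' Iterates whole environmental periods (2T generations) of the resident
#' recursion from `A1` frequency 0.5 until two successive periods differ by
#' less than `tol` in sup norm. Returns the converged periodic orbit.
#'
#' @param spec A [modifier_model()].
#' @param mu Mutation rate of the cycling resident; defaults to
#'   `spec$mu_res`.
#' @param tol Convergence tolerance between successive periods.
#' @param max_cycles Cap on the number of periods iterated.
#' @return A list of class `resident_cycle` with `states` (the `A1` frequency
#'   at the start of each of the 2T generations of the period), `residual`
#'   and `converged`.
#' @export
find_limit_cycle <- function(spec, mu = spec$mu_res, tol = 1e-12,
                             max_cycles = 1e5) {
  stopifnot(inherits(spec, "modifier_model"), tol > 0)
  envs <- env_schedule(spec)
  p <- 0.5
  residual <- Inf
  for (cyc in seq_len(max_cycles)) {
    p0 <- p
    for (e in envs) p <- resident_step(p, e, mu, spec)
    residual <- abs(p - p0)
    if (residual < tol) break
  }
  if (residual >= tol) {
    warning("resident cycle did not converge within max_cycles", call. = FALSE)
  }
  states <- numeric(2L * spec$T)
  for (t in seq_along(envs)) {
    states[t] <- p
    p <- resident_step(p, envs[t], mu, spec)
  }
  structure(list(states = states, residual = residual,
                 converged = residual < tol, mu = mu),
            class = "resident_cycle")
}

#' Per-generation linearized map of the rare mutant-modifier chromosomes
#'
#' Builds the 2x2 matrix taking the frequencies of the rare mutant
#' chromosomes `(M'A1, M'A2)` through one generation: selection in the given
#' environment (normalized by the resident mean fitness), mutation at the
#' mutant modifier's rate, and recombination at rate `r` with a resident
#' chromosome whose major-locus allele frequency is taken at the same
#' post-mutation stage.
#'
#' @param resident_freq `A1` frequency on the resident background at the
#'   census preceding this generation.
#' @param env Environment state, 1 or 2.
#' @param spec A [modifier_model()].
#' @param mu_mut Mutant modifier's mutation rate; defaults to `spec$mu_mut`.
#' @return A non-negative 2x2 matrix.
#' @export
mutant_generation_matrix <- function(resident_freq, env, spec,
                                     mu_mut = spec$mu_mut) {
  stopifnot(inherits(spec, "modifier_model"))
  p <- check_prob(resident_freq, "resident_freq")
  w <- env_fitness(env, spec)
  wbar <- p * w[1] + (1 - p) * w[2]
  S <- diag(w) / wbar
  U <- matrix(c(1 - mu_mut, mu_mut, mu_mut, 1 - mu_mut), 2, 2)
  # resident A1 frequency after selection and mutation (the pairing pool)
  ps <- p * w[1] / wbar
  q1 <- ps * (1 - spec$mu_res) + (1 - ps) * spec$mu_res
  Rec <- (1 - spec$r) * diag(2) +
    spec$r * matrix(c(q1, 1 - q1, q1, 1 - q1), 2, 2)
  Rec %*% U %*% S
}

#' Invasion fitness of a mutant mutation-rate modifier
#'
#' Multiplies the 2T per-generation mutant matrices in order along the
#' converged resident cycle (the monodromy matrix of the periodic rare-mutant
#' dynamics) with per-step scaling on a log accumulator to avoid under- or
#' overflow, and returns the leading-eigenvalue magnitude per full period
#' (`lam_cycle`) and per generation (`lam_pergen = lam_cycle^(1/(2T))`).
#' The mutant invades when `lam_cycle > 1`.
#'
#' @param spec A [modifier_model()].
#' @param cycle Optional pre-computed [find_limit_cycle()] result for the
#'   resident (must use `spec$mu_res`).
#' @param mu_mut Mutant rate; defaults to `spec$mu_mut`.
#' @return A list with `lam_cycle`, `lam_pergen` and the unscaled monodromy
#'   log-magnitude bookkeeping.
#' @export
invasion_eigenvalue <- function(spec, cycle = NULL, mu_mut = spec$mu_mut) {
  stopifnot(inherits(spec, "modifier_model"))
  if (is.null(cycle)) cycle <- find_limit_cycle(spec)
  envs <- env_schedule(spec)
  M <- diag(2)
  logscale <- 0
  for (t in seq_along(envs)) {
    M <- mutant_generation_matrix(cycle$states[t], envs[t], spec, mu_mut) %*% M
    s <- max(abs(M))
    if (s > 0 && (s > 1e100 || s < 1e-100)) {
      M <- M / s
      logscale <- logscale + log(s)
    }
  }
  ev <- eigen(M, only.values = TRUE)$values
  lam_cycle <- exp(log(max(Mod(ev))) + logscale)
  list(lam_cycle = lam_cycle,
       lam_pergen = lam_cycle^(1 / (2 * spec$T)))
}

#' Pairwise invasibility plot for the mutation-rate modifier
#'
#' Evaluates the per-generation invasion-fitness magnitude over a grid of
#' resident and mutant mutation rates. The resident limit cycle is computed
#' once per resident value and reused across mutants.
#'
#' @param spec A [modifier_model()] carrying `T`, `s1`, `s2`, `r` (the
#'   mutation rates in `spec` are ignored).
#' @param resident_grid,mutant_grid Mutation-rate grids in [0, 0.5].
#' @return A `pip_grid` tibble with columns `resident`, `mutant`, `lambda`
#'   (per generation) and `invades`; per-point failures are recorded as `NA`
#'   in `lambda` with `invades = NA`.
#' @export
modifier_pip <- function(spec, resident_grid = seq(0, 0.05, length.out = 41),
                         mutant_grid = resident_grid) {
  stopifnot(inherits(spec, "modifier_model"),
            all(resident_grid >= 0 & resident_grid <= 0.5),
            all(mutant_grid >= 0 & mutant_grid <= 0.5))
  rows <- purrr::map_dfr(resident_grid, function(mu_res) {
    sp <- modifier_model(spec$T, spec$s1, spec$s2, spec$r, mu_res = mu_res, constant_env = spec$constant_env)
    cycle <- find_limit_cycle(sp)
    lam <- vapply(mutant_grid, function(mu_mut) {
      tryCatch(invasion_eigenvalue(sp, cycle, mu_mut)$lam_pergen,
               error = function(e) NA_real_)
    }, numeric(1))
    tibble::tibble(resident = mu_res, mutant = mutant_grid, lambda = lam)
  })
  out <- dplyr::mutate(rows, invades = .data$lambda > 1 + 1e-9)
  class(out) <- c("pip_grid", class(out))
  out
}

#' Evolutionarily stable mutation rate
#'
#' Scans resident mutation rates on a grid and locates the value at which the
#' diagonal selection gradient, estimated as
#' `lam_cycle(mu + delta, mu) - 1`, changes sign from positive (higher rates
#' invade) to negative (lower rates invade); the crossing is refined by
#' bisection to `tol`. If the gradient is negative across the whole grid the
#' ES rate is the boundary value 0. The returned rate is verified to be
#' uninvadable against the full mutant grid.
#'
#' @inheritParams modifier_pip
#' @param grid Resident mutation-rate search grid.
#' @param delta Offset used in the gradient probe.
#' @param tol Bisection refinement tolerance on the rate.
#' @return A list of class `es_rate` with `mu_star`, `bracket`, `method`
#'   (`"diagonal_sign_change"` or `"boundary"`), `uninvadable` (logical
#'   verification over the mutant grid) and `gradient` (a tibble of the
#'   scanned gradient values). When the gradient changes sign more than once
#'   all crossings are reported in `all_crossings`.
#' @export
es_rate <- function(spec, grid = seq(0, 0.05, length.out = 41),
                    delta = 1e-4, tol = 1e-5) {
  stopifnot(inherits(spec, "modifier_model"))
  gradient_at <- function(mu) {
    mu <- max(mu, 0)
    sp <- modifier_model(spec$T, spec$s1, spec$s2, spec$r, mu_res = mu, constant_env = spec$constant_env)
    cycle <- find_limit_cycle(sp)
    invasion_eigenvalue(sp, cycle, min(mu + delta, 0.5))$lam_cycle - 1
  }
  g <- vapply(grid, gradient_at, numeric(1))
  gradient <- tibble::tibble(mu = grid, gradient = g)
  crossings <- which(g[-length(g)] > 0 & g[-1L] <= 0)
  refine <- function(i) {
    lo <- grid[i]; hi <- grid[i + 1L]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (gradient_at(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  if (length(crossings) == 0L) {
    if (all(g <= 0)) {
      mu_star <- 0
      bracket <- c(0, grid[2L])
      method <- "boundary"
    } else {
      # gradient positive through the top of the grid: ES rate beyond grid
      mu_star <- grid[length(grid)]
      bracket <- grid[length(grid) - 1:0]
      method <- "boundary"
      warning("selection gradient positive at the top of the grid; ",
              "mu_star reported at the grid boundary", call. = FALSE)
    }
    all_crossings <- numeric(0)
  } else {
    all_crossings <- vapply(crossings, refine, numeric(1))
    mu_star <- all_crossings[1L]
    bracket <- c(grid[crossings[1L]], grid[crossings[1L] + 1L])
    method <- "diagonal_sign_change"
    if (length(crossings) > 1L) {
      warning("multiple selection-gradient sign changes found; all reported",
              call. = FALSE)
    }
  }
  sp <- modifier_model(spec$T, spec$s1, spec$s2, spec$r, mu_res = mu_star, constant_env = spec$constant_env)
  cycle <- find_limit_cycle(sp)
  lam_all <- vapply(grid, function(mu_mut) {
    invasion_eigenvalue(sp, cycle, mu_mut)$lam_cycle
  }, numeric(1))
  structure(list(mu_star = mu_star, bracket = bracket, method = method,
                 uninvadable = all(lam_all <= 1 + 1e-6),
                 max_lambda = max(lam_all),
                 gradient = gradient,
                 all_crossings = all_crossings),
            class = "es_rate")
}

#' Stochastic branching simulation of a rare mutant-modifier lineage
#'
#' Simulates the multitype branching process whose mean matrices are the
#' per-generation mutant maps along the resident cycle: each mutant
#' chromosome of type `i` (carrying major allele `A_i`) leaves a Poisson
#' number of type-`j` descendants with mean given by the corresponding
#' matrix entry. Used as an independent stochastic check on the sign of the
#' monodromy eigenvalue.
#'
#' @param spec A [modifier_model()].
#' @param n_cycles Number of full environmental periods simulated.
#' @param replicates Number of independent lineages, each started from a
#'   single mutant chromosome carrying `A1`.
#' @return A list with `counts` (replicates x 2 matrix of final type counts),
#'   `totals` (per-replicate final totals) and `generations`.
#' @export
simulate_modifier_branching <- function(spec, n_cycles = 2L, replicates = 1e4L) {
  stopifnot(inherits(spec, "modifier_model"))
  cycle <- find_limit_cycle(spec)
  envs <- env_schedule(spec)
  mats <- lapply(seq_along(envs), function(t) {
    mutant_generation_matrix(cycle$states[t], envs[t], spec)
  })
  n1 <- rep(1L, replicates)
  n2 <- rep(0L, replicates)
  for (cyc in seq_len(n_cycles)) {
    for (L in mats) {
      m1 <- L[1, 1] * n1 + L[1, 2] * n2
      m2 <- L[2, 1] * n1 + L[2, 2] * n2
      n1 <- stats::rpois(replicates, m1)
      n2 <- stats::rpois(replicates, m2)
    }
  }
  list(counts = cbind(A1 = n1, A2 = n2), totals = n1 + n2,
       generations = n_cycles * length(envs))
}
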