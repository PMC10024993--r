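#' Specify a two-locus diploid game model
#'
#' Two recombining loci A (alleles `A_1..A_a`) and B (alleles `B_1..B_b`)
#' jointly determine a mixed strategy: genotype `A_i B_j / A_k B_l` chooses
#' behaviour C with probability `xg[i, j, k, l]`. Chromosome (gamete)
#' frequencies are censused after selection and recombination each
#' generation; individuals interact in randomly formed pairs and mate at
#' random.
#'
#' @param xg 4-d array `a x b x a x b` of genotype phenotypes in [0, 1],
#'   symmetric under exchange of the two chromosomes
#'   (`xg[i,j,k,l] == xg[k,l,i,j]`).
#' @param R Recombination rate between the loci, in (0, 0.5].
#' @param W A [payoff_matrix()].
#' @return An object of class `two_locus_model`.
#' @export
two_locus_model <- function(xg, R, W) {
  xg <- as.array(xg)
  d <- dim(xg)
  if (length(d) != 4L || d[1L] != d[3L] || d[2L] != d[4L]) {
    stop("`xg` must be an a x b x a x b array", call. = FALSE)
  }
  if (any(xg < 0 | xg > 1)) stop("phenotypes must lie in [0, 1]", call. = FALSE)
  if (!(R > 0 && R <= 0.5)) stop("`R` must lie in (0, 0.5]", call. = FALSE)
  sym <- aperm(xg, c(3, 4, 1, 2))
  if (!isTRUE(all.equal(as.vector(xg), as.vector(sym), tolerance = 1e-12))) {
    stop("`xg` must satisfy genotype symmetry xg[i,j,k,l] == xg[k,l,i,j]",
         call. = FALSE)
  }
  structure(list(a = d[1L], b = d[2L], R = R, xg = xg, W = as_payoff_matrix(W)),
            class = "two_locus_model")
}

check_chrom_freqs <- function(p, model) {
  p <- as.matrix(p)
  if (nrow(p) != model$a || ncol(p) != model$b) {
    stop("chromosome-frequency matrix has wrong dimensions", call. = FALSE)
  }
  if (any(p < -1e-14) || abs(sum(p) - 1) > 1e-8) {
    stop("chromosome frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  p
}

#' Mean phenotype of a two-locus population
#'
#' `x(p) = sum_{ijkl} p_ij p_kl xg[i,j,k,l]`, the population mean probability
#' of choosing C after random mating.
#'
#' @param p `a x b` matrix of chromosome frequencies.
#' @param model A [two_locus_model()].
#' @return Mean phenotype in [0, 1].
#' @export
mean_phenotype2 <- function(p, model) {
  stopifnot(inherits(model, "two_locus_model"))
  p <- check_chrom_freqs(p, model)
  P <- as.vector(p)
  X <- model$xg
  dim(X) <- c(model$a * model$b, model$a * model$b)
  as.numeric(t(P) %*% X %*% P)
}

#' Two-locus selection-recombination step
#'
#' The classical diploid selection-recombination recursion on chromosome
#' frequencies, censused after selection and recombination:
#' `p'_ij = (1/wbar) [ (1-R) sum_kl w(xg[i,j,k,l], xbar) p_ij p_kl
#'                     + R sum_kl w(xg[i,l,k,j], xbar) p_il p_kj ]`,
#' where `xbar = mean_phenotype2(p, model)` and recombination exchanges the
#' locus-B alleles of the two parental chromosomes in double heterozygotes.
#'
#' @inheritParams mean_phenotype2
#' @return Updated chromosome-frequency matrix.
#' @export
twolocus_step <- function(p, model) {
  stopifnot(inherits(model, "two_locus_model"))
  p <- check_chrom_freqs(p, model)
  a <- model$a; b <- model$b; R <- model$R
  xbar <- mean_phenotype2(p, model)
  Wm <- payoff(as.vector(model$xg), xbar, model$W)
  dim(Wm) <- c(a, b, a, b)
  P <- as.vector(p)
  Wmat <- Wm
  dim(Wmat) <- c(a * b, a * b)
  marg <- Wmat %*% P            # sum_kl w(xg[i,j,k,l]) p_kl, by chromosome ij
  wbar <- as.numeric(t(P) %*% marg)
  if (wbar <= 0) stop("mean fitness must be positive", call. = FALSE)
  t1 <- p * matrix(marg, a, b)
  t2 <- matrix(0, a, b)
  for (i in seq_len(a)) for (j in seq_len(b)) {
    acc <- 0
    for (k in seq_len(a)) for (l in seq_len(b)) {
      acc <- acc + Wm[i, l, k, j] * p[i, l] * p[k, j]
    }
    t2[i, j] <- acc
  }
  out <- ((1 - R) * t1 + R * t2) / wbar
  out <- pmax(out, 0)
  out / sum(out)
}

#' Iterate the two-locus recursion to an internal equilibrium
#'
#' @inheritParams mean_phenotype2
#' @param start Starting chromosome-frequency matrix; defaults to the uniform
#'   distribution.
#' @param tol,max_iter Passed to [iterate_to_equilibrium()].
#' @return A list with `p` (equilibrium frequencies), `converged`,
#'   `iterations` and `x_hat` (the equilibrium mean phenotype).
#' @export
find_internal_equilibrium <- function(model, start = NULL, tol = 1e-12,
                                      max_iter = 1e5) {
  stopifnot(inherits(model, "two_locus_model"))
  if (is.null(start)) start <- matrix(1 / (model$a * model$b), model$a, model$b)
  start <- check_chrom_freqs(start, model)
  res <- iterate_to_equilibrium(function(p) twolocus_step(p, model),
                                start, tol = tol, max_iter = max_iter)
  list(p = res$state, converged = res$converged, iterations = res$iterations,
       x_hat = mean_phenotype2(res$state, model))
}

#' Specify a mutant allele at locus A
#'
#' A new allele `A_mu` whose carriers (necessarily single-copy while rare)
#' have genotype `A_mu B_j / A_k B_l` and phenotype `xmu[j, k, l]`.
#'
#' @param xmu Array `b x a x b` of mutant genotype phenotypes in [0, 1].
#' @return An object of class `mutant_spec`.
#' @export
mutant_spec <- function(xmu) {
  xmu <- as.array(xmu)
  if (length(dim(xmu)) != 3L) stop("`xmu` must be a b x a x b array", call. = FALSE)
  if (any(xmu < 0 | xmu > 1)) stop("phenotypes must lie in [0, 1]", call. = FALSE)
  structure(list(xmu = xmu), class = "mutant_spec")
}

#' External stability of a two-locus equilibrium against a mutant allele
#'
#' Linearizes the two-locus recursion in the frequencies of the rare mutant
#' chromosomes `A_mu B_j`. A mutant chromosome paired with resident
#' chromosome `A_k B_l` (drawn with probability `phat[k, l]`) survives
#' selection with weight `w(xmu[j,k,l], x_hat) / wbar_hat` and transmits
#' `A_mu B_j` with probability `1 - R` and `A_mu B_l` with probability `R`.
#' The leading-eigenvalue magnitude of the resulting `b x b` map is the
#' invasion fitness `lambda`; its non-negative eigenvector `u` gives the
#' stabilized mutant-chromosome frequencies, and the mutant mean phenotype is
#' `x_mu = sum_jkl u_j phat_kl xmu[j,k,l]`.
#'
#' @inheritParams mean_phenotype2
#' @param phat Internal equilibrium chromosome frequencies of the resident.
#' @param mutant A [mutant_spec()].
#' @param equilibrium_tol Maximum allowed one-step drift of `phat`.
#' @return A list with `lambda`, `u` (normalized to sum 1), `x_mu`, `x_hat`
#'   and the linearized map `M`.
#' @export
external_stability <- function(model, phat, mutant,
                               equilibrium_tol = 1e-8) {
  stopifnot(inherits(model, "two_locus_model"), inherits(mutant, "mutant_spec"))
  phat <- check_chrom_freqs(phat, model)
  if (max(abs(twolocus_step(phat, model) - phat)) > equilibrium_tol) {
    stop("`phat` is not an equilibrium of the resident recursion", call. = FALSE)
  }
  a <- model$a; b <- model$b; R <- model$R
  xmu <- mutant$xmu
  if (!all(dim(xmu) == c(b, a, b))) {
    stop("mutant phenotype array must be b x a x b", call. = FALSE)
  }
  xhat <- mean_phenotype2(phat, model)
  wbar <- payoff(xhat, xhat, model$W)  # = mean fitness for bilinear pay-off
  if (wbar <= 0) stop("resident mean fitness must be positive", call. = FALSE)
  wmu <- payoff(as.vector(xmu), xhat, model$W)
  dim(wmu) <- c(b, a, b)               # w(xmu[j,k,l], xhat)
  M <- matrix(0, b, b)
  for (j in seq_len(b)) {
    M[j, j] <- M[j, j] + (1 - R) * sum(wmu[j, , ] * phat)
    for (jp in seq_len(b)) {
      M[jp, j] <- M[jp, j] + R * sum(wmu[j, , jp] * phat[, jp])
    }
  }
  M <- M / wbar
  ep <- leading_eigenpair(M)
  u <- ep$u
  x_mu <- 0
  for (j in seq_len(b)) x_mu <- x_mu + u[j] * sum(xmu[j, , ] * phat)
  list(lambda = ep$lambda, u = u, x_mu = x_mu, x_hat = xhat, M = M)
}

#' Check the ESS / external-stability correspondence on one model instance
#'
#' Tests both directions of the correspondence between external stability and
#' evolutionary stability on a supplied two-locus instance: (i) if no tested
#' mutant invades (`lambda < 1` for all), the equilibrium phenotype must
#' classify as an ESS of the pay-off matrix; (ii) if the equilibrium
#' phenotype is an ESS and the equilibrium is internally stable, no tested
#' mutant may invade.
#'
#' @inheritParams external_stability
#' @param phenotype_grid Mutant phenotypes to test; each becomes a mutant
#'   allele with that constant phenotype on every genetic background.
#' @param tol Neutrality tolerance on `lambda - 1`.
#' @return A list with `x_hat`, `ess_class`, a tibble `mutants`
#'   (`phenotype`, `lambda`, `invades`), logical `direction_i`,
#'   `direction_ii` and `pass`, and any counterexample rows.
#' @export
verify_external_stability_ess <- function(model, phat = NULL,
                            phenotype_grid = seq(0, 1, length.out = 11),
                            tol = 1e-9) {
  stopifnot(inherits(model, "two_locus_model"))
  if (is.null(phat)) phat <- find_internal_equilibrium(model)$p
  b <- model$b; a <- model$a
  res <- purrr::map_dfr(phenotype_grid, function(v) {
    mut <- mutant_spec(array(v, dim = c(b, a, b)))
    es <- external_stability(model, phat, mut)
    tibble::tibble(phenotype = v, lambda = es$lambda,
                   invades = es$lambda > 1 + tol)
  })
  xhat <- mean_phenotype2(phat, model)
  ess_class <- classify_strategy(xhat, model$W, tol = 1e-6)$ess_class[1L]
  none_invade <- !any(res$invades)
  is_ess <- ess_class %in% c("strict", "weak")
  direction_i <- !none_invade || is_ess
  # internal stability via the spectral radius of the resident Jacobian
  radius <- tryCatch(
    internal_stability(function(p) {
      as.vector(twolocus_step(matrix(p, a, b), model))
    }, as.vector(phat), fixed_point_tol = 1e-6),
    error = function(e) NA_real_)
  internally_stable <- is.finite(radius) && radius < 1 + 1e-6
  direction_ii <- !(is_ess && internally_stable) || none_invade
  list(x_hat = xhat, ess_class = ess_class, mutants = res,
       internally_stable = internally_stable, radius = radius,
       direction_i = direction_i, direction_ii = direction_ii,
       pass = direction_i && direction_ii,
       counterexamples = res[res$invades & is_ess & internally_stable, ])
}
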