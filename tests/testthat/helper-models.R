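# Shared fixtures and independent oracles used across the suite.

pd_game <- function() payoff_matrix(w11 = 3, w10 = 0, w01 = 5, w00 = 1)
hd_game <- function() payoff_matrix(w11 = 1, w10 = 3, w01 = 4, w00 = 0)

# Brute-force ESS oracle: checks conditions (strict / weak) over a dense
# grid of alternative strategies, independently of classify_strategy's
# endpoint shortcut.
brute_force_ess_class <- function(x, W, y_grid = seq(0, 1, by = 0.01),
                                  tol = 1e-9) {
  y <- y_grid[abs(y_grid - x) > tol]
  m1 <- payoff(x, x, W) - payoff(y, x, W)
  m2 <- payoff(x, y, W) - payoff(y, y, W)
  if (all(m1 > tol)) return("strict")
  if (all(m1 > tol | (abs(m1) <= tol & m2 > tol))) return("weak")
  "none"
}

# Closed-form interior mixed-ESS candidate of a 2x2 game.
interior_candidate <- function(W) {
  (W[["w10"]] - W[["w00"]]) / ((W[["w10"]] - W[["w00"]]) + (W[["w01"]] - W[["w11"]]))
}

# 2-allele diploid model whose phenotype range spans [0, 1] (so any mixed
# ESS is attainable): homozygotes fixed at 1 and 0, heterozygote random.
spanning_diploid_model <- function(W, x12 = stats::runif(1)) {
  diploid_locus_model(matrix(c(1, x12, x12, 0), 2, 2), W)
}

# All equilibria of the 2-allele diploid recursion: boundaries plus interior
# roots of the marginal-fitness difference, found by sign scanning.
diploid_equilibria_2allele <- function(model, n_scan = 400) {
  step1 <- function(p1) diploid_step(c(p1, 1 - p1), model)[1L]
  d <- function(p1) step1(p1) - p1
  ps <- seq(1e-6, 1 - 1e-6, length.out = n_scan)
  ds <- vapply(ps, d, numeric(1))
  roots <- c(0, 1)
  for (i in seq_len(n_scan - 1L)) {
    if (sign(ds[i]) != sign(ds[i + 1L]) && ds[i] != 0) {
      roots <- c(roots, stats::uniroot(d, c(ps[i], ps[i + 1L]), tol = 1e-12)$root)
    }
  }
  sort(unique(roots))
}

# Block-resampled growth-rate estimate from a branching simulation: returns
# the per-generation growth factor between two census points with its SE.
block_growth <- function(counts_a, counts_b, gens_apart, n_blocks = 20L) {
  n <- length(counts_a)
  blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  g <- vapply(blocks, function(i) {
    ma <- mean(counts_a[i]); mb <- mean(counts_b[i])
    if (ma <= 0) NA_real_ else (mb / ma)^(1 / gens_apart)
  }, numeric(1))
  g <- g[is.finite(g)]
  list(mean = mean(g), se = stats::sd(g) / sqrt(length(g)))
}
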