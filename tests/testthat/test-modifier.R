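test_that("resident step handles absorbing, randomizing and neutral regimes", {
  spec <- modifier_model(T = 10, s1 = 0.1, s2 = 0.1)
  # no mutation, favoured allele fixed: absorbing
  expect_equal(resident_step(1, 1, 0, spec), 1)
  # mutation rate 1/2 randomizes completely
  expect_equal(resident_step(0.8, 1, 0.5, spec), 0.5)
  expect_equal(resident_step(0.1, 2, 0.5, spec), 0.5)
  # neutral selection: pure mutation balance
  spec0 <- modifier_model(T = 10, s1 = 0, s2 = 0)
  for (p in c(0.1, 0.6)) {
    expect_equal(resident_step(p, 1, 0.02, spec0), p * 0.98 + (1 - p) * 0.02)
  }
})

test_that("the resident limit cycle converges and collapses appropriately", {
  # the printed fluctuating regime reaches a tight periodic orbit
  spec <- modifier_model(T = 50, s1 = 0.01, s2 = 0.015, mu_res = 0.02)
  cyc <- find_limit_cycle(spec)
  expect_true(cyc$converged)
  expect_lt(cyc$residual, 1e-12)
  expect_length(cyc$states, 100L)
  expect_true(all(cyc$states >= 0 & cyc$states <= 1))
  # neutral major locus: the orbit sits at 1/2
  cyc0 <- find_limit_cycle(modifier_model(T = 10, s1 = 0, s2 = 0, mu_res = 0.05))
  expect_equal(cyc0$states, rep(0.5, 20), tolerance = 1e-12)
  # constant environment: the cycle collapses onto the mutation-selection
  # balance fixed point, checked against a direct root solve
  spc <- modifier_model(T = 10, s1 = 0.05, s2 = 0.1, mu_res = 0.01,
                        constant_env = TRUE)
  cycc <- find_limit_cycle(spc)
  expect_lt(diff(range(cycc$states)), 1e-12)
  fixed <- stats::uniroot(function(p) resident_step(p, 1, 0.01, spc) - p,
                          c(0.5, 1 - 1e-9), tol = 1e-13)$root
  expect_equal(cycc$states[1], fixed, tolerance = 1e-9)
})

test_that("per-generation mutant matrices have the expected structure", {
  # neutral selection, tight linkage: the map is the pure mutation matrix
  spec <- modifier_model(T = 10, s1 = 0, s2 = 0, r = 0, mu_res = 0.02,
                         mu_mut = 0.07)
  M <- mutant_generation_matrix(0.5, 1, spec)
  expect_equal(M, matrix(c(0.93, 0.07, 0.07, 0.93), 2, 2), tolerance = 1e-12)
  expect_equal(eigen(M)$values[1], 1)
  # with recombination the neutral map stays doubly stochastic (eigenvalue 1)
  specr <- modifier_model(T = 10, s1 = 0, s2 = 0, r = 0.3, mu_res = 0.02,
                          mu_mut = 0.07)
  Mr <- mutant_generation_matrix(0.5, 1, specr)
  expect_equal(colSums(Mr), c(1, 1), tolerance = 1e-12)
  expect_equal(max(Mod(eigen(Mr)$values)), 1, tolerance = 1e-12)
  # with r = 0 the matrix does not involve the resident background beyond
  # its mean fitness: the off-diagonal coupling is mutation only
  sp0 <- modifier_model(T = 10, s1 = 0.2, s2 = 0.1, r = 0, mu_res = 0.02,
                        mu_mut = 0)
  M0 <- mutant_generation_matrix(0.3, 1, sp0)
  expect_equal(M0[1, 2], 0)
  expect_equal(M0[2, 1], 0)
  expect_true(all(M0 >= 0))
})

test_that("a neutral modifier has cycle eigenvalue exactly 1", {
  for (prm in list(c(10, 0.05, 0.08, 0), c(50, 0.01, 0.015, 0.2),
                   c(25, 0.1, 0.1, 0.5))) {
    spec <- modifier_model(T = prm[1], s1 = prm[2], s2 = prm[3], r = prm[4],
                           mu_res = 0.02, mu_mut = 0.02)
    expect_equal(invasion_eigenvalue(spec)$lam_cycle, 1, tolerance = 1e-9)
  }
})

test_that("the reduction principle holds in a constant environment", {
  spec <- modifier_model(T = 25, s1 = 0.05, s2 = 0.1, r = 0.2, mu_res = 0.02,
                         constant_env = TRUE)
  cyc <- find_limit_cycle(spec)
  grid <- seq(0, 0.05, length.out = 21)
  for (mu_hat in grid[grid > 0]) {
    sp <- modifier_model(T = 25, s1 = 0.05, s2 = 0.1, r = 0.2, mu_res = mu_hat,
                         constant_env = TRUE)
    cy <- find_limit_cycle(sp)
    lam <- vapply(grid, function(mu) invasion_eigenvalue(sp, cy, mu)$lam_cycle,
                  numeric(1))
    expect_true(all((lam > 1 + 1e-9) == (grid < mu_hat - 1e-12)),
                info = sprintf("resident %g", mu_hat))
  }
  er <- es_rate(spec)
  expect_equal(er$mu_star, 0)
  expect_identical(er$method, "boundary")
  expect_true(er$uninvadable)
})

test_that("the ES mutation rate tracks the environmental period and recombination", {
  # interior ES rate close to 1/T at tight linkage
  er50 <- es_rate(modifier_model(T = 50, s1 = 0.01, s2 = 0.015, r = 0))
  expect_identical(er50$method, "diagonal_sign_change")
  expect_gt(er50$mu_star, 0.5 / 50)
  expect_lt(er50$mu_star, 2 / 50)
  # symmetric weak costs give a nearby, globally uninvadable ES rate
  ers <- es_rate(modifier_model(T = 50, s1 = 0.0125, s2 = 0.0125, r = 0))
  expect_true(ers$uninvadable)
  expect_lt(abs(ers$mu_star - er50$mu_star) / er50$mu_star, 0.25)
  # the ES rate declines as the modifier recombines away from the major locus
  mu_by_r <- vapply(c(0, 0.05, 0.1, 0.2, 0.5), function(r) {
    es_rate(modifier_model(T = 50, s1 = 0.01, s2 = 0.015, r = r))$mu_star
  }, numeric(1))
  expect_true(all(diff(mu_by_r) <= 1e-9))
  expect_equal(mu_by_r[length(mu_by_r)], 0)
})

test_that("the monodromy eigenvalue sign matches a stochastic lineage simulation", {
  # seeded branching realizations of the rare modifier lineage
  set.seed(606)
  pts <- list(
    modifier_model(T = 10, s1 = 0.3, s2 = 0.35, r = 0,
                   mu_res = 0.002, mu_mut = 0.1),
    modifier_model(T = 10, s1 = 0.3, s2 = 0.35, r = 0,
                   mu_res = 0.4, mu_mut = 0.05),
    modifier_model(T = 10, s1 = 0.2, s2 = 0.2, r = 0.5,
                   mu_res = 0.3, mu_mut = 0.02),
    modifier_model(T = 10, s1 = 0.3, s2 = 0.2, r = 0,
                   mu_res = 0.01, mu_mut = 0.05, constant_env = TRUE),
    modifier_model(T = 10, s1 = 0.3, s2 = 0.2, r = 0.1,
                   mu_res = 0.25, mu_mut = 0.01, constant_env = TRUE)
  )
  for (spec in pts) {
    iv <- invasion_eigenvalue(spec)
    expect_gt(abs(iv$lam_pergen - 1), 1e-3)  # decisive parameter points
    # realized per-cycle growth between cycles 2 and 3 of the branching run
    sim2 <- simulate_modifier_branching(spec, n_cycles = 2L, replicates = 2e4L)
    sim3 <- simulate_modifier_branching(spec, n_cycles = 3L, replicates = 2e4L)
    m2 <- mean(sim2$totals); m3 <- mean(sim3$totals)
    ratio <- m3 / m2
    se <- ratio * sqrt(stats::var(sim2$totals) / (m2^2 * length(sim2$totals)) +
                         stats::var(sim3$totals) / (m3^2 * length(sim3$totals)))
    expect_lt(abs(ratio - iv$lam_cycle), 3 * se + 1e-12)
    expect_equal(sign(log(ratio)), sign(log(iv$lam_cycle)))
  }
})

test_that("modifier PIPs are neutral on the diagonal and all-ones when neutral", {
  spec0 <- modifier_model(T = 10, s1 = 0, s2 = 0, r = 0.1)
  g0 <- modifier_pip(spec0, seq(0, 0.05, length.out = 6))
  expect_true(all(abs(g0$lambda - 1) < 1e-9))
  expect_false(any(g0$invades))
  spec <- modifier_model(T = 20, s1 = 0.05, s2 = 0.06, r = 0)
  g <- modifier_pip(spec, seq(0.005, 0.1, length.out = 9))
  diag_rows <- g[g$resident == g$mutant, ]
  expect_true(all(abs(diag_rows$lambda - 1) < 1e-8))
  # somewhere above and somewhere below the diagonal invasion occurs/fails
  expect_true(any(g$invades) && !all(g$invades))
})
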