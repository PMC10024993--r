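test_that("group-state enumeration is complete, ordered, and capped", {
  expect_equal(enumerate_group_states(2), matrix(c(1, 2), 2, 1))
  s2 <- enumerate_group_states(c(1, 1))
  expect_equal(s2, matrix(c(0, 1, 1, 1, 0, 1), 3, 2))
  expect_equal(nrow(enumerate_group_states(3)), 3L)
  expect_equal(nrow(enumerate_group_states(c(2, 3))), 11L)
  expect_error(enumerate_group_states(c(99, 99), cap = 100), "coarsen")
})

test_that("the projection matrix satisfies the offspring-accounting identity", {
  # total class-s' offspring from a state-k group equals the k-weighted sum
  # of individual fitnesses, for built-in and random linear kernels
  set.seed(707)
  specs <- c(
    list(group_model(n = 2, m = 0.5, delta = 0.01, y = 1, xhat = 0, W = pd_game()),
         group_model(n = 3, m = 0.2, delta = 0.05, y = 0.8, xhat = 0.1, W = hd_game())),
    lapply(1:100, function(i) random_group_kernel())
  )
  for (spec in specs) {
    proj <- build_projection(spec)
    k <- seq_len(spec$n)
    lhs <- as.vector(t(k) %*% proj$A)   # offspring counted via group states
    rhs <- k * proj$omega               # offspring counted via individuals
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("leading eigenpair matches an independent power iteration", {
  expect_equal(leading_eigenpair(diag(2))$lambda, 1)
  ep <- leading_eigenpair(matrix(c(2, 0, 0, 1), 2, 2))
  expect_equal(ep$lambda, 2)
  expect_equal(ep$u, c(1, 0))
  set.seed(708)
  for (i in 1:20) {
    A <- matrix(runif(100), 10, 10)
    ep <- leading_eigenpair(A)
    v <- rep(1 / 10, 10)
    for (it in 1:5000) {
      w <- as.vector(A %*% v); lam_pi <- sum(w); v <- w / lam_pi
    }
    expect_equal(ep$lambda, lam_pi, tolerance = 1e-10)
    expect_equal(ep$u, v, tolerance = 1e-8)
  }
})

test_that("lineage fitness equals the leading eigenvalue", {
  set.seed(709)
  for (i in 1:50) {
    spec <- random_group_kernel()
    ia <- invasion_analysis(spec)
    expect_lt(abs(ia$lineage_fitness - ia$lambda), 1e-9)
  }
  # neutral mutants replace themselves exactly
  for (n in 1:3) for (m in c(0.2, 1)) {
    spec <- group_model(n = n, m = m, delta = 0, y = 0.7, xhat = 0.1,
                        W = pd_game())
    expect_equal(invasion_analysis(spec)$lambda, 1, tolerance = 1e-9)
    spec2 <- group_model(n = n, m = m, delta = 0.2, y = 0.4, xhat = 0.4,
                         W = hd_game())
    expect_equal(invasion_analysis(spec2)$lambda, 1, tolerance = 1e-9)
  }
  # panmictic single-individual groups: lambda is the fecundity ratio
  sp1 <- group_model(n = 1, m = 1, delta = 0.05, y = 1, xhat = 0, W = pd_game())
  expect_equal(invasion_analysis(sp1)$lambda,
               (1 + 0.05 * payoff(1, 0, pd_game())) /
                 (1 + 0.05 * payoff(0, 0, pd_game())),
               tolerance = 1e-12)
})

test_that("relatedness matches the island-model identity-by-descent value", {
  # neutral within-group relatedness has the closed form
  # (1-m)^2 / (n - (n-1)(1-m)^2); the lineage-based r must agree, and it
  # must rise to 1 as migration vanishes
  for (n in 2:3) for (m in c(0.8, 0.5, 0.2)) {
    spec <- group_model(n = n, m = m, delta = 0, y = 0.5, xhat = 0.5,
                        W = pd_game())
    r <- invasion_analysis(spec)$relatedness
    expect_equal(r, (1 - m)^2 / (n - (n - 1) * (1 - m)^2), tolerance = 1e-9,
                 info = sprintf("n=%d m=%g", n, m))
  }
  rs <- vapply(c(0.5, 0.1, 0.02, 0.004), function(m) {
    invasion_analysis(group_model(n = 2, m = m, delta = 0, y = 0.5,
                                  xhat = 0.5, W = pd_game()))$relatedness
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[length(rs)], 0.98)
  # a lone individual has no groupmates
  sp1 <- group_model(n = 1, m = 1, delta = 0, y = 0.5, xhat = 0.5, W = pd_game())
  expect_true(is.na(invasion_analysis(sp1)$relatedness))
})

test_that("relatedness agrees with a Monte-Carlo simulation of the life cycle", {
  set.seed(710)
  spec <- group_model(n = 2, m = 0.5, delta = 0, y = 0.5, xhat = 0.5,
                      W = pd_game())
  ia <- invasion_analysis(spec)
  # simulate the group branching process and measure the stabilized share of
  # two-mutant groups among mutant-containing groups, allele-weighted
  sim <- simulate_group_branching(spec, generations = 30L, replicates = 2e5L)
  counts <- sim$counts_by_state
  q2_hat <- 2 * counts[2] / (counts[1] + 2 * counts[2])
  se <- sqrt(q2_hat * (1 - q2_hat) / sum(counts))
  expect_lt(abs(q2_hat - ia$relatedness), 3 * se + 0.005)
})

test_that("cost-benefit decomposition behaves at the neutral point and asocial limit", {
  # neutral mutant: no costs, no benefits
  spec0 <- group_model(n = 3, m = 0.4, delta = 0.1, y = 0.3, xhat = 0.3,
                       W = pd_game())
  p0 <- decompose_costs_benefits(spec0)
  expect_equal(p0$cost, 0, tolerance = 1e-12)
  expect_equal(p0$benefit, 0, tolerance = 1e-12)
  # PD helping: positive own cost, positive received benefit
  spec <- group_model(n = 2, m = 0.5, delta = 0.05, y = 1, xhat = 0, W = pd_game())
  pp <- decompose_costs_benefits(spec)
  expect_gt(pp$cost, 0)
  expect_gt(pp$benefit, 0)
  # payoff independent of partners, full migration: no benefit channel
  spa <- group_model(n = 3, m = 1, delta = 0.1, y = 0.9, xhat = 0.2,
                     kernel = "linear", alpha = 1, beta = 0)
  pa <- decompose_costs_benefits(spa)
  expect_equal(pa$benefit, 0, tolerance = 1e-10)
  expect_lt(pa$cost, 0)  # raising an asocial beneficial trait: negative cost
})

test_that("both fitness partitions reconstruct the eigenvalue exactly", {
  W <- pd_game()
  for (n in c(2, 3)) for (m in c(0.2, 0.5, 1.0)) {
    for (delta in c(0.02, 0.01, 0.005)) {
      spec <- group_model(n = n, m = m, delta = delta, y = 1, xhat = 0, W = W)
      ia <- invasion_analysis(spec)
      inf <- inclusive_fitness(spec, ia)
      gp <- group_partition(spec, ia)
      expect_lt(abs(inf$lambda_if - gp$lambda_gs), 1e-12)
      expect_lt(abs(inf$lambda_if - ia$lambda), 1e-10)
    }
  }
  set.seed(711)
  for (i in 1:25) {
    spec <- random_group_kernel()
    ia <- invasion_analysis(spec)
    expect_lt(abs(inclusive_fitness(spec, ia)$lambda_if -
                    group_partition(spec, ia)$lambda_gs), 1e-12)
  }
})

test_that("helping is selected between groups and against within groups", {
  # a costly prosocial trait under the linear kernel: own coefficient
  # negative (paying the cost), groupmate coefficient positive and larger
  spec <- group_model(n = 3, m = 0.3, delta = 0.05, y = 1, xhat = 0.2,
                      kernel = "linear", alpha = -0.5, beta = 2)
  pp <- decompose_costs_benefits(spec)
  gp <- group_partition(spec)
  expect_gt(pp$cost, 0)
  expect_gt(pp$benefit, pp$cost)
  expect_gt(gp$omega_G, 0)
  expect_lt(gp$omega_dG, 0)
  # clonal-group limit: within-group selection carries the factor (1 - r)
  # and vanishes as migration (hence genetic mixing within groups) stops
  wdg <- vapply(c(0.5, 0.05, 0.004), function(m) {
    spc <- group_model(n = 2, m = m, delta = 0.02, y = 1, xhat = 0.2,
                       kernel = "linear", alpha = -0.5, beta = 2)
    ia <- invasion_analysis(spc)
    gp <- group_partition(spc, ia)
    pc <- decompose_costs_benefits(spc, ia)
    # the within-group term is exactly -(b + (n-1)c)(1 - r)/n
    expect_equal(gp$omega_dG,
                 -(pc$benefit + pc$cost) * (1 - ia$relatedness) / 2,
                 tolerance = 1e-12)
    abs(gp$omega_dG)
  }, numeric(1))
  expect_lt(wdg[3], 0.05 * wdg[1])
})

test_that("the eigenvalue matches the stochastic group branching growth rate", {
  set.seed(712)
  pts <- list(
    group_model(n = 2, m = 0.5, delta = 0.3, y = 1, xhat = 0, W = hd_game()),
    group_model(n = 2, m = 0.3, delta = 0.4, y = 0, xhat = 1, W = pd_game()),
    group_model(n = 3, m = 0.6, delta = 0.5, y = 1, xhat = 0.2, W = pd_game())
  )
  for (spec in pts) {
    lam <- invasion_analysis(spec)$lambda
    expect_gt(abs(lam - 1), 1e-3)
    sim10 <- simulate_group_branching(spec, generations = 10L, replicates = 4e4L)
    sim15 <- simulate_group_branching(spec, generations = 15L, replicates = 4e4L)
    m10 <- mean(sim10$final_totals); m15 <- mean(sim15$final_totals)
    g_hat <- (m15 / m10)^(1 / 5)
    se <- g_hat / 5 * sqrt(stats::var(sim10$final_totals) / (m10^2 * length(sim10$final_totals)) +
                             stats::var(sim15$final_totals) / (m15^2 * length(sim15$final_totals)))
    expect_lt(abs(g_hat - lam), 3 * se + 1e-12)
  }
})

test_that("the Fisherian sex ratio is the unique uninvadable resident", {
  # neutrality on the diagonal and at the 1:1 resident
  expect_equal(sex_ratio_invasion(0.3, 0.3), 1, tolerance = 1e-12)
  for (y in c(0.1, 0.5, 0.9)) {
    expect_equal(sex_ratio_invasion(y, 0.5), 1, tolerance = 1e-12)
  }
  # a mutant moving a biased population toward 1:1 invades
  expect_gt(sex_ratio_invasion(0.5, 0.3), 1)
  expect_gt(sex_ratio_invasion(0.5, 0.7), 1)
  expect_error(sex_ratio_invasion(0.5, 1), "inside")
  scan <- sex_ratio_scan()
  expect_equal(scan$resident[scan$uninvadable], 0.5)
})
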