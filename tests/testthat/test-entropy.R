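test_that("exact enumeration satisfies the thermodynamic identities", {
  for (seed in 1:10) {
    N <- sample(2:4, 1)
    p <- rand_params(N, 1, seed, coupling_sd = 1)
    marg <- state_marginal(runif(N, 0.2, 0.8))
    r <- exact_two_step(p, 1, marg)
    # production = entropy change + flow, and the flow decomposition
    expect_equal(r$production, (r$S_curr - r$S_prev) + r$flow,
                 tolerance = 1e-10)
    expect_equal(r$flow, -r$forward + r$backward, tolerance = 1e-12)
    # second law
    expect_gte(r$production, -1e-12)
    expect_equal(sum(r$marginal_curr), 1, tolerance = 1e-12)
  }
  p <- rand_params(3, 1, 99)
  expect_error(exact_two_step(p, 1, rep(1, 8)), "sum to 1")
  expect_error(exact_two_step(rand_params(4, 1, 1), 1,
                              state_marginal(0.5, 4), n_max = 3), "N <=")
})

test_that("stationary reversible systems produce no entropy", {
  # independent neurons at their stationary marginal
  fields <- c(-0.8, 0.4)
  p <- const_params(fields, matrix(0, 2, 2), T_ = 1)
  r <- exact_two_step(p, 1, state_marginal(plogis(fields)))
  expect_lt(abs(r$flow), 1e-12)
  expect_lt(abs(r$production), 1e-12)
  # symmetric couplings: iterate the marginal to its fixed point; the
  # synchronous dynamics then obey detailed balance
  set.seed(5)
  C <- matrix(rnorm(16, 0, 0.4), 4, 4); C <- (C + t(C)) / 2
  p2 <- const_params(rnorm(4, -0.3, 0.5), C, T_ = 1)
  marg <- state_marginal(0.5, 4)
  for (k in 1:3000) marg <- exact_two_step(p2, 1, marg)$marginal_curr
  r2 <- exact_two_step(p2, 1, marg)
  expect_lt(abs(r2$production), 1e-8)
})

test_that("summed exact flow bounds the total entropy change", {
  p <- rand_params(3, 8, seed = 17, coupling_sd = 0.8)
  ef <- entropy_flow_exact(p)
  S <- ef$entropy
  expect_gte(S[length(S)] - S[1] + sum(ef$flow), -1e-8)
  expect_equal(ef$production, diff(S) + ef$flow, tolerance = 1e-10)
})

test_that("sampling estimator is unbiased against enumeration and scales as 1/sqrt(n)", {
  p <- rand_params(4, 6, seed = 23, coupling_sd = 0.5, field_mean = -0.5)
  ef_ex <- entropy_flow_exact(p)
  ef_s <- entropy_flow_sampling(p, n_s = 10000, seed = 3)
  expect_true(all(abs(ef_s$flow - ef_ex$flow) < 4 * ef_s$se))
  expect_equal(ef_s$flow, -ef_s$forward + ef_s$backward, tolerance = 1e-12)
  expect_equal(colSums(ef_s$per_neuron), ef_s$flow, tolerance = 1e-12)
  # MC error shrinks roughly as n^(-1/2): reported se scales accordingly
  se_small <- mean(entropy_flow_sampling(p, n_s = 1000, seed = 4)$se)
  se_big <- mean(entropy_flow_sampling(p, n_s = 16000, seed = 5)$se)
  expect_equal(se_small / se_big, 4, tolerance = 0.35)
  # zero couplings, constant fields: flow indistinguishable from zero
  p0 <- const_params(c(-1, 0.5, 0), matrix(0, 3, 3), T_ = 5)
  ef0 <- entropy_flow_sampling(p0, n_s = 5000, seed = 6, p0 = plogis(c(-1, 0.5, 0)))
  expect_true(all(abs(ef0$flow) < 4 * ef0$se))
})

test_that("mean-field rates track the exact marginals for weak couplings", {
  # zero couplings: rates equal the logistic of the field exactly
  p0 <- param_trajectory(matrix(seq(-2, 1, length.out = 6), 1, 6),
                         array(0, c(1, 1, 6)))
  mf0 <- mean_field_rates(p0, m0 = 0.4)
  expect_equal(mf0$m[1, -1], plogis(p0$fields[1, ]), tolerance = 1e-12)
  expect_equal(max(mf0$d_prev), 0)
  # weak couplings: within 0.01 of the enumerated marginal rates
  p <- rand_params(5, 8, seed = 31, coupling_sd = 0.3, field_mean = -0.3)
  mf <- mean_field_rates(p, m0 = 0.5)
  marg <- state_marginal(0.5, 5)
  S <- kinflow:::enumerate_states(5)
  for (t in 1:8) {
    marg <- exact_two_step(p, t, marg)$marginal_curr
    exact_rate <- as.numeric(marg %*% S)
    expect_lt(max(abs(mf$m[, t + 1] - exact_rate)), 0.01)
  }
})

test_that("mean-field flow vanishes in equilibrium and matches enumeration when couplings are weak", {
  # uncoupled stationary system: forward and backward entropies cancel
  fields <- c(-1.2, 0.3, 0.8)
  p0 <- const_params(fields, matrix(0, 3, 3), T_ = 4)
  ef0 <- entropy_flow_meanfield(p0, m0 = plogis(fields))
  expect_equal(ef0$flow, rep(0, 4), tolerance = 1e-12)
  # all parameters zero: both conditional entropies are N log 2
  pz <- const_params(rep(0, 3), matrix(0, 3, 3), T_ = 2)
  efz <- entropy_flow_meanfield(pz, m0 = 0.5)
  expect_equal(efz$forward, rep(3 * log(2), 2), tolerance = 1e-12)
  expect_equal(efz$backward, rep(3 * log(2), 2), tolerance = 1e-12)
  # weak-coupling accuracy against the enumeration oracle
  p <- rand_params(6, 10, seed = 37, coupling_sd = 0.3, field_mean = -0.2)
  ef_ex <- entropy_flow_exact(p)
  ef_mf <- entropy_flow_meanfield(p, m0 = 0.5)
  tol <- pmax(0.02 * 6, 0.1 * abs(ef_ex$flow))
  expect_true(all(abs(ef_mf$flow - ef_ex$flow) <= tol))
  expect_equal(ef_mf$flow, -ef_mf$forward + ef_mf$backward, tolerance = 1e-12)
  expect_equal(colSums(ef_mf$per_neuron), ef_mf$flow, tolerance = 1e-12)
})

test_that("steady-state mean-field flow is self-consistent", {
  # no couplings: no input fluctuations, no flow
  st0 <- entropy_flow_steady(c(-1, 0.5), matrix(0, 2, 2))
  expect_equal(st0$flow, 0, tolerance = 1e-12)
  expect_equal(st0$m, plogis(c(-1, 0.5)), tolerance = 1e-10)
  # steady value equals the dynamic mean-field flow after burn-in
  set.seed(7)
  C <- matrix(rnorm(64, 0.1, 0.15), 8, 8)
  f <- rnorm(8, -0.8, 0.3)
  st <- entropy_flow_steady(f, C)
  T_ <- 60
  pd <- const_params(f, C, T_ = T_)
  efd <- entropy_flow_meanfield(pd, m0 = 0.5)
  expect_equal(efd$flow[T_], st$flow, tolerance = 1e-6)
  # quadrature value matches a large Monte-Carlo evaluation of the integral
  g <- f + as.numeric(C %*% st$m)
  d <- as.numeric((C^2) %*% (st$m * (1 - st$m)))
  set.seed(8)
  z <- rnorm(1e6)
  mc <- vapply(1:8, function(i)
    mean((plogis(g[i] + z * sqrt(d[i])) - st$m[i]) * z * sqrt(d[i])),
    numeric(1))
  mc_se <- vapply(1:8, function(i)
    sd((plogis(g[i] + z * sqrt(d[i])) - st$m[i]) * z * sqrt(d[i])) / 1000,
    numeric(1))
  expect_true(all(abs(st$per_neuron - mc) < 4 * mc_se))
})

test_that("quadrature rule is converged at the default node count", {
  # representative integrands at representative input statistics (mean-field
  # input variances in fitted models are of order 1 or below)
  g <- c(-3, -1, 0, 1.5); d <- c(0.04, 0.5, 2, 4)
  chi <- function(H) { R <- plogis(H); -R * H + kinflow:::softplus(H) }
  for (f in list(plogis, chi, kinflow:::softplus)) {
    a <- kinflow:::gauss_expect(f, g, d, nodes = 100)
    b <- kinflow:::gauss_expect(f, g, d, nodes = 201)
    expect_lt(max(abs(a - b)), 1e-10)
  }
})

test_that("a step decrease in the field drives a transient flow excursion", {
  # fields drop sharply mid-series; exact flow spikes positive at the step
  # while the population rate falls (organization costs dissipation)
  T_ <- 12
  fields <- matrix(c(rep(0.5, 18), rep(-2.5, 18)), 3, T_)
  set.seed(9)
  C <- matrix(rnorm(9, 0, 0.3), 3, 3)
  p <- param_trajectory(fields, array(C, c(3, 3, T_)))
  ef <- entropy_flow_exact(p, p0 = plogis(0.5))
  expect_gt(ef$flow[7], max(ef$flow[4:6]) + 0.01)
  expect_gt(ef$flow[7], max(ef$flow[10:12]) + 0.01)
})
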