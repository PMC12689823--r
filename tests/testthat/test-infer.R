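test_that("prediction step adds state noise and keeps the mean", {
  m <- c(0.3, -1)
  P <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  q0 <- matrix(0, 2, 2)
  expect_equal(predict_step(m, P, q0), list(pred_mean = m, pred_cov = P))
  pr <- predict_step(m, P, diag(c(3, 3)))
  expect_identical(pr$pred_mean, m)
  expect_equal(pr$pred_cov[1, 1], 5)
})

test_that("filter step recovers the Bernoulli MLE under a diffuse prior", {
  # one neuron, no informative coupling data: 25 spikes in 100 trials
  L <- 100
  x_prev <- matrix(0, 1, L)                  # silent previous bin
  x_t <- matrix(c(rep(1, 25), rep(0, 75)), 1, L)
  up <- filter_step(c(0, 0), 1e6 * diag(2), x_t, x_prev, i = 1)
  expect_equal(up$filt_mean[1], qlogis(0.25), tolerance = 1e-3)
  # conditioning never inflates the marginal variance
  expect_true(all(diag(up$filt_cov) <= diag(1e6 * diag(2)) + 1e-8))
})

test_that("filtered variance never exceeds predicted variance", {
  spk <- simulate_spikes(rand_params(3, 12, seed = 4, field_mean = -1),
                         L = 60, seed = 5)
  post <- kinetic_estep(spk, lapply(1:3, function(i)
    neuron_hyperparams(rep(0, 4), diag(4), 0.05 * diag(4))))
  for (i in 1:3) {
    n <- post$neurons[[i]]
    expect_true(all(apply(n$filt_cov, 3, diag) <=
                      apply(n$pred_cov, 3, diag) + 1e-10))
    # smoothed equals filtered at the last bin
    expect_equal(n$smooth_mean[, 12], n$filt_mean[, 12])
    expect_equal(n$smooth_cov[, , 12], n$filt_cov[, , 12])
  }
})

test_that("smoother reduces to the filter when T = 1 and gains are identity at q = 0", {
  spk1 <- simulate_spikes(rand_params(2, 1, seed = 6), L = 30, seed = 7)
  cfg0 <- fit_config(freeze_q = TRUE)
  post1 <- fit_em(spk1, cfg0)$posterior
  n <- post1$neurons[[1]]
  expect_equal(n$smooth_mean, n$filt_mean)
  # q = 0 on a longer series: every smoother gain is the identity
  spk2 <- simulate_spikes(rand_params(2, 6, seed = 8), L = 30, seed = 9)
  post2 <- fit_em(spk2, cfg0)$posterior
  for (t in 1:5)
    expect_equal(post2$neurons[[1]]$gains[, , t], diag(3), tolerance = 1e-8)
})

test_that("smoothed means approximate the brute-force joint MAP (N = 1 oracle)", {
  # the single-pass Laplace smoother tracks the joint posterior mode up to
  # the skewness of the per-bin logistic posteriors; with only L = 10
  # Bernoulli trials per bin that agreement is at the few-percent level
  # (it is exact in the linear-Gaussian limit)
  p <- param_trajectory(matrix(c(-0.5, 0.2, 0.6, -0.1), 1, 4),
                        array(c(0.4, 0.3, -0.2, 0.5), c(1, 1, 4)))
  spk <- simulate_spikes(p, L = 10, seed = 12)
  hyp <- list(neuron_hyperparams(c(0, 0), diag(2), 0.3 * diag(2)))
  post <- kinetic_estep(spk, hyp)
  oracle <- joint_map_oracle(spk, hyp[[1]])
  expect_equal(post$neurons[[1]]$smooth_mean, oracle, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("lag-one covariance follows the gain formula", {
  # scalar arithmetic case
  expect_equal(lag_one_covariance(matrix(2), matrix(4), matrix(3)),
               matrix(1.5))
  # q = 0 makes it equal the smoothed covariance
  W <- matrix(c(1, 0.2, 0.2, 0.5), 2, 2)
  Sm <- matrix(c(0.8, 0.1, 0.1, 0.4), 2, 2)
  expect_equal(lag_one_covariance(W, W, Sm), Sm, tolerance = 1e-12)
  expect_equal(dim(lag_one_covariance(W, W + diag(2), Sm)), c(2L, 2L))
})

test_that("state-noise update vanishes for a constant posterior and matches structures", {
  d <- 3; T_ <- 6
  C <- matrix(c(1, .2, .1, .2, .8, .3, .1, .3, .6), 3, 3)
  fake <- structure(list(N = 1L, T = T_, L = 10L, neurons = list(list(
    smooth_mean = matrix(0.7, d, T_),
    smooth_cov = array(C, c(d, d, T_)),
    lag_one = array(C, c(d, d, T_)),
    pred_mean = matrix(0, d, T_), pred_cov = array(diag(d), c(d, d, T_)),
    filt_mean = matrix(0, d, T_), filt_cov = array(diag(d), c(d, d, T_))))),
    class = "kinetic_posterior")
  hyp0 <- list(neuron_hyperparams(rep(0, d), diag(d), diag(d)))
  up <- m_step(fake, hyp0, fit_config())
  expect_equal(up[[1]]$q, matrix(0, d, d), tolerance = 1e-12)
  expect_equal(up[[1]]$mu, rep(0.7, d))
  expect_equal(up[[1]]$sigma, C)
  # zero covariances, known increments: Q is the mean outer product
  incr <- matrix(rnorm(d * T_), d, T_)
  means <- t(apply(incr, 1, cumsum))
  fake2 <- fake
  fake2$neurons[[1]]$smooth_mean <- means
  fake2$neurons[[1]]$smooth_cov <- array(0, c(d, d, T_))
  fake2$neurons[[1]]$lag_one <- array(0, c(d, d, T_))
  up2 <- m_step(fake2, hyp0, fit_config())
  Qexp <- matrix(0, d, d)
  for (t in 2:T_) Qexp <- Qexp + tcrossprod(incr[, t])
  expect_equal(up2[[1]]$q, Qexp / (T_ - 1), tolerance = 1e-8)
  # diagonal option equals the diagonal of the full option
  upd <- m_step(fake2, hyp0, fit_config(q_structure = "diagonal"))
  expect_equal(upd[[1]]$q, diag(diag(up2[[1]]$q), d), tolerance = 1e-8)
  ups <- m_step(fake2, hyp0, fit_config(q_structure = "scalar"))
  expect_equal(ups[[1]]$q, sum(diag(up2[[1]]$q)) / d * diag(d),
               tolerance = 1e-8)
})

test_that("Laplace marginal likelihood matches dense quadrature (N = 1 oracle)", {
  p <- param_trajectory(matrix(c(-0.3, 0.5), 1, 2),
                        array(c(0.4, -0.2), c(1, 1, 2)))
  spk <- simulate_spikes(p, L = 3, seed = 21)
  hyp <- list(neuron_hyperparams(c(0, 0), diag(2), 0.4 * diag(2)))
  post <- kinetic_estep(spk, hyp)
  expect_equal(post$log_marginal, quad_marginal_ll(spk, hyp[[1]]),
               tolerance = 0.05)
  # the standalone evaluator agrees with the filter-pass accumulation
  expect_equal(marginal_log_likelihood(post, spk), post$log_marginal,
               tolerance = 1e-10)
})

test_that("EM increases the marginal likelihood and stationary mode yields constant parameters", {
  truth <- sample_param_trajectories(2, 25, gp_config(-1.5, 0.4, 15),
                                     gp_config(0.3, 0.3, 8), seed = 31)
  spk <- simulate_spikes(truth, L = 120, seed = 32)
  fit <- fit_em(spk, fit_config(max_em_iter = 25))
  ll <- fit$ll_trace
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-1])))
  # results are the same regardless of the internal neuron loop order: the
  # per-neuron blocks are computed independently
  est <- smoothed_params(fit$posterior)
  rev_spk <- spike_tensor(spk$data[2:1, , ], spk$bin_width, spk$t0)
  fit_rev <- fit_em(rev_spk, fit_config(max_em_iter = 25))
  est_rev <- smoothed_params(fit_rev$posterior)
  expect_equal(est$fields[1, ], est_rev$fields[2, ], tolerance = 1e-8)
  # frozen state noise on stationary data: parameters constant across bins
  pc <- const_params(c(-1, 0.5), matrix(c(0.2, -0.3, 0.4, 0.1), 2, 2), T_ = 15)
  spk_st <- simulate_spikes(pc, L = 150, seed = 33)
  fit0 <- fit_em(spk_st, fit_config(freeze_q = TRUE))
  sp <- smoothed_params(fit0$posterior)
  expect_lt(max(apply(sp$fields, 1, function(v) diff(range(v)))), 1e-6)
  expect_lt(max(apply(sp$couplings, c(1, 2),
                      function(v) diff(range(v)))), 1e-6)
})

test_that("trial shuffling shrinks fitted cross-couplings", {
  pc <- const_params(c(-1.2, -1.2),
                     matrix(c(0.3, 2, 2, 0.3), 2, 2), T_ = 25)
  spk <- simulate_spikes(pc, L = 150, seed = 41)
  fit <- fit_em(spk, fit_config(max_em_iter = 30))
  fit_sh <- fit_em(trial_shuffle(spk, seed = 42), fit_config(max_em_iter = 30))
  cross <- function(f) {
    cp <- smoothed_params(f$posterior)$couplings
    mean(c(abs(cp[1, 2, ]), abs(cp[2, 1, ])))
  }
  expect_lt(cross(fit_sh), 0.5 * cross(fit))
})
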