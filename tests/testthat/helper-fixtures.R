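# small deterministic fixtures shared across test files

# constant-parameter trajectory
const_params <- function(fields, couplings, T_) {
  N <- length(fields)
  param_trajectory(matrix(fields, N, T_),
                   array(couplings, dim = c(N, N, T_)))
}

# random small system with controlled coupling scale
rand_params <- function(N, T_, seed, field_sd = 1, coupling_sd = 0.3,
                        field_mean = 0) {
  set.seed(seed)
  param_trajectory(
    matrix(rnorm(N * T_, field_mean, field_sd), N, T_),
    array(rnorm(N * N * T_, 0, coupling_sd / sqrt(N)), dim = c(N, N, T_)))
}

# brute-force joint MAP of the full parameter path (N = 1 only): direct
# optimization of the log joint posterior over theta_{1:T} in R^(2T)
joint_map_oracle <- function(spikes, hyper) {
  x <- spikes$data[1, , ]                      # (T+1) x L
  T_ <- nrow(x) - 1
  mu <- hyper$mu; Sig_i <- solve(hyper$sigma); Q_i <- solve(hyper$q)
  negpost <- function(v) {
    th <- matrix(v, 2, T_)
    ll <- 0
    for (t in seq_len(T_)) {
      h <- th[1, t] + th[2, t] * x[t, ]
      ll <- ll + sum(x[t + 1, ] * h - log1p(exp(h)))
    }
    d1 <- th[, 1] - mu
    pr <- -0.5 * sum(d1 * (Sig_i %*% d1))
    if (T_ >= 2) for (t in 2:T_) {
      dt <- th[, t] - th[, t - 1]
      pr <- pr - 0.5 * sum(dt * (Q_i %*% dt))
    }
    -(ll + pr)
  }
  o <- optim(rep(0, 2 * T_), negpost, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  matrix(o$par, 2, T_)
}

# dense-grid quadrature of the exact marginal likelihood for N = 1
# (theta_t in R^2), sequential over bins
quad_marginal_ll <- function(spikes, hyper, gl = 61, lim = 6) {
  x <- spikes$data[1, , ]
  T_ <- nrow(x) - 1
  g <- seq(-lim, lim, length.out = gl)
  th <- as.matrix(expand.grid(f = g, c = g))
  dA <- (g[2] - g[1])^2
  dmvn <- function(pts, m, S) {
    Si <- solve(S); d <- t(pts) - m
    exp(-0.5 * colSums(d * (Si %*% d))) / (2 * pi * sqrt(det(S)))
  }
  loglik_t <- function(t) vapply(seq_len(nrow(th)), function(k) {
    h <- th[k, 1] + th[k, 2] * x[t, ]
    sum(x[t + 1, ] * h - log1p(exp(h)))
  }, numeric(1))
  K <- matrix(0, nrow(th), nrow(th))
  for (k in seq_len(nrow(th))) K[, k] <- dmvn(th, th[k, ], hyper$q)
  alpha <- dmvn(th, hyper$mu, hyper$sigma) * exp(loglik_t(1))
  ll <- 0
  if (T_ >= 2) for (t in 2:T_) {
    s <- sum(alpha) * dA
    ll <- ll + log(s)
    alpha <- (K %*% (alpha / s)) * dA * exp(loglik_t(t))
  }
  ll + log(sum(alpha) * dA)
}
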