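# Gauss-Hermite rule for standard-normal expectations: E[f(Z)] ~ sum wt f(z).
# 100 nodes by default; validated against a 201-node rule in the test suite.
gauss_rule <- local({
  cache <- list()
  function(n = 100) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      gh <- pracma::gaussHermite(n)
      cache[[key]] <<- list(z = sqrt(2) * gh$x, wt = gh$w / sqrt(pi))
    }
    cache[[key]]
  }
})

# E over z ~ N(0,1) of f(mean + z * sqrt(var)), rowwise over vectors mean/var;
# degenerate rows (var below tol) are evaluated at their mean
gauss_expect <- function(f, mean, var, nodes = 100, var_tol = 1e-12) {
  rule <- gauss_rule(nodes)
  sd <- sqrt(pmax(var, 0))
  H <- outer(sd, rule$z) + mean          # n x nodes
  out <- as.numeric(f(H) %*% rule$wt)
  deg <- var < var_tol
  if (any(deg)) out[deg] <- f(matrix(mean[deg], ncol = 1))[, 1]
  out
}

#' Exact entropy flow and production over one transition
#'
#' Enumerates all 2^N population states, builds the transition matrix of the
#' kinetic Ising model at bin t, propagates the supplied marginal, and
#' computes the entropy flow (expected log-ratio of the forward transition
#' probability to the same kernel evaluated on the time-swapped pair), the
#' entropy production, and the Shannon entropies of the two marginals.
#' `0 * log 0` terms are treated as zero.
#'
#' @param params a [param_trajectory].
#' @param t bin index.
#' @param marginal_prev probability vector of length 2^N over the canonical
#'   binary state ordering (see [state_marginal]); must sum to 1.
#' @param n_max capacity guard on the population size (default 12).
#' @return list with `flow`, `forward`, `backward`, `production`, `S_prev`,
#'   `S_curr`, `marginal_curr`.
#' @export
exact_two_step <- function(params, t, marginal_prev, n_max = 12) {
  N <- nrow(params$fields)
  if (N > n_max) stop("exact enumeration limited to N <= ", n_max)
  if (abs(sum(marginal_prev) - 1) > 1e-9)
    stop("'marginal_prev' must sum to 1")
  logP <- log_transition_matrix(params, t)      # [prev, curr]
  P <- exp(logP)
  joint <- marginal_prev * P                    # [prev, curr]
  marginal_curr <- colSums(joint)
  forward <- -sum(joint * logP)
  backward <- -sum(joint * t(logP))             # same kernel, swapped arguments
  flow <- -forward + backward
  ent <- function(p) { nz <- p > 0; -sum(p[nz] * log(p[nz])) }
  S_prev <- ent(marginal_prev)
  S_curr <- ent(marginal_curr)
  list(flow = flow, forward = forward, backward = backward,
       production = (S_curr - S_prev) + flow,
       S_prev = S_prev, S_curr = S_curr, marginal_curr = marginal_curr)
}

#' Marginal over all binary patterns for independent neurons
#'
#' Probability vector over the 2^N canonical binary patterns for neurons
#' spiking independently with probabilities `p`.
#'
#' @param p per-neuron spike probability, length N (or scalar, recycled).
#' @param N population size.
#' @return numeric vector of length 2^N summing to 1.
#' @export
state_marginal <- function(p, N = length(p)) {
  p <- rep_len(p, N)
  S <- enumerate_states(N)
  exp(S %*% log(p) + (1 - S) %*% log1p(-p))[, 1]
}

#' Exact entropy-flow series by enumeration
#'
#' Convenience driver over [exact_two_step]: propagates the state marginal
#' from an independent-Bernoulli initial condition through all bins.
#'
#' @param params a [param_trajectory].
#' @param p0 initial spike probability (matches the simulator's initial
#'   condition; default 0.5).
#' @param n_max capacity guard on N.
#' @return an [entropy_flow_series] with method `"exact"`, carrying the exact
#'   per-bin `production` and the system `entropy` at bins 0..T.
#' @export
entropy_flow_exact <- function(params, p0 = 0.5, n_max = 12) {
  N <- nrow(params$fields); T_ <- ncol(params$fields)
  marg <- state_marginal(p0, N)
  flow <- fwd <- bwd <- prod_ <- numeric(T_)
  S <- numeric(T_ + 1)
  for (t in seq_len(T_)) {
    r <- exact_two_step(params, t, marg, n_max = n_max)
    flow[t] <- r$flow; fwd[t] <- r$forward; bwd[t] <- r$backward
    prod_[t] <- r$production
    S[t] <- r$S_prev; S[t + 1] <- r$S_curr
    marg <- r$marginal_curr
  }
  entropy_flow_series(seq_len(T_), flow, fwd, bwd, method = "exact",
                      production = prod_, entropy = S)
}

#' Sampling estimator of the entropy-flow series
#'
#' Runs `n_s` independent chains of the kinetic Ising dynamics from an
#' independent Bernoulli(`p0`) start and averages, at every bin, the
#' log-ratio of the forward transition probability of the sampled pair to the
#' same kernel evaluated on the time-swapped pair. The estimator is unbiased
#' for the exact flow; a per-bin Monte-Carlo standard error is reported.
#'
#' @param params a [param_trajectory].
#' @param n_s number of chains (default 10000).
#' @param seed integer seed.
#' @param p0 initial spike probability.
#' @return an [entropy_flow_series] with method `"sampling"`, per-neuron
#'   contributions, and `se`.
#' @export
entropy_flow_sampling <- function(params, n_s = 10000, seed = 1, p0 = 0.5) {
  stopifnot(n_s >= 1)
  N <- nrow(params$fields); T_ <- ncol(params$fields)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(child_seed(seed, "flowsample"))
  x_prev <- matrix(as.numeric(runif(N * n_s) < p0), N, n_s)
  flow <- fwd <- bwd <- se <- numeric(T_)
  per_neuron <- matrix(0, N, T_)
  for (t in seq_len(T_)) {
    Ct <- matrix(params$couplings[, , t], N, N)
    H <- params$fields[, t] + Ct %*% x_prev               # N x n_s
    x_t <- matrix(as.numeric(runif(N * n_s) < plogis(H)), N, n_s)
    lfwd <- x_t * H - softplus(H)                         # per neuron, chain
    Hrev <- params$fields[, t] + Ct %*% x_t
    lbwd <- x_prev * Hrev - softplus(Hrev)
    ratio <- colSums(lfwd) - colSums(lbwd)
    flow[t] <- mean(ratio)
    se[t] <- sd(ratio) / sqrt(n_s)
    fwd[t] <- -mean(colSums(lfwd))
    bwd[t] <- -mean(colSums(lbwd))
    per_neuron[, t] <- rowMeans(lfwd - lbwd)
    x_prev <- x_t
  }
  entropy_flow_series(seq_len(T_), flow, fwd, bwd, method = "sampling",
                      per_neuron = per_neuron, se = se)
}

#' Dynamic mean-field activation rates and input statistics
#'
#' Recursively propagates per-neuron activation rates `m_{i,t}` through the
#' Gaussian (central-limit) approximation of the summed synaptic input: at
#' each bin the input to neuron i is treated as Gaussian with mean
#' `g = theta_i + sum_j theta_ij m_j` and variance
#' `Delta = sum_j theta_ij^2 m_j (1 - m_j)`, and the rate is the Gaussian
#' expectation of the logistic link. Inputs are evaluated both against the
#' previous-bin rates (driving the forward dynamics) and the same-bin rates
#' (needed by the time-reversed term).
#'
#' @param params a [param_trajectory].
#' @param m0 initial rates, length N (or scalar). When fitted to data, the
#'   natural choice is each neuron's spiking probability averaged over all
#'   bins and trials (see [mean_rates]).
#' @param nodes Gauss-Hermite node count.
#' @return object of class `mean_field_state`: `m` (N x (T+1), column 1 =
#'   `m0`), and N x T matrices `g_prev`, `d_prev`, `g_curr`, `d_curr` of
#'   input means/variances against the previous-/same-bin rates.
#' @export
mean_field_rates <- function(params, m0 = 0.5, nodes = 100) {
  N <- nrow(params$fields); T_ <- ncol(params$fields)
  m0 <- rep_len(m0, N)
  stopifnot(all(m0 >= 0 & m0 <= 1))
  m <- matrix(0, N, T_ + 1)
  m[, 1] <- m0
  g1 <- d1 <- g2 <- d2 <- matrix(0, N, T_)
  for (t in seq_len(T_)) {
    Ct <- matrix(params$couplings[, , t], N, N)
    mp <- m[, t]
    g1[, t] <- params$fields[, t] + Ct %*% mp
    d1[, t] <- (Ct^2) %*% (mp * (1 - mp))
    m[, t + 1] <- gauss_expect(plogis, g1[, t], d1[, t], nodes)
    mc <- m[, t + 1]
    g2[, t] <- params$fields[, t] + Ct %*% mc
    d2[, t] <- (Ct^2) %*% (mc * (1 - mc))
  }
  structure(list(m = m, g_prev = g1, d_prev = d1, g_curr = g2, d_curr = d2,
                 nodes = nodes),
            class = "mean_field_state")
}

#' Per-neuron mean spiking probability
#'
#' Spiking probability of each neuron averaged over all bins and trials; the
#' standard initializer for the mean-field recursion on fitted data.
#'
#' @param spikes a [spike_tensor].
#' @return numeric vector of length N.
#' @export
mean_rates <- function(spikes) apply(spikes$data, 1, mean)

#' Mean-field estimator of the entropy-flow series
#'
#' Approximates the forward conditional entropy by the Gaussian expectation
#' of the Bernoulli entropy of the logistic rate, and the time-reversed
#' conditional entropy by the Gaussian expectation of
#' `phi_{i,t}(h) = -(m_{i,t-1} h - psi(h))` against same-bin input
#' statistics. The flow is `-forward + backward` per bin, and per-neuron
#' contributions are returned.
#'
#' @param params a [param_trajectory].
#' @param mf a `mean_field_state` from [mean_field_rates]; by default
#'   computed with `m0`.
#' @param m0 initial rates if `mf` is not supplied.
#' @param nodes Gauss-Hermite node count.
#' @return an [entropy_flow_series] with method `"meanfield"` and per-neuron
#'   contributions.
#' @export
entropy_flow_meanfield <- function(params, mf = NULL, m0 = 0.5, nodes = 100) {
  if (is.null(mf)) mf <- mean_field_rates(params, m0, nodes)
  N <- nrow(params$fields); T_ <- ncol(params$fields)
  fwd_i <- bwd_i <- matrix(0, N, T_)
  chi <- function(H) { R <- plogis(H); -R * H + softplus(H) }
  for (t in seq_len(T_)) {
    fwd_i[, t] <- gauss_expect(chi, mf$g_prev[, t], mf$d_prev[, t], nodes)
    m_prev <- mf$m[, t]
    phi <- function(H) softplus(H) - m_prev * H   # rowwise m_{i,t-1}
    bwd_i[, t] <- gauss_expect(phi, mf$g_curr[, t], mf$d_curr[, t], nodes)
  }
  per_neuron <- -fwd_i + bwd_i
  entropy_flow_series(seq_len(T_), colSums(per_neuron), colSums(fwd_i),
                      colSums(bwd_i), method = "meanfield",
                      per_neuron = per_neuron)
}

#' Steady-state mean-field entropy flow
#'
#' For constant parameters, iterates the mean-field rate recursion to a fixed
#' point and evaluates the stationary entropy flow
#' `sum_i E_z[(r(g_i + z sqrt(Delta_i)) - m_i) * z sqrt(Delta_i)]`, the
#' covariance between each neuron's rate deviation and its input fluctuation.
#'
#' @param fields numeric vector of constant fields, length N.
#' @param couplings constant N x N coupling matrix.
#' @param m_init starting rates for the fixed-point iteration.
#' @param max_iter,tol fixed-point iteration cap and max-abs change
#'   tolerance.
#' @param nodes Gauss-Hermite node count.
#' @return list with `flow` (scalar, nats), `per_neuron`, and the fixed-point
#'   rates `m`.
#' @export
entropy_flow_steady <- function(fields, couplings, m_init = 0.5,
                                max_iter = 1000, tol = 1e-12, nodes = 100) {
  N <- length(fields)
  couplings <- as.matrix(couplings)
  stopifnot(all(dim(couplings) == N))
  m <- rep_len(m_init, N)
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    g <- fields + as.numeric(couplings %*% m)
    d <- as.numeric((couplings^2) %*% (m * (1 - m)))
    m_new <- gauss_expect(plogis, g, d, nodes)
    resid <- max(abs(m_new - m))
    m <- m_new
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("mean-field fixed point not reached within ", max_iter,
         " iterations; residual = ", format(resid))
  g <- fields + as.numeric(couplings %*% m)
  d <- as.numeric((couplings^2) %*% (m * (1 - m)))
  rule <- gauss_rule(nodes)
  sdv <- sqrt(pmax(d, 0))
  H <- outer(sdv, rule$z) + g
  dev <- plogis(H) - m
  per_neuron <- as.numeric((dev * outer(sdv, rule$z)) %*% rule$wt)
  list(flow = sum(per_neuron), per_neuron = per_neuron, m = m)
}
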