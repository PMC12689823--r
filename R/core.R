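#' Binary spike tensor
#'
#' Container for binarized population activity: a 3-axis 0/1 array indexed
#' `[neuron, bin, trial]`. Bin 0 (the first slice of the bin axis) holds the
#' initial pattern that the kinetic Ising dynamics are conditioned on; bins
#' 1..T carry the modeled transitions, so the bin axis has length `T + 1`.
#'
#' @param data integer/numeric array with `dim = c(N, T + 1, L)`, entries 0/1.
#' @param bin_width bin width in milliseconds (default 10, a common choice for
#'   cortical population data).
#' @param t0 time of the left edge of bin 0, in milliseconds.
#' @return an object of class `spike_tensor` with elements `data`,
#'   `bin_width`, `t0`.
#' @examples
#' x <- spike_tensor(array(rbinom(2 * 6 * 3, 1, 0.4), dim = c(2, 6, 3)))
#' dim(x$data)  # 2 neurons, 5 modeled bins (+ bin 0), 3 trials
#' @export
spike_tensor <- function(data, bin_width = 10, t0 = 0) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-axis array [neuron, bin, trial]")
  if (!all(data %in% c(0, 1)))
    stop("'data' must be binary (0/1)")
  if (dim(data)[2] < 2L)
    stop("need at least two bins (bin 0 plus one modeled bin)")
  storage.mode(data) <- "double"
  structure(list(data = data, bin_width = bin_width, t0 = t0),
            class = "spike_tensor")
}

#' @export
print.spike_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("spike_tensor: N = %d neurons, T = %d bins (+ bin 0), L = %d trials, Delta = %g ms\n",
              d[1], d[2] - 1L, d[3], x$bin_width))
  cat(sprintf("grand-mean rate: %.4f spikes/bin\n", mean(x$data)))
  invisible(x)
}

#' @export
dim.spike_tensor <- function(x) dim(x$data)

#' Time-varying natural parameters of a kinetic Ising model
#'
#' Fields `theta_{i,t}` and causal couplings `theta_{ij,t}` (influence of
#' neuron j's state at bin t-1 on neuron i at bin t; the diagonal holds
#' self-couplings), for t = 1..T. Units are nats per spike (fields) and nats
#' per spike pair (couplings).
#'
#' @param fields numeric matrix `N x T`.
#' @param couplings numeric array `N x N x T`; entry `[i, j, t]` is
#'   `theta_{ij,t}`.
#' @return an object of class `param_trajectory`.
#' @export
param_trajectory <- function(fields, couplings) {
  fields <- as.matrix(fields)
  N <- nrow(fields); T_ <- ncol(fields)
  if (length(dim(couplings)) != 3L || !all(dim(couplings) == c(N, N, T_)))
    stop("'couplings' must be an N x N x T array matching 'fields'")
  if (!all(is.finite(fields)) || !all(is.finite(couplings)))
    stop("parameters must be finite")
  structure(list(fields = fields, couplings = couplings),
            class = "param_trajectory")
}

#' @export
print.param_trajectory <- function(x, ...) {
  cat(sprintf("param_trajectory: N = %d, T = %d\n", nrow(x$fields), ncol(x$fields)))
  cat(sprintf("field range [%.3f, %.3f]; coupling range [%.3f, %.3f]\n",
              min(x$fields), max(x$fields), min(x$couplings), max(x$couplings)))
  invisible(x)
}

#' Per-neuron state-model hyperparameters
#'
#' Initial mean `mu` (length N+1, ordered `[field, coupling from j = 1..N]`),
#' initial covariance `sigma` ((N+1) x (N+1), symmetric positive definite) and
#' state-noise covariance `q` (symmetric positive semidefinite) of the
#' Gaussian random-walk state model governing one neuron's parameter vector.
#'
#' @param mu numeric vector, length N+1.
#' @param sigma,q square symmetric matrices, (N+1) x (N+1).
#' @param q_structure one of `"full"`, `"diagonal"`, `"scalar"` — the
#'   constraint imposed on `q` during hyperparameter optimization.
#' @return an object of class `neuron_hyperparams`.
#' @export
neuron_hyperparams <- function(mu, sigma, q,
                               q_structure = c("full", "diagonal", "scalar")) {
  q_structure <- match.arg(q_structure)
  d <- length(mu)
  sigma <- as.matrix(sigma); q <- as.matrix(q)
  if (!all(dim(sigma) == d) || !all(dim(q) == d))
    stop("'sigma' and 'q' must be square matrices conformable with 'mu'")
  if (max(abs(sigma - t(sigma))) > 1e-8 || max(abs(q - t(q))) > 1e-8)
    stop("'sigma' and 'q' must be symmetric")
  ev_s <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  ev_q <- eigen(q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_s) <= 0) stop("'sigma' must be positive definite")
  if (min(ev_q) < -1e-10 * max(abs(ev_q), 1)) stop("'q' must be positive semidefinite")
  if (q_structure == "diagonal" && max(abs(q - diag(diag(q), d))) > 0)
    stop("q_structure 'diagonal' requires exactly-zero off-diagonals in 'q'")
  if (q_structure == "scalar" && max(abs(q - q[1, 1] * diag(d))) > 0)
    stop("q_structure 'scalar' requires q = lambda * identity")
  structure(list(mu = as.numeric(mu), sigma = sigma, q = q,
                 q_structure = q_structure),
            class = "neuron_hyperparams")
}

# -- elementary links ---------------------------------------------------------

#' Logistic link, log-partition and Bernoulli entropy
#'
#' For a scalar (or vector) input field h, returns the spiking rate
#' `r(h) = 1/(1 + exp(-h))`, the log-partition `psi(h) = log(1 + exp(h))`
#' (computed in a numerically stable branch for large |h|), and the entropy of
#' a 0/1 variable with mean r(h), `chi(h) = -r(h) h + psi(h)`. All in nats.
#'
#' @param h numeric vector of input fields; must be finite.
#' @return list with elements `rate`, `log_partition`, `bern_entropy`, each
#'   the same length as `h`.
#' @examples
#' scalar_links(0)       # rate 0.5, both entropies log(2)
#' scalar_links(log(3))  # rate 0.75
#' @export
scalar_links <- function(h) {
  if (!all(is.finite(h))) stop("'h' must be finite")
  rate <- plogis(h)
  lp <- softplus(h)
  list(rate = rate, log_partition = lp, bern_entropy = -rate * h + lp)
}

# stable log(1 + exp(h)); branch keeps exp() off the overflow path
softplus <- function(h) {
  out <- h
  lo <- h <= 30
  out[lo] <- log1p(exp(h[lo]))
  hi <- !lo
  out[hi] <- h[hi] + log1p(exp(-h[hi]))
  out
}

#' Conditional input field given the previous population state
#'
#' `h_i = theta_{i,t} + sum_j theta_{ij,t} x_prev_j` for every neuron i.
#'
#' @param params a [param_trajectory].
#' @param t bin index in 1..T.
#' @param x_prev binary vector (length N) or binary matrix (N x L, one column
#'   per trial) of states at bin t-1.
#' @return numeric vector of length N, or N x L matrix if `x_prev` is one.
#' @export
conditional_field <- function(params, t, x_prev) {
  N <- nrow(params$fields)
  if (is.matrix(x_prev)) {
    if (nrow(x_prev) != N) stop("'x_prev' has wrong number of neurons")
    params$fields[, t] + matrix(params$couplings[, , t], N, N) %*% x_prev
  } else {
    if (length(x_prev) != N) stop("'x_prev' has wrong length")
    if (!all(x_prev %in% c(0, 1))) stop("'x_prev' must be binary")
    as.numeric(params$fields[, t] +
                 matrix(params$couplings[, , t], N, N) %*% x_prev)
  }
}

#' Transition probability of the kinetic Ising observation model
#'
#' Probability of the population state `x_curr` at bin t given `x_prev` at
#' bin t-1, `prod_i exp(x_curr_i h_i - psi(h_i))`. Neurons are conditionally
#' independent given the previous pattern.
#'
#' @inheritParams conditional_field
#' @param x_curr binary vector of length N.
#' @param log return the log-probability instead.
#' @return scalar (log-)probability.
#' @export
transition_probability <- function(params, t, x_prev, x_curr, log = FALSE) {
  if (length(x_curr) != nrow(params$fields)) stop("'x_curr' has wrong length")
  if (!all(x_curr %in% c(0, 1))) stop("'x_curr' must be binary")
  h <- conditional_field(params, t, x_prev)
  lp <- sum(x_curr * h - softplus(h))
  if (log) lp else exp(lp)
}

# all 2^N binary patterns as a (2^N x N) matrix; row order is the canonical
# binary encoding (pattern k has bit j of k-1 in column j)
enumerate_states <- function(N) {
  if (N > 20) stop("state enumeration limited to N <= 20")
  k <- 0:(2^N - 1)
  vapply(seq_len(N), function(j) as.numeric(bitwAnd(k, 2^(j - 1)) > 0),
         numeric(length(k)))
}

# log transition matrix [prev, curr] over all 2^N states at bin t
log_transition_matrix <- function(params, t) {
  N <- nrow(params$fields)
  S <- enumerate_states(N)
  # H[p, i] = h_i(x_prev = S[p, ])
  H <- matrix(params$fields[, t], nrow(S), N, byrow = TRUE) +
    S %*% t(matrix(params$couplings[, , t], N, N))
  H %*% t(S) - rowSums(softplus(H))
}

#' Per-bin entropy flow series
#'
#' Time series of entropy flow with its forward/backward conditional-entropy
#' decomposition, `flow = -forward + backward` at every bin (in nats).
#'
#' @param t integer vector of bin indices.
#' @param flow,forward,backward numeric vectors over bins.
#' @param method one of `"exact"`, `"sampling"`, `"meanfield"`, `"steady"`.
#' @param per_neuron optional N x T matrix of per-neuron contributions that
#'   sum to `flow` columnwise.
#' @param se optional Monte-Carlo standard error per bin.
#' @param production,entropy optional exact entropy production and system
#'   entropy (available from the enumeration estimator only).
#' @return object of class `entropy_flow_series`.
#' @export
entropy_flow_series <- function(t, flow, forward, backward, method,
                                per_neuron = NULL, se = NULL,
                                production = NULL, entropy = NULL) {
  stopifnot(length(flow) == length(t), length(forward) == length(t),
            length(backward) == length(t))
  if (max(abs(flow - (-forward + backward))) > 1e-8 * max(1, max(abs(flow))))
    stop("flow must equal -forward + backward")
  if (!is.null(per_neuron)) {
    stopifnot(ncol(per_neuron) == length(t))
    if (max(abs(colSums(per_neuron) - flow)) > 1e-8 * max(1, max(abs(flow))))
      stop("per-neuron contributions must sum to flow")
  }
  structure(list(t = t, flow = flow, forward = forward, backward = backward,
                 per_neuron = per_neuron, se = se, production = production,
                 entropy = entropy,
                 method = match.arg(method,
                                    c("exact", "sampling", "meanfield", "steady"))),
            class = "entropy_flow_series")
}

#' @export
print.entropy_flow_series <- function(x, ...) {
  cat(sprintf("entropy_flow_series (%s): T = %d bins, total flow = %.4f nats\n",
              x$method, length(x$t), sum(x$flow)))
  invisible(x)
}
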