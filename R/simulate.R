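#' Gaussian-process configuration for parameter trajectories
#'
#' Squared-exponential kernel `k(t, s) = amplitude * exp(-(t-s)^2 /
#' (2 length_scale^2))` with a constant mean. Used to draw smooth
#' time-varying fields and couplings for simulation studies.
#'
#' @param mean GP mean (nats).
#' @param amplitude kernel variance k0 (> 0).
#' @param length_scale kernel length scale tau, in bins (> 0).
#' @param jitter value added to the kernel diagonal before Cholesky; escalated
#'   automatically (x10 up to 1e-4 * amplitude) if factorization fails.
#' @return object of class `gp_config`.
#' @export
gp_config <- function(mean = 0, amplitude = 1, length_scale = 10,
                      jitter = 1e-10 * amplitude) {
  stopifnot(amplitude > 0, length_scale > 0, jitter >= 0)
  structure(list(mean = mean, amplitude = amplitude,
                 length_scale = length_scale, jitter = jitter),
            class = "gp_config")
}

#' Standard simulation settings for fields and couplings
#'
#' The conventions used throughout the simulation studies: couplings drawn
#' with mean 5/N, variance 10/N and length scale 30/sqrt(N) (the
#' Sherrington-Kirkpatrick scaling), fields with mean -3, variance 1 and
#' length scale 50. The negative field mean produces the sparse firing
#' regime typical of cortical data.
#'
#' @param N number of neurons.
#' @return list with elements `field` and `coupling`, each a [gp_config].
#' @export
default_gp_configs <- function(N) {
  list(field = gp_config(mean = -3, amplitude = 1, length_scale = 50),
       coupling = gp_config(mean = 5 / N, amplitude = 10 / N,
                            length_scale = 30 / sqrt(N)))
}

# deterministic child seed from (seed, stream label, indices); keeps all
# derived seeds below 2^31 and distinct across streams in practice
child_seed <- function(seed, label, i = 0L, j = 0L) {
  lab <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 48271 + lab * 95279 + i * 1299721 + j * 7919) %% 2147483629
}

#' Draw one Gaussian-process trajectory
#'
#' @param T_ series length (bins).
#' @param cfg a [gp_config].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return numeric vector of length `T_`.
#' @export
sample_gp_trajectory <- function(T_, cfg, seed) {
  stopifnot(T_ >= 1)
  L <- gp_chol(T_, cfg)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  z <- rnorm(T_)
  as.numeric(cfg$mean + crossprod(L, z))
}

# upper Cholesky factor of the SE kernel, with jitter escalation
gp_chol <- function(T_, cfg) {
  d2 <- outer(seq_len(T_), seq_len(T_), function(a, b) (a - b)^2)
  K <- cfg$amplitude * exp(-d2 / (2 * cfg$length_scale^2))
  jit <- max(cfg$jitter, 1e-10 * cfg$amplitude)
  repeat {
    R <- tryCatch(chol(K + jit * diag(T_)), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- jit * 10
    if (jit > 1e-4 * cfg$amplitude * 10)
      stop("GP kernel not positive definite even after jitter escalation (jitter = ",
           jit, ")")
  }
}

#' Sample ground-truth field and coupling trajectories
#'
#' Draws N independent field series and N^2 independent coupling series from
#' Gaussian processes. Each series has its own random stream keyed by
#' `(seed, series identity)`, so the draw for a smaller population is exactly
#' the leading sub-block of the draw for a larger one with the same seed and
#' configurations — nested subsetting across system sizes.
#'
#' @param N population size.
#' @param T_ number of modeled bins.
#' @param field_cfg,coupling_cfg [gp_config] objects (see
#'   [default_gp_configs]).
#' @param seed integer seed.
#' @return a [param_trajectory].
#' @export
sample_param_trajectories <- function(N, T_, field_cfg, coupling_cfg, seed) {
  stopifnot(N >= 1)
  fields <- matrix(0, N, T_)
  couplings <- array(0, dim = c(N, N, T_))
  Lf <- gp_chol(T_, field_cfg)
  Lc <- gp_chol(T_, coupling_cfg)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (i in seq_len(N)) {
    set.seed(child_seed(seed, "field", i))
    fields[i, ] <- field_cfg$mean + as.numeric(crossprod(Lf, rnorm(T_)))
    for (j in seq_len(N)) {
      set.seed(child_seed(seed, "coupling", i, j))
      couplings[i, j, ] <- coupling_cfg$mean + as.numeric(crossprod(Lc, rnorm(T_)))
    }
  }
  param_trajectory(fields, couplings)
}

#' Simulate binary population activity from a kinetic Ising model
#'
#' Bin 0 is i.i.d. Bernoulli(`p0`) for every neuron and trial; bins 1..T are
#' drawn from the kinetic Ising transition law given the previous bin,
#' independently across trials.
#'
#' @param params a [param_trajectory].
#' @param L number of trials.
#' @param seed integer seed.
#' @param p0 initial spiking probability (default 0.5).
#' @param bin_width,t0 passed to [spike_tensor].
#' @return a [spike_tensor] with `dim = c(N, T + 1, L)`.
#' @export
simulate_spikes <- function(params, L, seed, p0 = 0.5, bin_width = 10, t0 = 0) {
  stopifnot(L >= 1)
  N <- nrow(params$fields); T_ <- ncol(params$fields)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(child_seed(seed, "spikes"))
  x <- array(0, dim = c(N, T_ + 1L, L))
  x[, 1, ] <- rbinom(N * L, 1, p0)
  for (t in seq_len(T_)) {
    h <- conditional_field(params, t, matrix(x[, t, ], N, L))
    x[, t + 1L, ] <- as.numeric(runif(N * L) < plogis(h))
  }
  spike_tensor(x, bin_width = bin_width, t0 = t0)
}

#' Trial-shuffle surrogate
#'
#' Applies an independent uniform random permutation of trial indices to each
#' neuron's (T+1) x L slab. This preserves every neuron's within-trial
#' temporal structure (hence self-coupling structure) and its trial-averaged
#' rate at every bin bit-exactly, while destroying same-trial cross-neuron
#' alignment — isolating the contribution of cross-neuron couplings.
#'
#' @param spikes a [spike_tensor].
#' @param seed integer seed.
#' @return a shuffled [spike_tensor].
#' @export
trial_shuffle <- function(spikes, seed) {
  d <- dim(spikes$data)
  out <- spikes$data
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (i in seq_len(d[1])) {
    set.seed(child_seed(seed, "shuffle", i))
    out[i, , ] <- out[i, , sample.int(d[3]), drop = FALSE]
  }
  spike_tensor(out, bin_width = spikes$bin_width, t0 = spikes$t0)
}
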