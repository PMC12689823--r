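#' Alternating-shrinking higher-order interaction model configuration
#'
#' A homogeneous exponential-family model of binary population patterns with
#' interactions of all orders: alternating-sign terms with geometrically
#' shrinking weights `C_j = shrink^j`, an entropy-canceling base measure
#' `1 / choose(N, n)`, and a sparsity parameter `f`. It produces
#' population spike-count distributions that are sparse (mode at 0) yet
#' widespread (heavy upper tail), and its single-unit conditional log-odds
#' is supra-linear in the count of active peers — both features a pairwise
#' logistic model cannot reproduce.
#'
#' @param n_units population size N.
#' @param sparsity sparsity parameter f (>= 0).
#' @param shrink geometric shrink factor in (0, 1).
#' @param sweeps total Gibbs sweeps.
#' @param burn_in sweeps discarded before retention (default 10% of sweeps).
#' @param seed integer seed.
#' @return object of class `hoi_config`.
#' @export
hoi_config <- function(n_units = 30, sparsity = 20, shrink = 0.8,
                       sweeps = 10000, burn_in = ceiling(sweeps / 10),
                       seed = 1) {
  stopifnot(n_units >= 1, sparsity >= 0, shrink > 0, shrink < 1,
            sweeps > burn_in, burn_in >= 0)
  structure(list(n_units = n_units, sparsity = sparsity, shrink = shrink,
                 sweeps = sweeps, burn_in = burn_in, seed = seed),
            class = "hoi_config")
}

# Q(n) = sum_j (-1)^(j+1) shrink^j (n/N)^j, the alternating geometric series
hoi_Q <- function(n, N, shrink) {
  j <- seq_len(N)
  vapply(n, function(nn) -sum((-shrink * nn / N)^j), numeric(1))
}

#' Exact population spike-count distribution of the HOI model
#'
#' The binomial pattern multiplicity cancels the base measure exactly, so
#' `P(n)` is proportional to `exp(-f * Q(n))` over n = 0..N; computed in the
#' log domain and normalized.
#'
#' @param cfg an [hoi_config].
#' @return numeric probability vector of length N+1 (counts 0..N).
#' @export
hoi_count_pmf <- function(cfg) {
  lp <- -cfg$sparsity * hoi_Q(0:cfg$n_units, cfg$n_units, cfg$shrink)
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Single-unit conditional log-odds of the HOI model
#'
#' `log(p1/p0) = log((n_active + 1)/(N - n_active)) - f * dQ(n_active)` where
#' `n_active` is the spike count of the other units; this is the model's
#' effective activation function, supra-linear in `n_active`.
#'
#' @param n_active integer vector of peer spike counts, in 0..N-1.
#' @param cfg an [hoi_config].
#' @return numeric vector of log-odds.
#' @export
hoi_log_odds <- function(n_active, cfg) {
  N <- cfg$n_units
  stopifnot(all(n_active >= 0), all(n_active <= N - 1))
  Q <- hoi_Q(0:N, N, cfg$shrink)
  dQ <- Q[n_active + 2] - Q[n_active + 1]
  log((n_active + 1) / (N - n_active)) - cfg$sparsity * dQ
}

#' Gibbs sampler for the HOI model
#'
#' One sweep visits all units in a fresh uniformly random permutation and
#' updates each from its conditional given the others. Burn-in sweeps are
#' discarded; retained sweeps are reorganized into a [spike_tensor] with
#' consecutive sweeps becoming consecutive bins, so each trial of `T + 1`
#' bins is a contiguous chain segment (dependencies across consecutive bins
#' are preserved; trial boundaries break the chain).
#'
#' @param cfg an [hoi_config]. `sweeps - burn_in` must be at least
#'   `(T + 1) * L`.
#' @param T_ number of modeled bins per trial.
#' @param L number of trials; default uses all retained sweeps.
#' @return a [spike_tensor].
#' @export
hoi_gibbs <- function(cfg, T_ = 200,
                      L = (cfg$sweeps - cfg$burn_in) %/% (T_ + 1)) {
  N <- cfg$n_units
  retained <- (T_ + 1) * L
  if (cfg$sweeps - cfg$burn_in < retained)
    stop("not enough retained sweeps for the requested T and L")
  # conditional spike probability indexed by peer count 0..N-1
  p_on <- plogis(hoi_log_odds(0:(N - 1), cfg))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(child_seed(cfg$seed, "hoi"))
  x <- rep(0, N)
  n_tot <- 0
  keep <- matrix(0, N, retained)
  total <- cfg$burn_in + retained
  for (s in seq_len(total)) {
    ord <- sample.int(N)
    u <- runif(N)
    for (k in seq_len(N)) {
      i <- ord[k]
      n_peer <- n_tot - x[i]
      xi_new <- as.numeric(u[k] < p_on[n_peer + 1])
      n_tot <- n_tot + xi_new - x[i]
      x[i] <- xi_new
    }
    if (s > cfg$burn_in) keep[, s - cfg$burn_in] <- x
  }
  spike_tensor(array(keep, dim = c(N, T_ + 1, L)))
}

# constant-parameter kinetic Ising summary of a stationary fit: bin-averaged
# smoothed fields and couplings
stationary_params <- function(posterior) {
  p <- smoothed_params(posterior)
  list(fields = rowMeans(p$fields),
       couplings = apply(p$couplings, c(1, 2), mean))
}

# simulate a tensor from constant kinetic Ising parameters
simulate_constant <- function(fields, couplings, T_, L, seed, p0 = 0.5) {
  N <- length(fields)
  params <- param_trajectory(matrix(fields, N, T_),
                             array(couplings, dim = c(N, N, T_)))
  simulate_spikes(params, L = L, seed = seed, p0 = p0)
}

# population spike-count histogram over all modeled bins and trials
count_histogram <- function(spikes) {
  N <- dim(spikes$data)[1]
  counts <- apply(spikes$data[, -1, , drop = FALSE], c(2, 3), sum)
  tabulate(counts + 1, nbins = N + 1) / length(counts)
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

#' Kinetic-Ising misspecification experiment against the HOI model
#'
#' Generates stationary HOI population activity by Gibbs sampling, fits the
#' kinetic Ising model with the state noise frozen at zero (stationary
#' mode, no hyperparameter optimization), resamples spike sequences from the
#' fitted constant-parameter model, and compares the population spike-count
#' histograms and the two activation functions (supra-linear HOI log-odds
#' vs. the fitted model's affine log-odds built from the averages of the
#' fitted fields and couplings). A matched control in which the source data
#' are themselves generated by a constant-parameter kinetic Ising model
#' quantifies the self-consistency floor of the histogram comparison.
#'
#' @param cfg an [hoi_config].
#' @param T_,L shape into which the Gibbs chain is reorganized.
#' @param resample_L number of resampled sequences (trials) drawn from the
#'   fitted model.
#' @param fit_cfg a [fit_config]; the state noise is frozen regardless.
#' @param control also run the kinetic-Ising-source control (default TRUE).
#' @return list with `hist_source`, `hist_refit`, `tv` (source vs refit),
#'   `tv_control` (control source vs its refit; NA if `control = FALSE`),
#'   `activation` (data frame: peer count, HOI log-odds, fitted log-odds),
#'   and the fitted constant `fields`/`couplings`.
#' @export
misspecification_experiment <- function(cfg, T_ = 100, L = NULL,
                                        resample_L = NULL,
                                        fit_cfg = fit_config(),
                                        control = TRUE) {
  if (is.null(L)) L <- (cfg$sweeps - cfg$burn_in) %/% (T_ + 1)
  if (is.null(resample_L)) resample_L <- L
  fit_cfg$freeze_q <- TRUE
  spk <- hoi_gibbs(cfg, T_ = T_, L = L)
  fit <- fit_em(spk, fit_cfg)
  sp <- stationary_params(fit$posterior)
  resim <- simulate_constant(sp$fields, sp$couplings, T_ = T_, L = resample_L,
                             seed = child_seed(cfg$seed, "resample"),
                             p0 = mean(spk$data))
  hist_source <- count_histogram(spk)
  hist_refit <- count_histogram(resim)
  tv <- tv_distance(hist_source, hist_refit)
  tv_control <- NA_real_
  if (control) {
    ctrl_src <- simulate_constant(sp$fields, sp$couplings, T_ = T_, L = L,
                                  seed = child_seed(cfg$seed, "ctrlsrc"),
                                  p0 = mean(spk$data))
    ctrl_fit <- fit_em(ctrl_src, fit_cfg)
    csp <- stationary_params(ctrl_fit$posterior)
    ctrl_resim <- simulate_constant(csp$fields, csp$couplings, T_ = T_,
                                    L = resample_L,
                                    seed = child_seed(cfg$seed, "ctrlres"),
                                    p0 = mean(ctrl_src$data))
    tv_control <- tv_distance(count_histogram(ctrl_src),
                              count_histogram(ctrl_resim))
  }
  n_active <- 0:(cfg$n_units - 1)
  N <- cfg$n_units
  offdiag <- sp$couplings[row(sp$couplings) != col(sp$couplings)]
  fitted_lo <- mean(sp$fields) + mean(offdiag) * n_active
  list(hist_source = hist_source, hist_refit = hist_refit,
       tv = tv, tv_control = tv_control,
       activation = data.frame(n_active = n_active,
                               hoi = hoi_log_odds(n_active, cfg),
                               fitted = fitted_lo),
       fields = sp$fields, couplings = sp$couplings)
}
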