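#' Coefficient of variation of a rate distribution
#'
#' Sparsity index of a nonnegative firing-rate distribution: standard
#' deviation divided by mean. Population convention (divisor n) by default.
#'
#' @param rates nonnegative numeric vector with positive mean.
#' @param population use the population standard deviation (default TRUE);
#'   `FALSE` for the sample (n-1) convention.
#' @return scalar CV.
#' @export
sparsity_cv <- function(rates, population = TRUE) {
  if (any(rates < 0)) stop("'rates' must be nonnegative")
  m <- mean(rates)
  if (m <= 0) stop("CV undefined: mean rate is zero")
  n <- length(rates)
  s2 <- sum((rates - m)^2) / if (population) n else n - 1
  sqrt(s2) / m
}

#' Skewness of firing-rate differences
#'
#' Standardized third central moment of per-neuron rate differences between
#' two conditions; used as a sparsification index. A uniform rate change
#' across neurons gives zero; negative skew indicates that a subset of
#' neurons carries the reduction. Population convention by default.
#'
#' @param rate_diff numeric vector (length >= 3, nonzero variance).
#' @param population population (n) vs sample-adjusted moment convention.
#' @return scalar skewness.
#' @export
sparsification_skewness <- function(rate_diff, population = TRUE) {
  n <- length(rate_diff)
  if (n < 3) stop("need at least 3 values")
  m <- mean(rate_diff)
  s2 <- sum((rate_diff - m)^2) / n
  if (s2 <= 0) stop("skewness undefined: zero variance")
  g1 <- mean((rate_diff - m)^3) / s2^1.5
  if (population) g1 else g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Coupling asymmetry
#'
#' Mean over unordered neuron pairs i < j of the absolute difference of
#' reciprocal time-averaged couplings `|theta_ij - theta_ji|`; self-pairs
#' excluded. Zero for a symmetric coupling matrix.
#'
#' @param couplings_time_avg N x N matrix of time-averaged couplings (see
#'   [time_average_couplings]).
#' @return scalar asymmetry.
#' @export
coupling_asymmetry <- function(couplings_time_avg) {
  M <- as.matrix(couplings_time_avg)
  N <- nrow(M)
  if (N < 2 || ncol(M) != N) stop("need a square matrix with N >= 2")
  D <- abs(M - t(M))
  mean(D[upper.tri(D)])
}

#' Time-averaged coupling matrix
#'
#' @param params a [param_trajectory].
#' @param bins optional bin subset to average over.
#' @return N x N matrix.
#' @export
time_average_couplings <- function(params, bins = NULL) {
  C <- params$couplings
  if (!is.null(bins)) C <- C[, , bins, drop = FALSE]
  apply(C, c(1, 2), mean)
}

#' Screen couplings by credible-interval exclusion of zero
#'
#' A coupling (i, j) is retained if its level-credible interval (smoothed
#' mean +/- z * posterior sd) excludes zero for at least one bin within the
#' analysis window. Self-couplings are excluded from the mask by default,
#' matching the usual display rule. Note the union over bins makes the
#' screen anti-conservative relative to the per-bin level.
#'
#' @param posterior a `kinetic_posterior`.
#' @param window integer vector of bin indices to screen.
#' @param level credible level (default 0.95).
#' @param include_self include the diagonal (default FALSE).
#' @return logical N x N mask.
#' @export
significant_couplings <- function(posterior, window = seq_len(posterior$T),
                                  level = 0.95, include_self = FALSE) {
  if (any(window < 1) || any(window > posterior$T))
    stop("'window' outside the fitted bin range")
  N <- posterior$N
  z <- qnorm(1 - (1 - level) / 2)
  mask <- matrix(FALSE, N, N)
  for (i in seq_len(N)) {
    nn <- posterior$neurons[[i]]
    for (j in seq_len(N)) {
      mu <- nn$smooth_mean[j + 1, window]
      sd_ <- sqrt(pmax(nn$smooth_cov[j + 1, j + 1, window], 0))
      mask[i, j] <- any(abs(mu) - z * sd_ > 0)
    }
  }
  if (!include_self) diag(mask) <- FALSE
  mask
}

#' Entropy-flow surface under parameter rescaling
#'
#' Multiplies all fields and couplings by each gain `beta` and recomputes
#' the mean-field entropy flow, giving a `beta x bin` surface of the flow
#' and of its forward/backward parts. Probes how close the fitted system
#' sits to the gain that maximizes dissipation: a peak at beta < 1 indicates
#' a subcritical operating point. Optionally subtracts the surface of a
#' second (e.g. trial-shuffled-fit) parameter set, and a range-averaged
#' summary over a beta interval is available via [scan_summary].
#'
#' @param params a [param_trajectory].
#' @param betas nonnegative gain vector.
#' @param m0 initial rates for the mean-field recursion (held fixed across
#'   betas).
#' @param shuffled_params optional second [param_trajectory] whose surface is
#'   subtracted.
#' @param nodes Gauss-Hermite node count.
#' @return object of class `rescale_scan`: matrices `flow`, `forward`,
#'   `backward` (`length(betas) x T`), the `betas`, and (when supplied) the
#'   shuffled-fit surface `flow_shuffled` plus `flow_subtracted`.
#' @export
rescale_entropy_scan <- function(params, betas, m0 = 0.5,
                                 shuffled_params = NULL, nodes = 100) {
  stopifnot(all(is.finite(betas)), all(betas >= 0))
  surf <- function(p) {
    rows <- lapply(betas, function(b) {
      pb <- param_trajectory(b * p$fields, b * p$couplings)
      ef <- entropy_flow_meanfield(pb, m0 = m0, nodes = nodes)
      list(ef$flow, ef$forward, ef$backward)
    })
    list(flow = do.call(rbind, lapply(rows, `[[`, 1)),
         forward = do.call(rbind, lapply(rows, `[[`, 2)),
         backward = do.call(rbind, lapply(rows, `[[`, 3)))
  }
  s <- surf(params)
  out <- list(betas = betas, flow = s$flow, forward = s$forward,
              backward = s$backward)
  if (!is.null(shuffled_params)) {
    ss <- surf(shuffled_params)
    out$flow_shuffled <- ss$flow
    out$flow_subtracted <- s$flow - ss$flow
  }
  structure(out, class = "rescale_scan")
}

#' Range-averaged summary of a rescaling scan
#'
#' Mean of a scan surface over a beta interval and all bins — the scalar
#' used to compare conditions over the low-gain range.
#'
#' @param scan a `rescale_scan`.
#' @param beta_range inclusive interval of betas to average (default
#'   c(0.2, 1.0)).
#' @param what surface to average: `"flow_subtracted"` (default, if present)
#'   or `"flow"`.
#' @return scalar mean.
#' @export
scan_summary <- function(scan, beta_range = c(0.2, 1.0),
                         what = if (!is.null(scan$flow_subtracted))
                           "flow_subtracted" else "flow") {
  sel <- scan$betas >= beta_range[1] & scan$betas <= beta_range[2]
  if (!any(sel)) stop("no betas inside 'beta_range'")
  mean(scan[[what]][sel, , drop = FALSE])
}

#' Shuffle subtraction and normalizations of an entropy-flow series
#'
#' @param flow an [entropy_flow_series] from the original data/fit.
#' @param flow_shuffled an [entropy_flow_series] from the trial-shuffled
#'   data/fit, same length.
#' @param rates per-neuron mean activity rates (spikes/bin); needed for the
#'   per-spike normalization when per-neuron contributions are present.
#' @param per_spike_mode `"per_neuron"` (default): mean over neurons of
#'   (neuron flow contribution)/(neuron rate); `"population"`: total flow
#'   divided by total rate.
#' @return list with `subtracted` (per-bin series), `total` (summed original
#'   flow), `total_subtracted`, and `per_spike` (NA when the inputs lack
#'   per-neuron contributions and the per-neuron mode is requested).
#' @export
flow_normalizations <- function(flow, flow_shuffled, rates = NULL,
                                per_spike_mode = c("per_neuron", "population")) {
  per_spike_mode <- match.arg(per_spike_mode)
  if (length(flow$flow) != length(flow_shuffled$flow))
    stop("series lengths differ")
  subtracted <- flow$flow - flow_shuffled$flow
  per_spike <- NA_real_
  if (!is.null(rates)) {
    if (per_spike_mode == "per_neuron") {
      if (!is.null(flow$per_neuron))
        per_spike <- mean(rowSums(flow$per_neuron) / (rates * length(flow$flow)))
    } else {
      per_spike <- sum(flow$flow) / (sum(rates) * length(flow$flow))
    }
  }
  list(subtracted = subtracted, total = sum(flow$flow),
       total_subtracted = sum(subtracted), per_spike = per_spike)
}

#' Behavioral sensitivity index d-prime
#'
#' Difference of the z-transformed hit and false-alarm rates. Rates are
#' clamped to `[1/(2n), 1 - 1/(2n)]` before the probit transform to keep the
#' index finite at perfect performance, with `n` the trial count behind each
#' rate.
#'
#' @param hit_rate,fa_rate probabilities in [0, 1].
#' @param n trial count used for the clamp (default 100).
#' @return scalar d-prime.
#' @export
dprime <- function(hit_rate, fa_rate, n = 100) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  clamp <- function(p) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  qnorm(clamp(hit_rate)) - qnorm(clamp(fa_rate))
}
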