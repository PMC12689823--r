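#' Fitting configuration
#'
#' Controls for the EM driver and its inner Newton-Raphson MAP searches.
#'
#' @param max_em_iter maximum EM iterations (default 200).
#' @param em_rel_tol relative tolerance on the approximate marginal
#'   log-likelihood for EM convergence (default 1e-6).
#' @param newton_max_iter,newton_grad_tol Newton-Raphson cap and max-abs
#'   gradient tolerance for the per-bin MAP searches.
#' @param q_structure constraint on the state-noise covariance update:
#'   `"full"`, `"diagonal"` (diagonal of the full update) or `"scalar"`
#'   (trace/(N+1) times identity).
#' @param init_q_scale initial state-noise covariance is
#'   `init_q_scale * identity` (default 1e-3).
#' @param optimize_initial update the initial mean/covariance hyperparameters
#'   in the M-step (`mu^i <- theta_{1|T}^i`, making the initial-covariance
#'   update collapse to `Sigma^i <- W_{1|T}^i`); set `FALSE` to hold them at
#'   their initial values.
#' @param freeze_q hold the state-noise covariance at exactly zero and skip
#'   hyperparameter optimization (stationary mode: parameters are constant
#'   across bins in the posterior limit).
#' @return object of class `fit_config`.
#' @export
fit_config <- function(max_em_iter = 200, em_rel_tol = 1e-6,
                       newton_max_iter = 100, newton_grad_tol = 1e-8,
                       q_structure = c("full", "diagonal", "scalar"),
                       init_q_scale = 1e-3, optimize_initial = TRUE,
                       freeze_q = FALSE) {
  stopifnot(max_em_iter >= 1, em_rel_tol > 0, newton_max_iter >= 1,
            newton_grad_tol > 0, init_q_scale >= 0)
  structure(list(max_em_iter = max_em_iter, em_rel_tol = em_rel_tol,
                 newton_max_iter = newton_max_iter,
                 newton_grad_tol = newton_grad_tol,
                 q_structure = match.arg(q_structure),
                 init_q_scale = init_q_scale,
                 optimize_initial = optimize_initial, freeze_q = freeze_q),
            class = "fit_config")
}

sym <- function(M) (M + t(M)) / 2

chol_solve <- function(M, b) {
  R <- chol(sym(M))
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

chol_inv <- function(M) chol2inv(chol(sym(M)))

logdet_pd <- function(M) 2 * sum(log(diag(chol(sym(M)))))

#' One-step prediction of the state density
#'
#' Under the Gaussian random-walk state model the predicted mean equals the
#' filtered mean and the predicted covariance is the filtered covariance plus
#' the state-noise covariance.
#'
#' @param filt_mean,filt_cov filtered moments at bin t-1.
#' @param q state-noise covariance.
#' @return list with `pred_mean`, `pred_cov` (symmetrized).
#' @export
predict_step <- function(filt_mean, filt_cov, q) {
  list(pred_mean = filt_mean, pred_cov = sym(filt_cov + q))
}

# grouped sufficient statistics of one bin transition: unique previous-state
# patterns, their trial counts, and per-neuron spike successes per pattern
bin_sufficient_stats <- function(x_prev, x_t) {
  N <- nrow(x_prev)
  key <- as.numeric(2^(seq_len(N) - 1) %*% x_prev)
  u <- !duplicated(key)
  grp <- match(key, key[u])
  list(design = cbind(1, t(x_prev[, u, drop = FALSE])),   # n_pat x (N+1)
       counts = tabulate(grp, nbins = sum(u)),
       succ = rowsum(t(x_t), grp))                        # n_pat x N
}

# Laplace filter update for one neuron at one bin, from grouped statistics.
# Returns the MAP mean, the inverse-Hessian covariance, the Laplace
# marginal-likelihood increment and the Newton iteration count.
filter_update <- function(pred_mean, pred_cov, design, counts, succ_i,
                          newton_max_iter = 100, newton_grad_tol = 1e-8) {
  Pinv <- chol_inv(pred_cov)
  obj <- function(th) {
    eta <- as.numeric(design %*% th)
    d <- th - pred_mean
    sum(succ_i * eta - counts * softplus(eta)) - 0.5 * sum(d * (Pinv %*% d))
  }
  th <- pred_mean
  f <- obj(th)
  iters <- 0L
  converged <- FALSE
  for (k in seq_len(newton_max_iter)) {
    eta <- as.numeric(design %*% th)
    r <- plogis(eta)
    g <- as.numeric(crossprod(design, succ_i - counts * r)) -
      as.numeric(Pinv %*% (th - pred_mean))
    if (max(abs(g)) < newton_grad_tol) { converged <- TRUE; break }
    w <- counts * r * (1 - r)
    H <- crossprod(design * w, design) + Pinv        # negative Hessian, PD
    step <- chol_solve(H, g)
    # Newton decrement: quadratic model of the remaining ascent; at roundoff
    # scale the line search cannot discriminate, so stop here
    if (sum(g * step) / 2 < 1e-12 * (abs(f) + 1)) { converged <- TRUE; break }
    lam <- 1
    for (h in seq_len(30)) {
      f_new <- obj(th + lam * step)
      if (f_new >= f - 1e-10 * (abs(f) + 1)) break
      lam <- lam / 2
    }
    th <- th + lam * step
    f <- f_new
    iters <- k
  }
  if (!converged)
    warning("Newton-Raphson did not reach gradient tolerance; using best iterate")
  eta <- as.numeric(design %*% th)
  r <- plogis(eta)
  G <- crossprod(design * (counts * r * (1 - r)), design)  # Fisher information
  W <- sym(chol_inv(G + Pinv))
  d <- th - pred_mean
  qval <- sum(succ_i * eta - counts * softplus(eta)) - 0.5 * sum(d * (Pinv %*% d))
  ll_inc <- qval + 0.5 * logdet_pd(W) - 0.5 * logdet_pd(pred_cov)
  list(filt_mean = th, filt_cov = W, ll_inc = ll_inc, qval = qval,
       newton_iters = iters)
}

#' Laplace filter update at one bin for one neuron
#'
#' Finds the MAP of the per-neuron filter density (logistic log-likelihood
#' over trials plus Gaussian one-step-prediction prior) by damped
#' Newton-Raphson with step-halving, and takes the covariance from the
#' inverse negative Hessian (Fisher information plus prior precision) at the
#' mode.
#'
#' @param pred_mean,pred_cov one-step prediction moments (length N+1 /
#'   (N+1) x (N+1)).
#' @param x_t,x_prev binary N x L matrices of states at bins t and t-1.
#' @param i neuron index.
#' @param newton_max_iter,newton_grad_tol see [fit_config].
#' @return list with `filt_mean`, `filt_cov`, `newton_iters`, plus the
#'   bin's Laplace marginal-likelihood increment `ll_inc`.
#' @export
filter_step <- function(pred_mean, pred_cov, x_t, x_prev, i,
                        newton_max_iter = 100, newton_grad_tol = 1e-8) {
  if (!is.matrix(x_t) || !is.matrix(x_prev) || !all(dim(x_t) == dim(x_prev)))
    stop("'x_t' and 'x_prev' must be N x L matrices of equal shape")
  st <- bin_sufficient_stats(x_prev, x_t)
  filter_update(pred_mean, pred_cov, st$design, st$counts, st$succ[, i],
                newton_max_iter, newton_grad_tol)
}

#' Fixed-interval smoother for one neuron
#'
#' Backward recursion combining the filter pass with later data: the smoothed
#' innovation at bin t is taken against the one-step prediction moments, with
#' gain `A_{t-1} = W_{t-1|t-1} (W_{t|t-1})^{-1}`. The smoothed moments at the
#' last bin equal the filtered ones.
#'
#' @param filt_mean,pred_mean d x T matrices of filtered and one-step
#'   predicted means.
#' @param filt_cov,pred_cov d x d x T arrays of filtered and predicted
#'   covariances.
#' @return list with `smooth_mean` (d x T), `smooth_cov` (d x d x T) and
#'   `gains` (d x d x T; slot t holds `A_t`, defined for t = 1..T-1).
#' @export
smooth_pass <- function(filt_mean, filt_cov, pred_mean, pred_cov) {
  d <- nrow(filt_mean); T_ <- ncol(filt_mean)
  sm <- filt_mean
  sc <- filt_cov
  gains <- array(NA_real_, dim = c(d, d, T_))
  if (T_ >= 2) {
    for (t in T_:2) {
      A <- tryCatch(
        t(chol_solve(pred_cov[, , t], t(filt_cov[, , t - 1]))),
        error = function(e) stop("singular one-step prediction covariance at bin ",
                                 t, ": ", conditionMessage(e)))
      sm[, t - 1] <- filt_mean[, t - 1] + A %*% (sm[, t] - pred_mean[, t])
      sc[, , t - 1] <- sym(filt_cov[, , t - 1] +
                             A %*% (sc[, , t] - pred_cov[, , t]) %*% t(A))
      gains[, , t - 1] <- A
    }
  }
  list(smooth_mean = sm, smooth_cov = sc, gains = gains)
}

#' Lag-one smoothing covariance
#'
#' Cross-covariance between the states of two consecutive bins under the
#' smoothing posterior: `filt_cov %*% solve(pred_cov_next) %*% smooth_cov`.
#' Called with the filtered covariance at bin t, the predicted covariance at
#' t+1 and the smoothed covariance at t+1, this yields
#' `Cov(theta_t, theta_{t+1} | all data) = A_t W_{t+1|T}`.
#'
#' @param filt_cov filtered covariance at the earlier bin.
#' @param pred_cov_next one-step prediction covariance at the later bin.
#' @param smooth_cov smoothed covariance (see above for the index pairing
#'   used by the EM update).
#' @return d x d matrix.
#' @export
lag_one_covariance <- function(filt_cov, pred_cov_next, smooth_cov) {
  filt_cov %*% chol_solve(pred_cov_next, smooth_cov)
}

#' E-step: filter and smooth all neurons
#'
#' Runs the Laplace filter forward over bins 1..T and the fixed-interval
#' smoother backward, independently per neuron, under fixed hyperparameters.
#' Also accumulates the Laplace approximation of the marginal log-likelihood.
#'
#' @param spikes a [spike_tensor].
#' @param hyper list of [neuron_hyperparams], one per neuron.
#' @param cfg a [fit_config].
#' @param stats optional precomputed per-bin sufficient statistics (internal).
#' @return object of class `kinetic_posterior`: per neuron the prediction,
#'   filter and smoothing moments (`d x T` means, `d x d x T` covariances),
#'   lag-one covariances (`lag_one[, , t]` holds
#'   `Cov(theta_{t-1}, theta_t | T)` for t >= 2) and the total
#'   `log_marginal`.
#' @export
kinetic_estep <- function(spikes, hyper, cfg = fit_config(), stats = NULL) {
  d3 <- dim(spikes$data)
  N <- d3[1]; T_ <- d3[2] - 1L; L <- d3[3]
  d <- N + 1L
  if (is.null(stats)) stats <- precompute_stats(spikes)
  neurons <- vector("list", N)
  ll_total <- 0
  for (i in seq_len(N)) {
    pm <- matrix(0, d, T_); pc <- array(0, dim = c(d, d, T_))
    fm <- matrix(0, d, T_); fc <- array(0, dim = c(d, d, T_))
    ll_i <- 0
    mean_prev <- hyper[[i]]$mu
    cov_prev <- hyper[[i]]$sigma
    for (t in seq_len(T_)) {
      if (t == 1L) {
        pm[, 1] <- mean_prev; pc[, , 1] <- sym(cov_prev)
      } else {
        pr <- predict_step(fm[, t - 1], fc[, , t - 1], hyper[[i]]$q)
        pm[, t] <- pr$pred_mean; pc[, , t] <- pr$pred_cov
      }
      st <- stats[[t]]
      up <- tryCatch(
        filter_update(pm[, t], pc[, , t], st$design, st$counts, st$succ[, i],
                      cfg$newton_max_iter, cfg$newton_grad_tol),
        error = function(e) stop("filter failed for neuron ", i, ", bin ", t,
                                 ": ", conditionMessage(e)))
      fm[, t] <- up$filt_mean; fc[, , t] <- up$filt_cov
      ll_i <- ll_i + up$ll_inc
    }
    smo <- smooth_pass(fm, fc, pm, pc)
    lag <- array(NA_real_, dim = c(d, d, T_))
    if (T_ >= 2) for (t in 2:T_)
      lag[, , t] <- lag_one_covariance(fc[, , t - 1], pc[, , t],
                                       smo$smooth_cov[, , t])
    neurons[[i]] <- list(pred_mean = pm, pred_cov = pc,
                         filt_mean = fm, filt_cov = fc,
                         smooth_mean = smo$smooth_mean,
                         smooth_cov = smo$smooth_cov,
                         gains = smo$gains, lag_one = lag,
                         log_marginal = ll_i)
    ll_total <- ll_total + ll_i
  }
  structure(list(neurons = neurons, N = N, T = T_, L = L,
                 log_marginal = ll_total),
            class = "kinetic_posterior")
}

precompute_stats <- function(spikes) {
  d3 <- dim(spikes$data)
  T_ <- d3[2] - 1L
  lapply(seq_len(T_), function(t)
    bin_sufficient_stats(matrix(spikes$data[, t, ], d3[1], d3[3]),
                         matrix(spikes$data[, t + 1L, ], d3[1], d3[3])))
}

#' @export
print.kinetic_posterior <- function(x, ...) {
  cat(sprintf("kinetic_posterior: N = %d, T = %d, L = %d, approx. log marginal likelihood = %.3f\n",
              x$N, x$T, x$L, x$log_marginal))
  invisible(x)
}

#' M-step: hyperparameter updates from the smoothed posterior
#'
#' State-noise covariance update averaging smoothed increments and
#' covariances over bins 2..T; under `q_structure = "diagonal"` the diagonal
#' of the full update is taken, under `"scalar"` its trace over the dimension
#' times identity. The initial mean is set to the smoothed mean at bin 1 (its
#' joint maximizer with the initial covariance), which collapses the
#' initial-covariance update to the smoothed covariance at bin 1.
#'
#' @param posterior a `kinetic_posterior` from [kinetic_estep].
#' @param hyper current list of [neuron_hyperparams] (carried through when
#'   `optimize_initial` is off).
#' @param cfg a [fit_config].
#' @return updated list of [neuron_hyperparams].
#' @export
m_step <- function(posterior, hyper, cfg = fit_config()) {
  T_ <- posterior$T
  lapply(seq_len(posterior$N), function(i) {
    n <- posterior$neurons[[i]]
    d <- nrow(n$smooth_mean)
    Q <- matrix(0, d, d)
    for (t in 2:T_) {
      dd <- n$smooth_mean[, t] - n$smooth_mean[, t - 1]
      C <- n$lag_one[, , t]                       # Cov(theta_{t-1}, theta_t | T)
      Q <- Q + tcrossprod(dd) + n$smooth_cov[, , t] + n$smooth_cov[, , t - 1] -
        C - t(C)
    }
    Q <- sym(Q / (T_ - 1))
    if (cfg$q_structure == "diagonal") Q <- diag(diag(Q), d)
    if (cfg$q_structure == "scalar") Q <- (sum(diag(Q)) / d) * diag(d)
    # guard: PSD projection against tiny negative eigenvalues from roundoff
    ev <- eigen(Q, symmetric = TRUE)
    Q <- sym(ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors)))
    if (cfg$optimize_initial) {
      mu <- n$smooth_mean[, 1]
      Sigma <- sym(n$smooth_cov[, , 1])
    } else {
      mu <- hyper[[i]]$mu
      dd <- n$smooth_mean[, 1] - mu
      Sigma <- sym(n$smooth_cov[, , 1] + tcrossprod(dd))
    }
    # positive-definite floor so the next E-step can factorize Sigma
    ev_s <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_s < 1e-10) Sigma <- Sigma + (1e-10 - min(ev_s, 0)) * diag(d)
    neuron_hyperparams(mu, Sigma, Q, q_structure = cfg$q_structure)
  })
}

#' Approximate marginal log-likelihood (Laplace)
#'
#' Recomputes the Laplace approximation of the marginal log-likelihood from
#' the stored prediction/filter moments and the data:
#' `sum_{t,i} [ loglik(theta_{t|t}^i) - quad(theta_{t|t}^i)
#' + log|W_{t|t}^i|/2 - log|W_{t|t-1}^i|/2 ]`, where `quad` is the prediction
#' -prior quadratic form at the MAP. The initial-pattern term `log p(x_0)` is
#' zero under the conditioned-on-`x_0` convention used throughout.
#'
#' @param posterior a `kinetic_posterior`.
#' @param spikes the [spike_tensor] it was fitted to.
#' @return scalar log-likelihood (nats).
#' @export
marginal_log_likelihood <- function(posterior, spikes) {
  stats <- precompute_stats(spikes)
  total <- 0
  for (i in seq_len(posterior$N)) {
    n <- posterior$neurons[[i]]
    for (t in seq_len(posterior$T)) {
      st <- stats[[t]]
      th <- n$filt_mean[, t]
      eta <- as.numeric(st$design %*% th)
      d <- th - n$pred_mean[, t]
      Pinv <- chol_inv(n$pred_cov[, , t])
      qval <- sum(st$succ[, i] * eta - st$counts * softplus(eta)) -
        0.5 * sum(d * (Pinv %*% d))
      total <- total + qval + 0.5 * logdet_pd(n$filt_cov[, , t]) -
        0.5 * logdet_pd(n$pred_cov[, , t])
    }
  }
  total
}

#' Fit the state-space kinetic Ising model by EM
#'
#' Alternates the Laplace filter/smoother E-step with closed-form
#' hyperparameter M-steps, independently per neuron, until the approximate
#' marginal log-likelihood changes by less than `em_rel_tol` in relative
#' terms or `max_em_iter` is reached. Initialization: the initial mean is the
#' logit of each neuron's grand-mean rate (clamped away from 0/1) with zero
#' couplings, identity initial covariance, and `init_q_scale * identity`
#' state noise. With `freeze_q = TRUE` a single E-step is run with zero state
#' noise and no hyperparameter optimization (stationary mode).
#'
#' @param spikes a [spike_tensor].
#' @param cfg a [fit_config].
#' @param hyper optional initial list of [neuron_hyperparams]; by default
#'   built from the data as described above.
#' @return list with `posterior` (a `kinetic_posterior`), `hyper` (final
#'   hyperparameters), `ll_trace` (marginal log-likelihood per EM iteration)
#'   and `converged`.
#' @examples
#' \donttest{
#' truth <- sample_param_trajectories(2, 40, gp_config(-2, 0.5, 20),
#'                                    gp_config(0, 0.5, 10), seed = 1)
#' spk <- simulate_spikes(truth, L = 100, seed = 2)
#' fit <- fit_em(spk, fit_config(max_em_iter = 20))
#' plot(fit$ll_trace, type = "b")
#' }
#' @export
fit_em <- function(spikes, cfg = fit_config(), hyper = NULL) {
  d3 <- dim(spikes$data)
  N <- d3[1]; T_ <- d3[2] - 1L; L <- d3[3]
  d <- N + 1L
  if (T_ < 2 && !cfg$freeze_q)
    stop("need T >= 2 unless the state noise is frozen at zero")
  stats <- precompute_stats(spikes)
  if (is.null(hyper)) {
    rate <- apply(spikes$data, 1, mean)
    eps <- 1 / (T_ * L + 2)
    rate <- pmin(pmax(rate, eps), 1 - eps)
    q0 <- if (cfg$freeze_q) 0 else cfg$init_q_scale
    hyper <- lapply(seq_len(N), function(i)
      neuron_hyperparams(c(qlogis(rate[i]), rep(0, N)), diag(d),
                         q0 * diag(d), q_structure = cfg$q_structure))
  }
  if (cfg$freeze_q) {
    post <- kinetic_estep(spikes, hyper, cfg, stats)
    return(list(posterior = post, hyper = hyper,
                ll_trace = post$log_marginal, converged = TRUE))
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (it in seq_len(cfg$max_em_iter)) {
    post <- kinetic_estep(spikes, hyper, cfg, stats)
    ll_trace <- c(ll_trace, post$log_marginal)
    if (it > 1) {
      rel <- abs(ll_trace[it] - ll_trace[it - 1]) /
        max(abs(ll_trace[it]), .Machine$double.eps)
      if (rel < cfg$em_rel_tol) { converged <- TRUE; break }
    }
    hyper <- m_step(post, hyper, cfg)
  }
  list(posterior = post, hyper = hyper, ll_trace = ll_trace,
       converged = converged)
}

#' Extract smoothed parameter trajectories
#'
#' Repackages the smoothed posterior means as a [param_trajectory] (fields
#' and couplings), the form consumed by the entropy-flow estimators.
#'
#' @param posterior a `kinetic_posterior`.
#' @return a [param_trajectory].
#' @export
smoothed_params <- function(posterior) {
  N <- posterior$N; T_ <- posterior$T
  fields <- matrix(0, N, T_)
  couplings <- array(0, dim = c(N, N, T_))
  for (i in seq_len(N)) {
    sm <- posterior$neurons[[i]]$smooth_mean
    fields[i, ] <- sm[1, ]
    couplings[i, , ] <- sm[-1, , drop = FALSE]
  }
  param_trajectory(fields, couplings)
}
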