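#' Read a spike-event table
#'
#' Tab-separated, UTF-8, with a required header row `trial`, `neuron`,
#' `time_ms`; lines starting with `#` are comments. Trial and neuron ids
#' must be positive integers densely mappable to 1..L and 1..N.
#'
#' @param path file path.
#' @return data frame with columns `trial`, `neuron`, `time_ms`.
#' @export
read_spike_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("trial", "neuron", "time_ms")
  if (!all(need %in% names(ev)))
    stop("event table must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(ev$time_ms))) stop("event times must be finite")
  if (any(ev$trial < 1) || any(ev$neuron < 1))
    stop("trial and neuron ids must be >= 1")
  ev
}

#' Bin a spike-event table into a binary tensor
#'
#' Element (i, t, l) is 1 iff neuron i has one or more events in the
#' half-open window `[t_start + t * bin_width, t_start + (t+1) * bin_width)`
#' on trial l — an event exactly on a right edge belongs to the next bin.
#' Events outside the covered window are dropped (a message reports the
#' count). Bin index 0 is the first bin of the tensor.
#'
#' @param events data frame with columns `trial`, `neuron`, `time_ms` (see
#'   [read_spike_events]).
#' @param bin_width bin width in ms (> 0).
#' @param t_start left edge of bin 0, in ms.
#' @param n_bins total number of bins (>= 2), i.e. `T + 1`.
#' @param n_neurons,n_trials optional fixed dimensions; default to the
#'   maximum ids present.
#' @return a [spike_tensor].
#' @export
bin_spikes <- function(events, bin_width, t_start, n_bins,
                       n_neurons = NULL, n_trials = NULL) {
  stopifnot(bin_width > 0, n_bins >= 2)
  if (nrow(events) == 0) {
    warning("empty event table; returning all-zero tensor")
    if (is.null(n_neurons) || is.null(n_trials))
      stop("empty table needs explicit 'n_neurons' and 'n_trials'")
    return(spike_tensor(array(0, dim = c(n_neurons, n_bins, n_trials)),
                        bin_width = bin_width, t0 = t_start))
  }
  if (is.null(n_neurons)) n_neurons <- max(events$neuron)
  if (is.null(n_trials)) n_trials <- max(events$trial)
  bin <- floor((events$time_ms - t_start) / bin_width)
  keep <- bin >= 0 & bin < n_bins
  if (any(!keep))
    message(sum(!keep), " event(s) outside the binning window dropped")
  x <- array(0, dim = c(n_neurons, n_bins, n_trials))
  idx <- cbind(events$neuron[keep], bin[keep] + 1, events$trial[keep])
  x[idx] <- 1
  spike_tensor(x, bin_width = bin_width, t0 = t_start)
}

#' Keep the most active neurons
#'
#' Retains the `n_keep` neurons with the highest grand-mean spike rate,
#' preserving original order; ties broken in favor of the lower original
#' index.
#'
#' @param spikes a [spike_tensor].
#' @param n_keep number of neurons to keep (<= N).
#' @return list with `spikes` (subset tensor) and `index` (original ids of
#'   the kept neurons, in their original order).
#' @export
select_top_neurons <- function(spikes, n_keep) {
  N <- dim(spikes$data)[1]
  stopifnot(n_keep >= 1, n_keep <= N)
  r <- mean_rates(spikes)
  keep <- sort(order(-r, seq_len(N))[seq_len(n_keep)])
  list(spikes = spike_tensor(spikes$data[keep, , , drop = FALSE],
                             bin_width = spikes$bin_width, t0 = spikes$t0),
       index = keep)
}

# -- plain-text serialization -------------------------------------------------
# One TSV per object; '#'-prefixed header lines carry a format tag, a format
# version and the metadata needed to rebuild the object bit-exactly.

write_header <- function(con, kind, meta) {
  writeLines(sprintf("# kinflow %s v1", kind), con)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(meta[[k]], digits = 17), collapse = " ")),
               con)
}

read_header <- function(path, kind) {
  lines <- readLines(path, n = 50)
  hdr <- lines[startsWith(lines, "# ")]
  if (!length(hdr) || !grepl(paste0("kinflow ", kind, " v1"), hdr[1]))
    stop("'", path, "' is not a kinflow ", kind, " file")
  meta <- list()
  for (ln in hdr[-1]) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- strsplit(sub("^[^:]*: *", "", kv), " ")[[1]]
  }
  meta
}

#' Write / read a spike tensor as plain text
#'
#' The tensor is stored as a TSV whose rows are the `(bin, trial)` slices
#' (trial-major) and whose columns are neurons, preceded by a commented
#' header holding dimensions, bin width and time origin. The round trip is
#' bit-exact.
#'
#' @param spikes a [spike_tensor].
#' @param path file path.
#' @return `write_spike_tensor` returns `path` invisibly;
#'   `read_spike_tensor` returns a [spike_tensor].
#' @export
write_spike_tensor <- function(spikes, path) {
  d <- dim(spikes$data)
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, "spike_tensor",
               list(N = d[1], n_bins = d[2], L = d[3],
                    bin_width = spikes$bin_width, t0 = spikes$t0))
  m <- matrix(aperm(spikes$data, c(2, 3, 1)), d[2] * d[3], d[1])
  utils::write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_tensor
#' @export
read_spike_tensor <- function(path) {
  meta <- read_header(path, "spike_tensor")
  N <- as.integer(meta$N); nb <- as.integer(meta$n_bins)
  L <- as.integer(meta$L)
  m <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  x <- aperm(array(m, dim = c(nb, L, N)), c(3, 1, 2))
  spike_tensor(x, bin_width = as.numeric(meta$bin_width),
               t0 = as.numeric(meta$t0))
}

#' Write / read a parameter trajectory as plain text
#'
#' Long-format TSV with columns `i`, `j`, `t`, `value`; field rows carry
#' `j = 0`. Values are written with full (17 significant digit) precision,
#' so the round trip reproduces doubles bit-exactly.
#'
#' @param params a [param_trajectory].
#' @param path file path.
#' @return `write_param_trajectory` returns `path` invisibly;
#'   `read_param_trajectory` returns a [param_trajectory].
#' @export
write_param_trajectory <- function(params, path) {
  N <- nrow(params$fields); T_ <- ncol(params$fields)
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, "param_trajectory", list(N = N, T = T_))
  fi <- data.frame(i = rep(seq_len(N), T_), j = 0L,
                   t = rep(seq_len(T_), each = N),
                   value = sprintf("%.17g", as.numeric(params$fields)))
  idx <- expand.grid(i = seq_len(N), j = seq_len(N), t = seq_len(T_))
  co <- data.frame(idx, value = sprintf("%.17g", as.numeric(params$couplings)))
  utils::write.table(rbind(fi, co), con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_param_trajectory
#' @export
read_param_trajectory <- function(path) {
  meta <- read_header(path, "param_trajectory")
  N <- as.integer(meta$N); T_ <- as.integer(meta$T)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c("integer", "integer", "integer",
                                         "character"))
  v <- as.numeric(df$value)
  fields <- matrix(v[df$j == 0][order(df$t[df$j == 0], df$i[df$j == 0])], N, T_)
  cc <- df[df$j > 0, ]
  couplings <- array(0, dim = c(N, N, T_))
  couplings[cbind(cc$i, cc$j, cc$t)] <- as.numeric(cc$value)
  param_trajectory(fields, couplings)
}

#' Write / read an entropy-flow series as plain text
#'
#' TSV with one row per bin (`t`, `flow`, `forward`, `backward`, optional
#' `se`) at full precision; per-neuron contributions, when present, follow
#' as additional `neuron_<i>` columns.
#'
#' @param flow an [entropy_flow_series].
#' @param path file path.
#' @return `write_entropy_flow` returns `path` invisibly;
#'   `read_entropy_flow` returns an [entropy_flow_series].
#' @export
write_entropy_flow <- function(flow, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, "entropy_flow", list(method = flow$method,
                                         T = length(flow$t)))
  df <- data.frame(t = flow$t,
                   flow = sprintf("%.17g", flow$flow),
                   forward = sprintf("%.17g", flow$forward),
                   backward = sprintf("%.17g", flow$backward))
  if (!is.null(flow$se)) df$se <- sprintf("%.17g", flow$se)
  if (!is.null(flow$per_neuron)) {
    pn <- t(flow$per_neuron)
    colnames(pn) <- paste0("neuron_", seq_len(nrow(flow$per_neuron)))
    df <- cbind(df, apply(pn, 2, function(v) sprintf("%.17g", v)))
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_entropy_flow
#' @export
read_entropy_flow <- function(path) {
  meta <- read_header(path, "entropy_flow")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = "character")
  num <- function(col) as.numeric(df[[col]])
  pn_cols <- grep("^neuron_", names(df), value = TRUE)
  per_neuron <- if (length(pn_cols))
    t(vapply(df[pn_cols], as.numeric, numeric(nrow(df)))) else NULL
  entropy_flow_series(as.integer(df$t), num("flow"), num("forward"),
                      num("backward"), method = meta$method,
                      per_neuron = per_neuron,
                      se = if ("se" %in% names(df)) num("se") else NULL)
}
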