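#' Simulation configuration
#'
#' Controls for the time-stepped point-process simulator.  The time step must
#' resolve the kernels (`dt <= tau/10` is enforced); the warmup period is
#' simulated and discarded before any spike is recorded, so that statistics
#' are taken in the stationary state.
#'
#' @param duration_s Total simulated time in seconds (including warmup).
#' @param dt_ms Time step in milliseconds (default 0.1 ms).
#' @param warmup_s Initial period discarded, in seconds (default 10 s);
#'   must be smaller than `duration_s`.
#' @param y0_rate Constant external drive in spikes/s.
#' @param tau_exc_ms,tau_inh_ms Kernel time constants of excitatory and
#'   inhibitory sources (ms).
#' @param delay_ms Global synaptic delay (ms); delays shift kernels in time
#'   and leave all integrated quantities unchanged.  At least one time step.
#' @param rate_ceiling Abort threshold on the intensity (spikes/s); an
#'   exploding network raises an error instead of running away.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_s, dt_ms = 0.1, warmup_s = 10, y0_rate = 10,
                       tau_exc_ms = 10, tau_inh_ms = 10, delay_ms = 1,
                       rate_ceiling = 1e4) {
  check_scalar(duration_s, "duration_s", lower = .Machine$double.eps)
  check_scalar(dt_ms, "dt_ms", lower = .Machine$double.eps)
  check_scalar(warmup_s, "warmup_s", lower = 0)
  check_scalar(y0_rate, "y0_rate", lower = 0)
  check_scalar(tau_exc_ms, "tau_exc_ms", lower = .Machine$double.eps)
  check_scalar(tau_inh_ms, "tau_inh_ms", lower = .Machine$double.eps)
  check_scalar(delay_ms, "delay_ms", lower = 0)
  if (dt_ms > min(tau_exc_ms, tau_inh_ms) / 10) {
    abort("`dt_ms` must not exceed tau/10: the step has to resolve the kernel.",
      class = "hawkesnet_parameter_error"
    )
  }
  if (warmup_s >= duration_s) {
    abort("`warmup_s` must be smaller than `duration_s`.",
      class = "hawkesnet_parameter_error"
    )
  }
  structure(
    list(
      duration_s = duration_s, dt_ms = dt_ms, warmup_s = warmup_s,
      y0_rate = y0_rate, tau_exc_ms = tau_exc_ms, tau_inh_ms = tau_inh_ms,
      delay_ms = delay_ms, rate_ceiling = rate_ceiling
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %.4g s (%.4g s warmup), dt %.3g ms, drive %.4g spikes/s, tau E/I %.3g/%.3g ms, delay %.3g ms\n",
    x$duration_s, x$warmup_s, x$dt_ms, x$y0_rate, x$tau_exc_ms, x$tau_inh_ms, x$delay_ms
  ))
  invisible(x)
}

#' Simulate a network of linearly interacting point processes
#'
#' Time-stepped simulation: each neuron carries an intensity
#' `u_i = y0_rate + synaptic state`; per step it fires a Bernoulli spike with
#' probability `max(u_i, 0) * dt` (negative intensities are rectified to
#' produce no output, the nonlinearity the linear theory neglects).  A spike
#' of neuron `j` increments the state of every target `i` by
#' `G[i,j] / tau_j` after the global delay; states decay exponentially with
#' the exact per-step factor.  Identical seeds give identical spike trains.
#'
#' @param net A [hawkes_network()].
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `spike_trains` tibble with columns `neuron` (1-based) and
#'   `time` (seconds, relative to the end of the warmup, strictly increasing
#'   within neuron).  Attributes: `n`, `duration` (seconds of recorded
#'   activity), `config`, `seed`.
#' @section Warnings: if `max(u) * dt` exceeded 0.1 at any step the Bernoulli
#'   discretisation is too coarse and a warning is emitted.
#' @export
simulate_hawkes <- function(net, config, seed = NULL) {
  stopifnot(inherits(net, "hawkes_network"), inherits(config, "sim_config"))
  G <- net$G
  n <- net$n
  dt_s <- config$dt_ms / 1000
  tau_s <- ifelse(net$types == "E", config$tau_exc_ms, config$tau_inh_ms) / 1000
  srcs <- rep.int(seq_len(n), diff(G@p))
  amp <- G@x / tau_s[srcs]
  n_steps <- round(config$duration_s / dt_s)
  warm_steps <- round(config$warmup_s / dt_s)
  delay_steps <- max(1L, as.integer(round(config$delay_ms / config$dt_ms)))
  res <- with_seed_if(seed, {
    simulate_hawkes_cpp(
      n, G@p, G@i, amp, as.integer(net$types == "I"),
      config$y0_rate, dt_s,
      exp(-dt_s * 1000 / config$tau_exc_ms), exp(-dt_s * 1000 / config$tau_inh_ms),
      delay_steps, n_steps, warm_steps, config$rate_ceiling
    )
  })
  if (res$max_step_probability > 0.1) {
    warn(sprintf(
      "Per-step spike probability reached %.3g (> 0.1): the time step is too coarse for this intensity range.",
      res$max_step_probability
    ))
  }
  out <- tibble(neuron = res$neuron, time = res$time)
  attr(out, "n") <- n
  attr(out, "duration") <- (n_steps - warm_steps) * dt_s
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("spike_trains", class(out))
  out
}

#' Count statistics of simulated spike trains
#'
#' Bins the spike trains and estimates the quantities the theory predicts:
#' per-neuron rates (total spikes over the recording), the matrix of spike
#' count covariances divided by the bin size (which estimates the integrated
#' covariance density for bins much wider than the kernels; `bin_s >=
#' 20 * tau` recommended), the population count variance per bin size, and
#' per-neuron inter-spike-interval coefficients of variation.
#'
#' @param spikes A `spike_trains` tibble from [simulate_hawkes()] or
#'   [read_spikes()].
#' @param bin_s Counting bin in seconds.
#' @return An object of class `count_statistics`: list with `rates_hat`,
#'   `cov_hat`, `pop_var_hat`, `cv` (NA for neurons with fewer than 3
#'   spikes), `bin_s`, `n`, `duration`, `n_bins`.  `pop_var_hat` equals
#'   `sum(cov_hat)` by construction.
#' @export
estimate_counts <- function(spikes, bin_s) {
  n <- attr(spikes, "n")
  duration <- attr(spikes, "duration")
  if (is.null(n) || is.null(duration)) {
    abort("`spikes` must carry `n` and `duration` attributes (see simulate_hawkes()/read_spikes()).",
      class = "hawkesnet_parameter_error"
    )
  }
  check_scalar(bin_s, "bin_s", lower = .Machine$double.eps)
  n_bins <- floor(duration / bin_s)
  if (n_bins < 2) {
    abort("Fewer than 2 counting bins; lengthen the recording or shrink the bin.",
      class = "hawkesnet_estimator_error"
    )
  }
  b <- floor(spikes$time / bin_s) + 1
  keep <- b <= n_bins
  counts <- matrix(
    tabulate(spikes$neuron[keep] + n * (b[keep] - 1L), nbins = n * n_bins),
    nrow = n, ncol = n_bins
  )
  cov_hat <- cov(t(counts)) / bin_s
  cv <- vapply(seq_len(n), function(i) {
    ts <- spikes$time[spikes$neuron == i]
    if (length(ts) < 3) return(NA_real_)
    isi <- diff(ts)
    sd(isi) / mean(isi)
  }, numeric(1))
  structure(
    list(
      rates_hat = tabulate(spikes$neuron, nbins = n) / duration,
      cov_hat = cov_hat,
      pop_var_hat = var(colSums(counts)) / bin_s,
      cv = cv,
      bin_s = bin_s, n = n, duration = duration, n_bins = n_bins
    ),
    class = "count_statistics"
  )
}

#' @export
print.count_statistics <- function(x, ...) {
  cat(sprintf(
    "<count_statistics> %d neurons, %.4g s in %d bins of %.3g s | mean rate %.4g spikes/s | mean ISI CV %.3g | population variance %.4g\n",
    x$n, x$duration, x$n_bins, x$bin_s, mean(x$rates_hat),
    mean(x$cv, na.rm = TRUE), x$pop_var_hat
  ))
  invisible(x)
}

#' @describeIn estimate_counts Per-neuron tibble: `neuron`, `rate_hat`, `cv`.
#' @param x A `count_statistics` object.
#' @param ... Unused.
#' @export
tidy.count_statistics <- function(x, ...) {
  tibble(neuron = seq_len(x$n), rate_hat = x$rates_hat, cv = x$cv)
}

#' @describeIn estimate_counts One-row summary tibble.
#' @export
glance.count_statistics <- function(x, ...) {
  tibble(
    n_neurons = x$n, duration = x$duration, bin_s = x$bin_s,
    mean_rate = mean(x$rates_hat), mean_cv = mean(x$cv, na.rm = TRUE),
    pop_var_hat = x$pop_var_hat
  )
}
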