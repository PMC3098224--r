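#' Interaction kernel specification
#'
#' Describes the causal synaptic interaction kernel of one population.  The
#' kernel is exponential: a presynaptic spike at time \eqn{t} changes the
#' postsynaptic intensity by \eqn{(w/\tau)\,e^{-(s-t-\delta)/\tau}} for
#' \eqn{s > t + \delta}, so that its time integral equals the weight \eqn{w} —
#' the expected number of extra postsynaptic spikes caused by one presynaptic
#' spike.  Delays shift the kernel in time and leave all integrated quantities
#' unchanged.
#'
#' @param weight Integrated kernel (dimensionless, expected extra spikes per
#'   input spike).  Positive for excitation, negative for inhibition.
#' @param tau_ms Kernel time constant in milliseconds; must be positive.
#' @param delay_ms Transmission delay in milliseconds; must be non-negative.
#' @param shape Kernel shape; only `"exponential"` is implemented.
#'
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec(weight = 0.035, tau_ms = 10)
#' @export
kernel_spec <- function(weight, tau_ms = 10, delay_ms = 1, shape = "exponential") {
  shape <- match.arg(shape, "exponential")
  check_scalar(weight, "weight")
  check_scalar(tau_ms, "tau_ms", lower = .Machine$double.eps)
  check_scalar(delay_ms, "delay_ms", lower = 0)
  structure(
    list(shape = shape, weight = weight, tau_ms = tau_ms, delay_ms = delay_ms),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf(
    "<kernel_spec> %s, weight %.4g, tau %.3g ms, delay %.3g ms\n",
    x$shape, x$weight, x$tau_ms, x$delay_ms
  ))
  invisible(x)
}

#' Boxcar connection-probability profile on a ring
#'
#' Distance-dependent connectivity on a ring is parametrised by a boxcar:
#' a presynaptic neuron connects to a neuron at geodesic distance `d` with
#' probability `height` if `1 <= d <= half_width` and 0 otherwise (distance 0
#' is excluded: no self-connections).  The expected out-connectivity of a
#' source is `height * 2 * half_width / n` up to the antipodal offset on even
#' rings, which is counted once.
#'
#' @param half_width Half width \eqn{\sigma} of the boxcar, in geodesic
#'   distance units (non-negative integer, at most `n/2` for a ring of `n`).
#' @param height Connection probability inside the boxcar, in `[0, 1]`.
#'
#' @return An object of class `ring_profile`.
#' @examples
#' ring_profile(half_width = 100, height = 0.5)
#' @export
ring_profile <- function(half_width, height) {
  check_scalar(half_width, "half_width", lower = 0)
  if (half_width != round(half_width)) {
    abort("`half_width` must be an integer number of ring positions.",
      class = "hawkesnet_parameter_error"
    )
  }
  check_prob(height, "height")
  structure(
    list(half_width = as.integer(half_width), height = height),
    class = "ring_profile"
  )
}

#' @export
print.ring_profile <- function(x, ...) {
  cat(sprintf(
    "<ring_profile> boxcar, half width %d, height %.3g\n",
    x$half_width, x$height
  ))
  invisible(x)
}

# Probability vector over circular offsets 0..n-1 for a boxcar profile.
# Symmetric, zero at offset 0; for even n the antipodal offset appears once.
profile_vector <- function(profile, n) {
  stopifnot(inherits(profile, "ring_profile"))
  if (profile$half_width > n / 2) {
    abort("`half_width` may not exceed n/2 on a ring of n nodes.",
      class = "hawkesnet_parameter_error"
    )
  }
  p <- numeric(n)
  d <- seq_len(n) - 1L
  geo <- pmin(d, n - d)
  p[geo >= 1 & geo <= profile$half_width] <- profile$height
  p
}
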