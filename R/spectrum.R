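#' Predicted bulk-spectrum radius of a random connectivity matrix
#'
#' For a large random network with uniform connection probability `p`, the
#' eigenvalues of `G` form a circular bulk of radius
#' \eqn{B = \sqrt{p(1-p)(N_E w_E^2 + N_I w_I^2)}}
#' (the standard deviation of the total input of a neuron) plus a single
#' real outlier at the mean input \eqn{p(N_E w_E + N_I w_I)}.  The network
#' is linearly stable only if both the mean input and `B` stay below 1.
#'
#' @inheritParams avg_correlation_closed_form
#' @return The bulk radius `B` (non-negative).
#' @examples
#' # dense local subnetwork: stable (B slightly below one)
#' bulk_radius(0.6, 2000, 500, 0.019, -0.076)
#' # sparse large network, same weights: linearly unstable
#' bulk_radius(0.1, 12000, 3000, 0.019, -0.076)
#' @export
bulk_radius <- function(p, n_exc, n_inh, w_exc, w_inh) {
  check_prob(p, "p")
  sqrt(p * (1 - p) * (n_exc * w_exc^2 + n_inh * w_inh^2))
}

#' Spectral stability report for a network
#'
#' Computes the eigenvalues of the connectivity matrix (optionally — dense
#' non-symmetric eigendecomposition is the expensive step), the predicted
#' bulk radius and mean-input outlier from the realised network parameters,
#' and the two stability flags: `stable` (all real parts below 1, otherwise
#' activity explodes) and `series_convergent` (spectral radius below 1,
#' required for the motif series and the covariance formula).
#'
#' @param net A [hawkes_network()].
#' @param eigenvalues If `FALSE`, skip the eigendecomposition and report
#'   predictions only (flags are then `NA`).
#' @return An object of class `spectrum_report`.
#' @export
spectrum_report <- function(net, eigenvalues = TRUE) {
  stopifnot(inherits(net, "hawkes_network"))
  n <- net$n
  n_exc <- sum(net$types == "E")
  n_inh <- n - n_exc
  w <- net$G@x
  w_exc <- if (any(w > 0)) max(w) else 0
  w_inh <- if (any(w < 0)) min(w) else 0
  p_hat <- length(w) / (n * (n - 1))
  ev <- NULL
  rho <- max_re <- NA_real_
  if (eigenvalues) {
    ev <- eigen(as.matrix(net$G), only.values = TRUE)$values
    rho <- max(Mod(ev))
    max_re <- max(Re(ev))
  }
  structure(
    list(
      eigenvalues = ev,
      spectral_radius = rho,
      max_real_part = max_re,
      predicted_bulk_radius = bulk_radius(p_hat, n_exc, n_inh, w_exc, w_inh),
      predicted_mean_outlier = p_hat * (n_exc * w_exc + n_inh * w_inh),
      stable = if (eigenvalues) max_re < 1 else NA,
      series_convergent = if (eigenvalues) rho < 1 else NA,
      n = n, p_hat = p_hat, n_exc = n_exc, n_inh = n_inh,
      w_exc = w_exc, w_inh = w_inh
    ),
    class = "spectrum_report"
  )
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf(
    "<spectrum_report> %d nodes | bulk radius (predicted) %.4g | mean-input outlier (predicted) %.4g\n",
    x$n, x$predicted_bulk_radius, x$predicted_mean_outlier
  ))
  if (!is.na(x$spectral_radius)) {
    cat(sprintf(
      "  spectral radius %.4g | max real part %.4g | stable: %s | series convergent: %s\n",
      x$spectral_radius, x$max_real_part, x$stable, x$series_convergent
    ))
  }
  invisible(x)
}

#' @describeIn spectrum_report Eigenvalues as a tibble (`re`, `im`,
#'   `modulus`).
#' @param x A `spectrum_report`.
#' @param ... Unused.
#' @export
tidy.spectrum_report <- function(x, ...) {
  if (is.null(x$eigenvalues)) {
    abort("No eigenvalues computed; rerun spectrum_report() with eigenvalues = TRUE.",
      class = "hawkesnet_parameter_error"
    )
  }
  tibble(re = Re(x$eigenvalues), im = Im(x$eigenvalues), modulus = Mod(x$eigenvalues))
}

#' @describeIn spectrum_report One-row summary tibble.
#' @export
glance.spectrum_report <- function(x, ...) {
  tibble(
    n_nodes = x$n,
    spectral_radius = x$spectral_radius,
    max_real_part = x$max_real_part,
    predicted_bulk_radius = x$predicted_bulk_radius,
    predicted_mean_outlier = x$predicted_mean_outlier,
    stable = x$stable,
    series_convergent = x$series_convergent
  )
}
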