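# Distance-dependent correlation analytics on ring networks: numeric curves
# from full covariance matrices, and analytic curves from circular
# convolutions of the expected interaction profiles, evaluated with the
# discrete spatial Fourier transform.

signed_offset <- function(d, n) ifelse(d > n / 2, d - n, d)

#' Distance-dependent correlation from a covariance matrix
#'
#' Averages the integrated covariance over all ordered node pairs at each
#' signed ring offset: `c(d) = mean_i C[pos i + d, pos i]` (indices mod N).
#' The offset-0 entry is the mean autocovariance (including the Poisson rate
#' term).
#'
#' @param C Integrated covariance matrix.
#' @param positions Integer ring coordinates (0-based permutation of
#'   `0:(n-1)`), e.g. `net$positions`.
#' @return A tibble with one row per circular offset: `offset` (signed,
#'   `-floor((n-1)/2) .. floor(n/2)`), `distance` (geodesic), `value`.
#' @export
distance_correlation <- function(C, positions) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (is.null(positions) || length(positions) != n || !setequal(positions, 0:(n - 1))) {
    abort("`positions` must be a permutation of 0:(n-1) defining a ring.",
      class = "hawkesnet_parameter_error"
    )
  }
  ord <- order(positions)
  Cp <- C[ord, ord, drop = FALSE]
  i0 <- 0:(n - 1)
  value <- vapply(i0, function(d) {
    mean(Cp[cbind((i0 + d) %% n + 1L, i0 + 1L)])
  }, numeric(1))
  tibble(
    offset = signed_offset(i0, n),
    distance = pmin(i0, n - i0),
    value = value
  ) |> dplyr::arrange(.data$offset)
}

#' Analytic distance-dependent correlations on a ring
#'
#' Expected-profile (mean-field) correlations versus ring offset, expanded
#' by path length and evaluated in Fourier space.  The average interaction
#' at offset `d` is
#' \eqn{h(d) = f_E w_E p_E(d) + f_I w_I p_I(d)} and the distance-dependent
#' common input is the circular autocorrelation
#' \eqn{q(d) = f_E w_E^2 (p_E \star p_E)(d) + f_I w_I^2 (p_I \star p_I)(d)}.
#' With the DFT \eqn{\hat h(\omega)}, chains of length `n` contribute
#' \eqn{y\,\hat h^n} (plus the conjugate for the opposite branch) and
#' `(n, m)` common-input terms \eqn{y\,\hat q\,\hat h^{n-1}\bar{\hat h}^{m-1}},
#' so the order-`k` contribution is
#' \eqn{\hat c_k = y[\hat h^k + \bar{\hat h}^k + (k-1)\hat q\,\hat h^{k-2}]}
#' (symmetric profiles give a real \eqn{\hat h}) and the complete correlation
#' is the closed form
#' \eqn{\hat c = y[1 + \hat h/(1-\hat h) + \bar{\hat h}/(1-\bar{\hat h}) +
#'   \hat q/|1-\hat h|^2]}, inverse-transformed to offset space.  The series
#' converges iff \eqn{|\hat h(\omega)| < 1} at every spatial frequency; the
#' modes that violate this are the large-scale oscillatory eigenmodes of the
#' ring.
#'
#' The homogeneous rate \eqn{y = y_0/(1 - \hat h(0))} is used throughout, as
#' appropriate for the ensemble-averaged (homogeneous) ring.
#'
#' @inheritParams make_ring_network
#' @param y0 External drive (normalised default 1).
#' @param max_order Largest path-length order to tabulate.
#' @return An object of class `ring_profile_set`: list with `n`, `rate`,
#'   `profiles` (tibble: `offset`, `distance`, `h`, `q`), `orders` (long
#'   tibble: `order`, `offset`, `distance`, `value`), `total` (tibble:
#'   `offset`, `distance`, `value`; includes the Poisson rate term at offset
#'   0), and `hhat_max` (largest `|hhat|` over non-zero frequencies).
#' @export
distance_correlation_analytic <- function(n, profile_exc, profile_inh,
                                          w_exc, w_inh, frac_inhib = 0.2,
                                          y0 = 1, max_order = 10) {
  check_scalar(n, "n", lower = 2)
  check_prob(frac_inhib, "frac_inhib")
  f_inh <- frac_inhib
  pE <- profile_vector(profile_exc, n)
  pI <- profile_vector(profile_inh, n)
  h <- (1 - f_inh) * w_exc * pE + f_inh * w_inh * pI
  circ_autocorr <- function(p) Re(fft(Mod(fft(p))^2, inverse = TRUE)) / n
  q <- (1 - f_inh) * w_exc^2 * circ_autocorr(pE) + f_inh * w_inh^2 * circ_autocorr(pI)
  hhat <- fft(h)
  qhat <- fft(q)
  bad <- which(Mod(hhat) >= 1)
  if (length(bad)) {
    k <- bad[which.max(Mod(hhat)[bad])]
    abort(
      sprintf(
        "Analytic series diverges: |hhat| = %.4g >= 1 at spatial mode %d (oscillatory eigenmode).",
        max(Mod(hhat)), k - 1L
      ),
      class = "hawkesnet_divergence_error"
    )
  }
  y <- y0 / (1 - Re(hhat[1]))
  d <- 0:(n - 1)
  base <- tibble(offset = signed_offset(d, n), distance = pmin(d, n - d))
  idft <- function(z) Re(fft(z, inverse = TRUE)) / n
  orders <- purrr::map_dfr(seq_len(max_order), function(k) {
    chat <- y * (hhat^k + Conj(hhat)^k)
    if (k >= 2) {
      s <- 0 + 0i
      for (a in seq_len(k - 1)) s <- s + hhat^(a - 1) * Conj(hhat)^(k - a - 1)
      chat <- chat + y * qhat * s
    }
    dplyr::mutate(base, order = k, value = idft(chat))
  })
  chat_tot <- y * (1 + hhat / (1 - hhat) + Conj(hhat) / (1 - Conj(hhat)) +
    qhat / ((1 - hhat) * Conj(1 - hhat)))
  total <- dplyr::mutate(base, value = idft(chat_tot))
  structure(
    list(
      n = n, rate = y,
      profiles = dplyr::mutate(base, h = h, q = q),
      orders = dplyr::select(orders, "order", "offset", "distance", "value"),
      total = total,
      hhat_max = if (n > 1) max(Mod(hhat[-1])) else 0,
      mean_input = Re(hhat[1])
    ),
    class = "ring_profile_set"
  )
}

#' @export
print.ring_profile_set <- function(x, ...) {
  cat(sprintf(
    "<ring_profile_set> ring of %d | rate %.4g | mean input %.4g | max |hhat| (non-zero modes) %.4g\n",
    x$n, x$rate, x$mean_input, x$hhat_max
  ))
  invisible(x)
}

#' @describeIn distance_correlation_analytic Long tibble of per-order and
#'   total analytic curves.
#' @param x A `ring_profile_set`.
#' @param ... Unused.
#' @export
tidy.ring_profile_set <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$orders, component = paste0("order_", .data$order)),
    dplyr::mutate(x$total, order = NA_integer_, component = "total")
  ) |>
    dplyr::select("component", "order", "offset", "distance", "value")
}

#' Population variance versus population size
#'
#' Sums the integrated covariance over growing populations: contiguous arcs
#' of the ring (spatially compact populations) or uniformly random subsets.
#' In networks with distance-independent correlations the curve grows
#' quadratically; on rings with local correlations, contiguous populations
#' grow approximately linearly until the population spans the correlated
#' neighbourhood.
#'
#' @param C Integrated covariance matrix, or a [hawkes_network()] (then the
#'   theory covariance is computed with drive `y0`).
#' @param sizes Vector of population sizes.
#' @param contiguous If `TRUE`, populations are contiguous arcs (requires
#'   `positions`); otherwise uniformly random subsets.
#' @param positions Ring coordinates; taken from the network if `C` is a
#'   `hawkes_network`.  Defaults to node order if `NULL` and `contiguous`.
#' @param n_rep Number of starting points / subsets averaged per size.
#' @param y0 Drive used when `C` is a network.
#' @param seed Seed for the subset/arc sampling.
#' @return A tibble: `size`, `variance` (mean over replicates), `se`.
#' @export
variance_vs_population_size <- function(C, sizes, contiguous = TRUE,
                                        positions = NULL, n_rep = 5,
                                        y0 = 1, seed = NULL) {
  if (inherits(C, "hawkes_network")) {
    if (is.null(positions)) positions <- C$positions
    C <- integrated_covariance(C, y0 = y0)
  }
  C <- as.matrix(C)
  n <- nrow(C)
  if (any(sizes < 1 | sizes > n)) {
    abort("`sizes` must lie in 1..n.", class = "hawkesnet_parameter_error")
  }
  if (contiguous) {
    if (is.null(positions)) positions <- 0:(n - 1)
    ord <- order(positions)
  }
  with_seed_if(seed, {
    res <- purrr::map_dfr(sizes, function(sz) {
      v <- vapply(seq_len(n_rep), function(r) {
        members <- if (contiguous) {
          start <- sample.int(n, 1) - 1L
          ord[(start + 0:(sz - 1L)) %% n + 1L]
        } else {
          sample.int(n, sz)
        }
        population_variance(C, members)
      }, numeric(1))
      tibble(size = sz, variance = mean(v), se = sd(v) / sqrt(n_rep))
    })
    res
  })
}

#' Log-log slope of a variance-size curve
#'
#' Least-squares slope of `log(variance)` on `log(size)`; close to 2 for
#' distance-independent correlations and close to 1 for contiguous
#' populations on locally correlated rings.
#'
#' @param curve A tibble from [variance_vs_population_size()].
#' @return The fitted slope.
#' @export
loglog_slope <- function(curve) {
  stopifnot(all(c("size", "variance") %in% names(curve)))
  unname(coef(lm(log(variance) ~ log(size), data = curve))[2])
}
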