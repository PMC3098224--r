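#' Closed-form average correlation of a homogeneous random network
#'
#' For a network with uniform connection probability `p` between all nodes,
#' `n_exc` excitatory sources of weight `w_exc` and `n_inh` inhibitory
#' sources of weight `w_inh`, the average correlation is determined by two
#' numbers only: the average direct interaction between two nodes
#' \eqn{\bar g = p (N_E w_E + N_I w_I)/N} and the average common input
#' shared by two nodes \eqn{\bar q = p^2 (N_E w_E^2 + N_I w_I^2)}.  With
#' \eqn{\Gamma = N \bar g} (the mean total input of a node) and homogeneous
#' rate \eqn{y = y_0/(1-\Gamma)}, the contribution of all paths of total
#' length `k` is
#' \deqn{A_k = y\left[\,2\bar g\,\Gamma^{k-1} + (k-1)\,\bar q\,\Gamma^{k-2}\right]}
#' (chain part and common-input part), and the average correlation is the
#' geometric sum
#' \deqn{\bar c = y\left[\frac{2\bar g}{1-\Gamma} + \frac{\bar q}{(1-\Gamma)^2}\right].}
#' The expression is exact for regular (fixed-degree) networks and a good
#' approximation for independent-Bernoulli networks, improving with size.
#'
#' @param n,n_exc,n_inh Total, excitatory and inhibitory node counts.
#' @param p Uniform connection probability.
#' @param w_exc,w_inh Integrated weights (excitatory `>= 0`, inhibitory `<= 0`).
#' @param y0 External drive (defaults to 1, normalised).
#' @param max_order Number of per-order contributions to tabulate.
#' @return An object of class `closed_form_correlation`: a list with
#'   `avg_correlation`, `rate`, `g_bar`, `q_bar`, `gamma` (mean total input)
#'   and a tibble `contributions` (`order`, `chain`, `common_input`,
#'   `total`, `cumulative`).
#' @section Errors: `|Gamma| >= 1` makes the series diverge and raises an
#'   error of class `"hawkesnet_divergence_error"`.
#' @examples
#' cf <- avg_correlation_closed_form(1000, 800, 200, 0.1, 0.035, -0.175)
#' cf$avg_correlation
#' @export
avg_correlation_closed_form <- function(n, n_exc, n_inh, p, w_exc, w_inh,
                                        y0 = 1, max_order = 30) {
  check_scalar(n, "n", lower = 1)
  check_prob(p, "p")
  stopifnot(n_exc + n_inh == n)
  g_bar <- p * (n_exc * w_exc + n_inh * w_inh) / n
  q_bar <- p^2 * (n_exc * w_exc^2 + n_inh * w_inh^2)
  gamma <- n * g_bar
  if (abs(gamma) >= 1) {
    abort(
      sprintf("Mean total input Gamma = %.4g has |Gamma| >= 1: the homogeneous series diverges.", gamma),
      class = "hawkesnet_divergence_error"
    )
  }
  y <- y0 / (1 - gamma)
  k <- seq_len(max_order)
  chain <- 2 * y * g_bar * gamma^(k - 1)
  common <- y * (k - 1) * q_bar * ifelse(k >= 2, gamma^(k - 2), 0)
  contributions <- tibble(
    order = k, chain = chain, common_input = common,
    total = chain + common, cumulative = cumsum(chain + common)
  )
  structure(
    list(
      avg_correlation = y * (2 * g_bar / (1 - gamma) + q_bar / (1 - gamma)^2),
      rate = y, g_bar = g_bar, q_bar = q_bar, gamma = gamma,
      contributions = contributions
    ),
    class = "closed_form_correlation"
  )
}

#' @export
print.closed_form_correlation <- function(x, ...) {
  cat(sprintf(
    "<closed_form_correlation> g_bar %.4g, q_bar %.4g, Gamma %.4g | rate %.4g | avg correlation %.6g\n",
    x$g_bar, x$q_bar, x$gamma, x$rate, x$avg_correlation
  ))
  invisible(x)
}

#' @describeIn avg_correlation_closed_form Per-order contributions as a tibble.
#' @param x A `closed_form_correlation` object.
#' @param ... Unused.
#' @export
tidy.closed_form_correlation <- function(x, ...) x$contributions

#' @describeIn avg_correlation_closed_form One-row summary tibble.
#' @export
glance.closed_form_correlation <- function(x, ...) {
  tibble(
    avg_correlation = x$avg_correlation, rate = x$rate,
    g_bar = x$g_bar, q_bar = x$q_bar, gamma = x$gamma
  )
}
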