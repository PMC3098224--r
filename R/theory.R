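# Closed-form equilibrium rates and integrated covariances of the linear
# point-process (Hawkes) model, and the motif power-series decomposition.

solve_ImG <- function(G, b) {
  n <- nrow(G)
  out <- tryCatch(
    solve(diag(n) - G, b),
    error = function(e) {
      ev <- eigen(G, only.values = TRUE)$values
      abort(
        sprintf(
          "(I - G) is singular or near-singular: max |eigenvalue| = %.4g, max real part = %.4g. The network has no stable linear equilibrium.",
          max(Mod(ev)), max(Re(ev))
        ),
        class = "hawkesnet_linalg_error", parent = e
      )
    }
  )
  out
}

#' Equilibrium firing rates
#'
#' Stationary rates of the linear point-process model,
#' \eqn{y = (I - G)^{-1} y_0}: the external drive amplified through all
#' recurrent feedback loops.  Components can come out negative in strongly
#' inhibitory networks; the linear theory is then used as-is (rectification
#' is left to the simulator) and a warning is emitted.
#'
#' @param net A [hawkes_network()] or a square matrix of integrated weights.
#' @param y0 External drive per node (spikes/s); scalar or length-n vector.
#'   Defaults to 1 (normalised drive), so rates are in units of the drive.
#' @return Numeric vector of equilibrium rates.
#' @examples
#' G <- matrix(c(0, 0.5, 0, 0), 2, 2) # edge 1 -> 2 with weight 0.5
#' equilibrium_rates(G) # c(1, 1.5)
#' @export
equilibrium_rates <- function(net, y0 = 1) {
  G <- as_G(net)
  n <- nrow(G)
  if (any(y0 < 0)) {
    abort("`y0` must be non-negative.", class = "hawkesnet_parameter_error")
  }
  y0 <- rep_len(y0, n)
  y <- as.numeric(solve_ImG(G, y0))
  if (any(y < 0)) {
    warn(sprintf(
      "%d of %d predicted rates are negative; the linear prediction ignores rectification and is unreliable for those nodes.",
      sum(y < 0), n
    ))
  }
  y
}

#' Integrated covariance matrix
#'
#' The matrix of time-integrated spike-train covariance densities,
#' \eqn{C = (I-G)^{-1}\, \mathrm{diag}(y)\, (I-G^\top)^{-1}}: equal to the
#' large-window limit of spike-count covariances per unit time.  Symmetric by
#' construction, and positive semidefinite whenever all rates are
#' non-negative.  The diagonal includes the Poisson rate term of the
#' autocovariances.
#'
#' @inheritParams equilibrium_rates
#' @param rates Equilibrium rates; computed from `y0` when `NULL`.
#' @return Dense `n x n` covariance matrix (spikes^2/s).
#' @examples
#' G <- matrix(c(0, 0.5, 0, 0), 2, 2)
#' integrated_covariance(G) # [[1, .5], [.5, 1.75]]
#' @export
integrated_covariance <- function(net, rates = NULL, y0 = 1) {
  G <- as_G(net)
  n <- nrow(G)
  if (is.null(rates)) {
    rates <- equilibrium_rates(G, y0)
  }
  stopifnot(length(rates) == n)
  A <- solve_ImG(G, diag(n))
  C <- A %*% (rates * t(A))
  (C + t(C)) / 2
}

#' Average pairwise correlation of a network
#'
#' The mean over all \eqn{N^2} ordered node pairs of the integrated
#' covariances with the Poisson rate term of the autocovariances removed:
#' \eqn{\bar c = (\sum_{ij} C_{ij} - \sum_i y_i) / N^2}.  Computed from two
#' linear solves, without forming the full covariance matrix, so it scales to
#' the network sizes used in the architecture comparisons.
#'
#' @inheritParams equilibrium_rates
#' @return A single number.
#' @export
average_correlation <- function(net, y0 = 1) {
  G <- as_G(net)
  n <- nrow(G)
  y <- as.numeric(solve_ImG(G, rep_len(y0, n)))
  r <- as.numeric(solve_ImG(t(G), rep(1, n))) # column sums of (I-G)^{-1}
  (sum(r^2 * y) - sum(y)) / n^2
}

#' Full theory summary for a network
#'
#' Convenience wrapper computing the equilibrium rates, the integrated
#' covariance matrix, the average correlation and the population count
#' variance in one pass.
#'
#' @inheritParams equilibrium_rates
#' @return An object of class `hawkes_theory`: a list with elements `rates`,
#'   `covariance`, `avg_correlation`, `population_variance`, `n`, `y0`.
#' @export
hawkes_theory <- function(net, y0 = 1) {
  G <- as_G(net)
  n <- nrow(G)
  rates <- equilibrium_rates(G, y0)
  C <- integrated_covariance(G, rates = rates)
  structure(
    list(
      rates = rates, covariance = C,
      avg_correlation = (sum(C) - sum(rates)) / n^2,
      population_variance = sum(C),
      n = n, y0 = y0
    ),
    class = "hawkes_theory"
  )
}

#' @export
print.hawkes_theory <- function(x, ...) {
  cat(sprintf(
    "<hawkes_theory> %d nodes | mean rate %.4g | average correlation %.4g | population variance %.4g\n",
    x$n, mean(x$rates), x$avg_correlation, x$population_variance
  ))
  invisible(x)
}

#' @describeIn hawkes_theory Per-node tibble: `neuron`, `rate`,
#'   `autocovariance` (diagonal of the integrated covariance).
#' @param x A `hawkes_theory` object.
#' @param ... Unused.
#' @export
tidy.hawkes_theory <- function(x, ...) {
  tibble(
    neuron = seq_len(x$n),
    rate = x$rates,
    autocovariance = diag(x$covariance)
  )
}

#' @describeIn hawkes_theory One-row summary tibble.
#' @export
glance.hawkes_theory <- function(x, ...) {
  tibble(
    n_nodes = x$n,
    mean_rate = mean(x$rates),
    n_negative_rates = sum(x$rates < 0),
    avg_correlation = x$avg_correlation,
    population_variance = x$population_variance
  )
}

#' Population spike-count variance
#'
#' Variance of the pooled spike count of a population, normalised by the bin
#' size (valid in the large-bin limit): the sum of the integrated covariance
#' matrix over the members-by-members submatrix.  For the full population it
#' equals the total sum of `C`.
#'
#' @param C Integrated covariance matrix (from [integrated_covariance()]).
#' @param members Node indices of the population; defaults to all nodes.
#' @return A single number (spikes^2/s).
#' @export
population_variance <- function(C, members = NULL) {
  C <- as.matrix(C)
  if (is.null(members)) members <- seq_len(nrow(C))
  if (length(members) == 0) {
    abort("`members` must contain at least one node.", class = "hawkesnet_parameter_error")
  }
  if (any(members < 1 | members > nrow(C))) {
    abort("`members` out of range.", class = "hawkesnet_parameter_error")
  }
  sum(C[members, members, drop = FALSE])
}

# ---- motif power series ------------------------------------------------

check_convergent <- function(G) {
  ev <- eigen(G, only.values = TRUE)$values
  rho <- max(Mod(ev))
  if (rho >= 1) {
    k <- which.max(Mod(ev))
    abort(
      sprintf(
        "The covariance power series diverges: spectral radius %.4g >= 1 (offending eigenvalue %.4g%+.4gi).",
        rho, Re(ev[k]), Im(ev[k])
      ),
      class = "hawkesnet_divergence_error"
    )
  }
  ev
}

#' Motif decomposition of the integrated covariance
#'
#' Expands \eqn{C = \sum_{n,m \ge 0} G^n\,\mathrm{diag}(y)\,(G^\top)^m} and
#' returns one row per `(n, m)` term with `n + m <= max_order`.  The `(n, m)`
#' term sums all two-branch motifs in which a source node reaches node `i`
#' along a path of length `n` and node `j` along a path of length `m`,
#' weighted by edge weights and the source rate.  Terms are classified as
#' `"rate"` (`n = m = 0`, the Poisson autocovariance), `"chain"` (one branch
#' empty: direct or indirect input of one node to the other), or
#' `"common_input"` (both branches non-empty: a shared, possibly indirect,
#' source).
#'
#' The series converges iff the spectral radius of `G` is below 1; otherwise
#' an error names the offending eigenvalue.
#'
#' @inheritParams equilibrium_rates
#' @param max_order Largest total order `n + m` to return.
#' @param keep_matrices If `TRUE`, attach the full `n x n` matrix of each
#'   term as a list column `term` (memory grows as `max_order^2 * n^2`).
#' @return A tibble with columns `n`, `m`, `order`, `kind`, `avg` (mean of
#'   the term over all `N^2` node pairs) and optionally `term`.  Attributes:
#'   `rates`, `spectral_radius`, `n_nodes`.
#' @examples
#' net <- make_random_network(50, 0.1, 0.02, -0.1, seed = 1)
#' terms <- motif_terms(net, max_order = 4)
#' average_contributions(terms)
#' @export
motif_terms <- function(net, y0 = 1, max_order = 8, keep_matrices = FALSE) {
  G <- as_G(net)
  n <- nrow(G)
  check_scalar(max_order, "max_order", lower = 0)
  ev <- check_convergent(G)
  rates <- equilibrium_rates(G, y0)
  K <- as.integer(max_order)
  # u_k = (G^T)^k 1 gives column sums of G^k; avg(n, m) = sum(y u_n u_m)/N^2
  u <- vector("list", K + 1L)
  u[[1]] <- rep(1, n)
  if (K >= 1) {
    tG <- t(G)
    for (k in seq_len(K)) u[[k + 1]] <- as.numeric(tG %*% u[[k]])
  }
  if (keep_matrices) {
    Gp <- vector("list", K + 1L) # G^k
    Gp[[1]] <- diag(n)
    if (K >= 1) for (k in seq_len(K)) Gp[[k + 1]] <- G %*% Gp[[k]]
  }
  grid <- expand.grid(n = 0:K, m = 0:K)
  grid <- grid[grid$n + grid$m <= K, , drop = FALSE]
  avg_vals <- purrr::map2_dbl(
    grid$n, grid$m,
    function(a, b) sum(rates * u[[a + 1]] * u[[b + 1]]) / n^2
  )
  out <- tibble(
    n = as.integer(grid$n), m = as.integer(grid$m),
    order = as.integer(grid$n + grid$m),
    kind = dplyr::case_when(
      grid$n == 0 & grid$m == 0 ~ "rate",
      grid$n == 0 | grid$m == 0 ~ "chain",
      TRUE ~ "common_input"
    ),
    avg = avg_vals
  )
  if (keep_matrices) {
    out$term <- purrr::map2(
      out$n, out$m,
      function(a, b) Gp[[a + 1]] %*% (rates * t(Gp[[b + 1]]))
    )
  }
  out <- dplyr::arrange(out, .data$order, .data$n)
  attr(out, "rates") <- rates
  attr(out, "spectral_radius") <- max(Mod(ev))
  attr(out, "n_nodes") <- n
  out
}

#' Per-order average contributions to the mean correlation
#'
#' Aggregates the motif terms of [motif_terms()] by total order `k = n + m`
#' and splits each order into its chain and common-input parts.  The
#' cumulative sum over orders `k >= 1` converges to the average correlation
#' of the network; the rate term (`k = 0`) is reported separately and is not
#' part of the average correlation.
#'
#' @param terms A tibble from [motif_terms()].
#' @return A tibble with one row per order `k >= 1`: `order`, `chain`,
#'   `common_input`, `total`, `cumulative`.  Attribute `rate_term` holds the
#'   order-0 average; attribute `avg_correlation_estimate` the summed total.
#' @export
average_contributions <- function(terms) {
  stopifnot(is.data.frame(terms), all(c("order", "kind", "avg") %in% names(terms)))
  out <- terms |>
    dplyr::filter(.data$order >= 1) |>
    dplyr::group_by(.data$order) |>
    dplyr::summarise(
      chain = sum(.data$avg[.data$kind == "chain"]),
      common_input = sum(.data$avg[.data$kind == "common_input"]),
      total = sum(.data$avg),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$order) |>
    dplyr::mutate(cumulative = cumsum(.data$total))
  attr(out, "rate_term") <- sum(terms$avg[terms$order == 0])
  attr(out, "avg_correlation_estimate") <- sum(out$total)
  out
}

#' Order-truncated covariance series
#'
#' Partial sum \eqn{\sum_{n+m \le K} G^n \mathrm{diag}(y) (G^\top)^m} of the
#' motif series, which converges to [integrated_covariance()] as `K` grows
#' whenever the spectral radius of `G` is below 1.  The truncation error is
#' certified by [series_tail_bound()].
#'
#' @inheritParams motif_terms
#' @return Dense `n x n` matrix: the truncated covariance.
#' @export
motif_series_sum <- function(net, y0 = 1, max_order = 8) {
  G <- as_G(net)
  check_convergent(G)
  rates <- equilibrium_rates(G, y0)
  K <- as.integer(max_order)
  # U_k = sum_{n+m=k} G^n Y G^T^m obeys U_k = G U_{k-1} + Y (G^T)^k
  tG <- t(G)
  Vk <- rates * diag(nrow(G)) # Y (G^T)^k, updated in place
  Uk <- Vk
  S <- Uk
  if (K >= 1) {
    for (k in seq_len(K)) {
      Vk <- Vk %*% tG
      Uk <- G %*% Uk + Vk
      S <- S + Uk
    }
  }
  unname(as.matrix(S))
}

#' Geometric tail bound for the truncated motif series
#'
#' Bound on the norm of the dropped terms of the covariance series:
#' \eqn{\|C - \sum_{n+m\le K}\| \le \|Y\| \sum_{k>K} (k+1)\rho^k}
#' with \eqn{\rho} a norm of `G` below 1.  The closed form of the tail is
#' \eqn{\rho^{K+1}\,[(K+2)(1-\rho) + \rho]/(1-\rho)^2}.  Used with the
#' spectral (operator 2-) norm of `G` as a certificate; the convergence
#' check itself uses exact eigenvalues.
#'
#' @param rho Norm of `G` in `[0, 1)`.
#' @param max_order Truncation order `K`.
#' @param norm_Y Norm of the rate matrix (max rate); defaults to 1.
#' @return Upper bound on the norm of the truncation error.
#' @export
series_tail_bound <- function(rho, max_order, norm_Y = 1) {
  check_scalar(rho, "rho", lower = 0)
  if (rho >= 1) {
    abort("Tail bound requires rho < 1.", class = "hawkesnet_divergence_error")
  }
  K <- max_order
  norm_Y * rho^(K + 1) * ((K + 2) * (1 - rho) + rho) / (1 - rho)^2
}

#' Smallest truncation order meeting a tail tolerance
#'
#' @param rho Norm of `G` in `[0, 1)`.
#' @param tol Required bound on the relative tail (in units of `norm_Y`).
#' @return Integer order `K` with `series_tail_bound(rho, K) < tol`.
#' @export
choose_truncation_order <- function(rho, tol = 1e-6) {
  if (rho <= 0) return(0L)
  K <- 0L
  while (series_tail_bound(rho, K) >= tol) {
    K <- K + 1L
    if (K > 100000L) {
      abort("Tolerance unreachable: rho too close to 1.",
        class = "hawkesnet_divergence_error"
      )
    }
  }
  K
}
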