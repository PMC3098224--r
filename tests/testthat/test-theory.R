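# Equilibrium rates, integrated covariance, and the motif power series.
# Expected values for the small examples were derived by solving the 2x2 /
# scalar linear systems by hand (see comments in each block).

test_that("rates and covariance reduce to known closed forms on tiny systems", {
  # no recurrence: rates = drive, C = diag(rates) (independent Poisson)
  G0 <- matrix(0, 2, 2)
  expect_equal(equilibrium_rates(G0, y0 = c(1, 1)), c(1, 1))
  expect_equal(integrated_covariance(G0, rates = c(3, 4)), diag(c(3, 4)))

  # single edge 1 -> 2, weight 0.5:
  # y = (I-G)^{-1} (1,1) = (1, 1.5);
  # C = (I-G)^{-1} Y (I-G^T)^{-1} = [[1, 0.5], [0.5, 1.75]]
  G <- matrix(c(0, 0.5, 0, 0), 2, 2)
  expect_equal(equilibrium_rates(G), c(1, 1.5))
  expect_equal(integrated_covariance(G), matrix(c(1, 0.5, 0.5, 1.75), 2, 2))

  # self-exciting node, g = 0.5: y = 1/(1-g) = 2, C = y/(1-g)^2 = 8
  g <- matrix(0.5, 1, 1)
  expect_equal(equilibrium_rates(g), 2)
  expect_equal(integrated_covariance(g)[1, 1], 8)
  # truncated series n+m <= 4: 2 * sum_{k<=4} (k+1) 0.5^k = 7.125
  expect_equal(sum(motif_series_sum(g, max_order = 4)), 7.125)
})

test_that("negative predicted rates warn; singular systems raise a diagnostic", {
  G <- matrix(c(0, -2, 0, 0), 2, 2) # strong inhibition drives node 2 negative
  expect_warning(equilibrium_rates(G), "negative")
  G1 <- matrix(1, 1, 1) # eigenvalue exactly 1
  expect_error(equilibrium_rates(G1), class = "hawkesnet_linalg_error")
})

test_that("motif terms: classification, transpose symmetry, divergence guard", {
  net <- generator_zoo(1)$bernoulli
  terms <- motif_terms(net, max_order = 4, keep_matrices = TRUE)
  expect_setequal(unique(terms$kind[terms$order == 0]), "rate")
  expect_setequal(unique(terms$kind[terms$n == 0 & terms$m > 0]), "chain")
  expect_setequal(unique(terms$kind[terms$n > 0 & terms$m > 0]), "common_input")
  # (n, m) term is exactly the transpose of the (m, n) term
  for (k in seq_len(nrow(terms))) {
    mirror <- which(terms$n == terms$m[k] & terms$m == terms$n[k])
    expect_equal(terms$term[[k]], t(terms$term[[mirror]]))
    expect_equal(terms$avg[k], terms$avg[mirror])
  }
  # K = 0 keeps only the Poisson rate term
  t0 <- motif_terms(net, max_order = 0)
  expect_equal(nrow(t0), 1L)
  expect_equal(t0$avg, mean(attr(t0, "rates")) / net$n)

  # divergent network refused, naming the offending eigenvalue
  bad <- hawkes_network(matrix(c(0, 1.2, 1.2, 0), 2, 2), c("E", "E"))
  expect_error(motif_terms(bad, max_order = 2), "eigenvalue",
    class = "hawkesnet_divergence_error"
  )
})

test_that("truncated series converges monotonically to the inverse formula", {
  for (net in generator_zoo(3, n = 100)[c("bernoulli", "ring", "hub")]) {
    C <- integrated_covariance(net)
    errs <- vapply(c(2, 6, 12, 24), function(K) {
      max(abs(motif_series_sum(net, max_order = K) - C))
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
    # error certified by the operator-norm tail bound
    rho <- norm(as.matrix(net$G), type = "2")
    y <- equilibrium_rates(net)
    for (K in c(6, 12)) {
      err <- max(abs(motif_series_sum(net, max_order = K) - C))
      expect_lt(err, series_tail_bound(rho, K, norm_Y = max(abs(y))))
    }
  }
})

test_that("covariance is symmetric positive semidefinite for stable networks", {
  for (seed in 1:4) {
    for (net in generator_zoo(seed, n = 80)[c("bernoulli", "regular", "ring", "patchy", "hub")]) {
      C <- integrated_covariance(net)
      expect_equal(C, t(C))
      y <- suppressWarnings(equilibrium_rates(net))
      if (all(y >= 0)) {
        expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
      }
    }
  }
})

test_that("per-order averages sum to the average correlation within the tail bound", {
  net <- generator_zoo(2, n = 120)$fixed_deg
  K <- 40
  contribs <- average_contributions(motif_terms(net, max_order = K))
  cbar <- average_correlation(net)
  rho <- norm(as.matrix(net$G), type = "2")
  y <- suppressWarnings(equilibrium_rates(net))
  bound <- series_tail_bound(rho, K, norm_Y = max(abs(y)))
  expect_lt(abs(sum(contribs$total) - cbar), bound)
  # G = 0 network: all contributions vanish
  z <- hawkes_network(matrix(0, 10, 10), rep("E", 10))
  cz <- average_contributions(motif_terms(z, max_order = 3))
  expect_true(all(cz$total == 0))
})

test_that("closed form matches the doubly regular network and scales with drive", {
  cf0 <- avg_correlation_closed_form(100, 80, 20, 0.1, 0, 0)
  expect_equal(cf0$avg_correlation, 0)

  n <- 500
  cf <- avg_correlation_closed_form(n, 400, 100, 0.1, 0.02, -0.08)
  net <- make_regular_network(n, 0.1, 0.02, -0.08, seed = 9)
  expect_equal(average_correlation(net), cf$avg_correlation, tolerance = 1e-10)
  # per-order contributions match the full-matrix averages on the regular net
  ac <- average_contributions(motif_terms(net, max_order = 6))
  expect_equal(ac$total, cf$contributions$total[1:6], tolerance = 1e-8)
  # linear scaling with the external drive
  cf2 <- avg_correlation_closed_form(n, 400, 100, 0.1, 0.02, -0.08, y0 = 3)
  expect_equal(cf2$avg_correlation, 3 * cf$avg_correlation)
  # divergent regime refused
  expect_error(
    avg_correlation_closed_form(1000, 800, 200, 0.5, 0.05, 0),
    class = "hawkesnet_divergence_error"
  )
})

test_that("population variance: definition, Poisson limit, subset validation", {
  net <- generator_zoo(1, n = 60)$bernoulli
  th <- hawkes_theory(net)
  expect_equal(population_variance(th$covariance), sum(th$covariance))
  # Eq.-(19)-style identity: v = sum(rates) + N^2 cbar
  expect_equal(
    th$population_variance,
    sum(th$rates) + net$n^2 * th$avg_correlation
  )
  # independent Poisson: v = sum of rates
  z <- hawkes_theory(hawkes_network(matrix(0, 10, 10), rep("E", 10)), y0 = 4)
  expect_equal(z$population_variance, sum(z$rates))
  expect_equal(population_variance(th$covariance, members = 2:5),
    sum(th$covariance[2:5, 2:5]))
  expect_error(population_variance(th$covariance, members = integer(0)),
    class = "hawkesnet_parameter_error"
  )
  expect_error(population_variance(th$covariance, members = c(1, 99)),
    class = "hawkesnet_parameter_error"
  )
})

test_that("tidiers expose rates, autocovariances and summaries", {
  net <- generator_zoo(1, n = 50)$bernoulli
  th <- hawkes_theory(net)
  td <- tidy(th)
  expect_named(td, c("neuron", "rate", "autocovariance"))
  expect_equal(td$rate, th$rates)
  gl <- glance(th)
  expect_equal(gl$avg_correlation, th$avg_correlation)
  expect_equal(glance(net)$n_nodes, 50)
})
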