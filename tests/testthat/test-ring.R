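# Distance-dependent correlation analytics on rings.

test_that("numeric distance correlation: definition and exchangeability", {
  n <- 300
  net <- make_random_network(n, 0.1, 0.01, -0.04, seed = 11)
  C <- integrated_covariance(net)
  dc <- distance_correlation(C, positions = 0:(n - 1))
  # offset 0 is the mean autocovariance
  expect_equal(dc$value[dc$offset == 0], mean(diag(C)))
  expect_equal(nrow(dc), n)
  # a random network has no distance structure: both halves of the offsets
  # have the same mean within sampling error
  v <- dc$value[dc$offset != 0]
  near <- v[abs(dc$offset[dc$offset != 0]) <= n / 4]
  far <- v[abs(dc$offset[dc$offset != 0]) > n / 4]
  se <- sqrt(var(near) / length(near) + var(far) / length(far))
  expect_lt(abs(mean(near) - mean(far)), 4 * se)
  expect_error(distance_correlation(C, positions = rep(0, n)),
    class = "hawkesnet_parameter_error"
  )
})

test_that("uniform profile reproduces the homogeneous closed form", {
  n <- 1000
  w_exc <- 0.01
  w_inh <- -0.05
  an <- distance_correlation_analytic(
    n, ring_profile(n / 2, 0.1), ring_profile(n / 2, 0.1), w_exc, w_inh,
    max_order = 6
  )
  cf <- avg_correlation_closed_form(n, 800, 200, 0.1, w_exc, w_inh)
  # Parseval: summed analytic curve minus the rate term = N * cbar
  expect_equal((sum(an$total$value) - an$rate) / n, cf$avg_correlation,
    tolerance = 0.01
  )
  expect_equal(an$rate, cf$rate, tolerance = 0.01)
  # flat off-offset profile
  off <- an$total$value[an$total$offset != 0]
  expect_lt(diff(range(off)) / abs(mean(off)), 0.05)
})

test_that("average correlation is profile-shape invariant at fixed connectivity", {
  cbar_of <- function(ps) (sum(ps$total$value) - ps$rate) / ps$n
  u <- distance_correlation_analytic(
    1000, ring_profile(500, 0.1), ring_profile(500, 0.1), 0.01, -0.05
  )
  hat <- distance_correlation_analytic(
    1000, ring_profile(100, 0.5), ring_profile(500, 0.1), 0.01, -0.05
  )
  inv <- distance_correlation_analytic(
    1000, ring_profile(500, 0.1), ring_profile(100, 0.5), 0.01, -0.05
  )
  expect_equal(cbar_of(hat), cbar_of(u), tolerance = 0.02)
  expect_equal(cbar_of(inv), cbar_of(u), tolerance = 0.02)
})

test_that("order decomposition sums to the closed-form total", {
  ps <- distance_correlation_analytic(
    400, ring_profile(40, 0.5), ring_profile(200, 0.1), 0.01, -0.05,
    max_order = 60
  )
  partial <- stats::aggregate(value ~ offset, data = ps$orders, FUN = sum)
  partial <- partial[order(partial$offset), ]
  total <- ps$total[order(ps$total$offset), ]
  # remove the order-0 rate contribution at offset 0
  tot <- total$value
  tot[total$offset == 0] <- tot[total$offset == 0] - ps$rate
  expect_lt(max(abs(partial$value - tot)), ps$rate * ps$hhat_max^59 + 1e-12)
})

test_that("oscillatory eigenmodes beyond unit gain are refused", {
  expect_error(
    distance_correlation_analytic(
      1000, ring_profile(100, 1), ring_profile(500, 0.2), 0.05, -0.25
    ),
    "mode",
    class = "hawkesnet_divergence_error"
  )
})

test_that("hat orders reinforce at short range; inverted-hat orders alternate", {
  hat <- ring_analytic("hat", max_order = 4)
  inv <- ring_analytic("inverted", max_order = 4)
  near <- function(ps, k) {
    with(ps$orders, value[order == k & abs(offset) <= 20 & offset != 0])
  }
  hat_signs <- sapply(1:4, function(k) sign(mean(near(hat, k))))
  inv_signs <- sapply(1:4, function(k) sign(mean(near(inv, k))))
  expect_true(all(hat_signs[2:4] == hat_signs[1]))
  expect_true(all(inv_signs == c(-1, 1, -1, 1)))
})

test_that("population variance curve: totals and degenerate sizes", {
  n <- 200
  net <- make_ring_network(n, ring_profile(10, 0.5), ring_profile(100, 0.1),
    0.02, -0.1,
    seed = 13
  )
  C <- integrated_covariance(net)
  v_full_arc <- variance_vs_population_size(C, n,
    contiguous = TRUE,
    positions = net$positions, n_rep = 2, seed = 1
  )
  v_full_rand <- variance_vs_population_size(C, n,
    contiguous = FALSE, n_rep = 2, seed = 2
  )
  expect_equal(v_full_arc$variance, sum(C))
  expect_equal(v_full_rand$variance, sum(C))
  expect_error(variance_vs_population_size(C, 0),
    class = "hawkesnet_parameter_error"
  )
  # network input works directly and uses its own positions
  v_net <- variance_vs_population_size(net, c(10, 50), n_rep = 3, seed = 3)
  expect_named(v_net, c("size", "variance", "se"))
  expect_true(all(v_net$variance > 0))
})
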