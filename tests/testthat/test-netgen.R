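# Network generators: reproducibility, structural invariants, and the
# statistics each construction promises.

test_that("all generators are reproducible and respect structural invariants", {
  for (seed in c(1, 2)) {
    z1 <- generator_zoo(seed)
    z2 <- generator_zoo(seed)
    for (nm in names(z1)) {
      net <- z1[[nm]]
      expect_identical(as.matrix(net$G), as.matrix(z2[[nm]]$G), label = nm)
      # no self-connections
      expect_true(all(Matrix::diag(net$G) == 0), label = nm)
      # column sign discipline: one sign per presynaptic neuron
      tl <- tidy(net)
      expect_true(all(tl$weight[tl$source_type == "E"] > 0), label = nm)
      expect_true(all(tl$weight[tl$source_type == "I"] < 0), label = nm)
      # no multi-edges by construction of the sparse matrix
      expect_true(all(!duplicated(tl[, c("source", "target")])), label = nm)
    }
  }
})

test_that("random generator: empty graph, exact fixed out-degree, binomial mean", {
  expect_equal(length(make_random_network(100, 0, 0.02, -0.1, seed = 1)$G@x), 0)

  net <- make_random_network(100, 0.1, 0.02, -0.1, fixed_out_degree = TRUE, seed = 1)
  expect_true(all(Matrix::colSums(net$G != 0) == 10)) # round(0.1 * 99)

  # Bernoulli variant: mean out-degree over seeds within 3 SE of (N-1) p
  n <- 1000
  p <- 0.1
  n_seeds <- 25
  deg <- unlist(lapply(seq_len(n_seeds), function(s) {
    Matrix::colSums(make_random_network(n, p, 0.01, -0.04, seed = s)$G != 0)
  }))
  se <- sqrt((n - 1) * p * (1 - p) / length(deg))
  expect_lt(abs(mean(deg) - (n - 1) * p), 3 * se)
})

test_that("regular generator gives exact per-type in- and out-degrees", {
  net <- make_regular_network(500, 0.1, 0.02, -0.08, seed = 3)
  expect_true(all(Matrix::colSums(net$G != 0) == 50))
  expect_true(all(Matrix::rowSums(net$G != 0) == 50))
  # per-type blocks: every node sends round(p * n_Y) edges to type Y
  tl <- tidy(net)
  to_inh <- table(factor(tl$source[tl$target_type == "I"], levels = 1:500))
  expect_true(all(to_inh == 10))
  expect_error(
    make_regular_network(503, 0.1, 0.02, -0.08, seed = 1),
    class = "hawkesnet_parameter_error"
  )
})

test_that("ring generator respects the boxcar range and overall connectivity", {
  net <- make_ring_network(400, ring_profile(5, 0.8), ring_profile(100, 0.2),
    0.02, -0.08,
    seed = 4
  )
  tl <- tidy(net)
  d0 <- abs(tl$source - tl$target)
  d <- pmin(d0, 400 - d0)
  expect_true(all(d[tl$source_type == "E"] <= 5))
  expect_true(all(d[tl$source_type == "I"] <= 100))
  expect_true(all(d >= 1))
  expect_error(
    make_ring_network(100, ring_profile(60, 0.5), ring_profile(10, 0.5), 0.02, -0.08),
    class = "hawkesnet_parameter_error"
  )

  # per-type total connectivity p_box * 2 sigma / N held at 0.1 while sigma varies
  n <- 1000
  for (sigma in c(100, 250, 500)) {
    p_box <- 0.1 * n / (2 * sigma)
    dens <- vapply(1:6, function(s) {
      glance(make_ring_network(n, ring_profile(sigma, p_box),
        ring_profile(sigma, p_box), 0.01, -0.04,
        seed = s
      ))$density
    }, numeric(1))
    # binomial SE of the mean empirical density over 6 seeds
    se <- sqrt(0.1 * 0.9 / (n * (n - 1) * 6))
    expect_lt(abs(mean(dens) - 0.1), 4 * se + 0.1 / (n - 1))
  }
})

test_that("uniform ring and full-ring patchy reproduce the random edge density", {
  n <- 600
  d_rand <- vapply(1:8, function(s) {
    glance(make_random_network(n, 0.1, 0.01, -0.04, seed = s))$density
  }, numeric(1))
  d_ring <- vapply(1:8, function(s) {
    glance(make_ring_network(n, ring_profile(n / 2, 0.1), ring_profile(n / 2, 0.1),
      0.01, -0.04,
      seed = 100 + s
    ))$density
  }, numeric(1))
  d_patch <- vapply(1:8, function(s) {
    glance(make_patchy_network(n, n, 0.1, 0.01, -0.04, seed = 200 + s))$density
  }, numeric(1))
  se2 <- sqrt(var(d_rand) / 8 + var(d_ring) / 8)
  expect_lt(abs(mean(d_rand) - mean(d_ring)), 4 * se2)
  se3 <- sqrt(var(d_rand) / 8 + var(d_patch) / 8)
  expect_lt(abs(mean(d_rand) - mean(d_patch)), 4 * se3)
})

test_that("hub generator: geometric degrees, hub wiring, pool fallback", {
  # f = 0: no hub-to-hub excitatory edges
  net0 <- suppressWarnings(make_hub_network(400, 20, 0, 0.01, -0.04, seed = 5))
  hubs <- net0$meta$hubs
  tl <- tidy(net0)
  expect_equal(sum(tl$source %in% hubs & tl$target %in% hubs), 0)

  # geometric out-degree mean within 3 SE (mean mu, variance mu(mu+1))
  mu <- 50
  ks <- unlist(lapply(1:10, function(s) {
    Matrix::colSums(suppressWarnings(make_hub_network(1000, mu, 0.5, 0.005, -0.02, seed = s))$G != 0)
  }))
  se <- sqrt(mu * (mu + 1) / length(ks))
  expect_lt(abs(mean(ks) - mu), 3 * se)

  # hub-to-hub edge count strictly larger for f = 0.9 than f = 0.1, same seed
  for (s in 1:3) {
    hh <- vapply(c(0.1, 0.9), function(f) {
      net <- suppressWarnings(make_hub_network(600, 30, f, 0.005, -0.02, seed = s))
      tl <- tidy(net)
      sum(tl$source %in% net$meta$hubs & tl$target %in% net$meta$hubs)
    }, numeric(1))
    expect_gt(hh[2], hh[1])
  }

  # impossible hub demand falls back with a warning instead of failing
  expect_warning(
    make_hub_network(200, 60, 1, 0.005, -0.02, seed = 1),
    "pool"
  )
})

test_that("patchy generator: targets confined to one patch, density invariant", {
  net <- make_patchy_network(500, 60, 0.5, 0.01, -0.04, seed = 6)
  tl <- tidy(net)
  for (src in unique(tl$source)) {
    tg <- sort((tl$target[tl$source == src] - 1))
    # minimal circular arc covering all targets must fit in the patch
    if (length(tg) >= 2) {
      gaps <- diff(c(tg, tg[1] + 500))
      expect_lte(500 - max(gaps) + 1, 60)
    }
  }
  # expected overall connectivity s * p / n invariant as s varies
  n <- 1000
  for (s_patch in c(125, 250, 500)) {
    pp <- 0.1 * n / s_patch
    dens <- vapply(1:6, function(s) {
      glance(make_patchy_network(n, s_patch, pp, 0.01, -0.04, seed = s))$density
    }, numeric(1))
    se <- sqrt(0.1 * 0.9 / (n * s_patch * 6)) # p_patch Bernoulli per patch slot
    expect_lt(abs(mean(dens) - 0.1), 4 * se + 0.1 / (n - 1))
  }
  # separated types occupy one contiguous block
  net_sep <- make_patchy_network(500, 100, 0.5, 0.01, -0.04,
    separated_types = TRUE, seed = 7
  )
  inh_pos <- sort(which(net_sep$types == "I") - 1)
  gaps <- diff(c(inh_pos, inh_pos[1] + 500))
  expect_equal(500 - max(gaps) + 1, length(inh_pos))
})

test_that("generator metadata records realised counts and expected connectivity", {
  net <- make_patchy_network(400, 100, 0.4, 0.01, -0.04, seed = 8)
  expect_equal(net$meta$expected_connectivity, 100 * 0.4 / 400)
  expect_equal(net$meta$n_exc + net$meta$n_inh, 400)
  expect_equal(net$meta$n_inh, sum(net$types == "I"))
})
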