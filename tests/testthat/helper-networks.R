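# Shared fixtures: small networks spanning every generator, and the frozen
# study conditions used by the architecture experiments.

# Rescale a network's weights so the spectral 2-norm of G hits `target`
# (keeps the E/I weight ratio; used to place test networks safely inside the
# convergence region of the motif series).
scale_to_norm <- function(net, target = 0.7) {
  s <- target / norm(as.matrix(net$G), type = "2")
  net$G <- net$G * s
  net$meta$params$w_exc <- net$meta$params$w_exc * s
  net$meta$params$w_inh <- net$meta$params$w_inh * s
  net
}

# One small network per generator (N <= 160), weights scaled to 2-norm 0.7.
# The regular construction needs divisible per-type degrees, so it uses the
# nearest multiple of 50.
generator_zoo <- function(seed = 1, n = 150, norm_target = 0.7) {
  n_reg <- max(50, 50 * round(n / 50))
  sigma_e <- max(2, round(n / 10))
  nets <- list(
    bernoulli = make_random_network(n, 0.1, 0.02, -0.08, seed = seed),
    fixed_deg = make_random_network(n, 0.1, 0.02, -0.08,
      fixed_out_degree = TRUE, seed = seed + 1
    ),
    regular = make_regular_network(n_reg, 0.1, 0.02, -0.08,
      frac_inhib = 0.2, seed = seed + 2
    ),
    ring = make_ring_network(n, ring_profile(sigma_e, 0.5),
      ring_profile(floor(n / 2), 0.1), 0.02, -0.08,
      seed = seed + 3
    ),
    hub = suppressWarnings(
      make_hub_network(n, mu = 12, f = 0.5, w_exc = 0.02, w_inh = -0.08, seed = seed + 4)
    ),
    patchy = make_patchy_network(n, patch_size = max(5, round(n / 5)), p_patch = 0.5,
      w_exc = 0.02, w_inh = -0.08,
      separated_types = (seed %% 2 == 0), seed = seed + 5
    )
  )
  lapply(nets, scale_to_norm, target = norm_target)
}

# Frozen study conditions for the architecture comparisons (see the methods
# vignette for the reasoning behind each choice).
conditions <- list(
  # asynchronous irregular simulation regime: 80/20, p = 0.1, tau = 10 ms,
  # inhibition dominated (g = 5), bulk radius ~ 0.8, drive 10 spikes/s
  async = list(n = 1000, p = 0.1, w_exc = 0.035, w_inh = -0.175, y0 = 10),
  # weak-fluctuation recovery regime for simulator-vs-theory checks
  recovery = list(n = 200, p = 0.1, w_exc = 0.016, w_inh = -0.072, y0 = 20),
  # balanced sparse net where the regular-graph closed form is valid
  balanced = list(n = 1000, p = 0.1, w_exc = 0.0025, w_inh = -0.01),
  # hub architecture (geometric out-degrees, mean 50)
  hub = list(n = 1000, mu = 50, w_exc = 0.0033, w_inh = -0.0165),
  # patchy architecture at overall connectivity 0.1
  patchy = list(n = 1000, p_total = 0.1, w_exc = 0.01, w_inh = -0.05),
  # ring profiles at per-type connectivity 0.1 (hat / inverted hat)
  ring = list(
    n = 1000, w_exc = 0.01, w_inh = -0.05,
    # weaker weights for the mean-field vs ensemble comparison (validity
    # regime of the expected-profile analytics)
    w_exc_cmp = 0.004, w_inh_cmp = -0.02,
    hat = list(exc = c(100, 0.5), inh = c(500, 0.1)),
    inverted = list(exc = c(500, 0.1), inh = c(100, 0.5))
  )
)

ring_net <- function(profile, seed, w_exc = conditions$ring$w_exc,
                     w_inh = conditions$ring$w_inh) {
  pr <- conditions$ring[[profile]]
  make_ring_network(
    conditions$ring$n,
    ring_profile(pr$exc[1], pr$exc[2]), ring_profile(pr$inh[1], pr$inh[2]),
    w_exc, w_inh,
    seed = seed
  )
}

ring_analytic <- function(profile, max_order = 8,
                          w_exc = conditions$ring$w_exc,
                          w_inh = conditions$ring$w_inh) {
  pr <- conditions$ring[[profile]]
  distance_correlation_analytic(
    conditions$ring$n,
    ring_profile(pr$exc[1], pr$exc[2]), ring_profile(pr$inh[1], pr$inh[2]),
    w_exc, w_inh,
    max_order = max_order
  )
}
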