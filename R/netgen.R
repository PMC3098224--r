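# Seeded generators for the network architectures under study.  All
# generators share conventions: G[i, j] is the integrated effect of
# presynaptic j on postsynaptic i; no self-connections; no multi-edges;
# every column carries the sign of its source type.

# assemble a hawkes_network from per-source target lists
build_network <- function(targets, n, types, w_exc, w_inh, positions, meta) {
  srcs <- rep.int(seq_len(n), lengths(targets))
  tgts <- unlist(targets, use.names = FALSE)
  if (is.null(tgts)) tgts <- integer(0)
  w <- ifelse(types[srcs] == "E", w_exc, w_inh)
  keep <- w != 0
  G <- Matrix::sparseMatrix(
    i = tgts[keep], j = srcs[keep], x = w[keep],
    dims = c(n, n)
  )
  meta$n_exc <- sum(types == "E")
  meta$n_inh <- sum(types == "I")
  hawkes_network(G, types, positions = positions, meta = meta)
}

check_weights <- function(w_exc, w_inh) {
  check_scalar(w_exc, "w_exc", lower = 0)
  check_scalar(w_inh, "w_inh", upper = 0)
}

assign_types_exact <- function(n, frac_inhib) {
  n_inh <- round(n * frac_inhib)
  types <- rep("E", n)
  if (n_inh > 0) types[sample.int(n, n_inh)] <- "I"
  types
}

#' Random (Erdos-Renyi style) network generator
#'
#' Connects every ordered pair of distinct nodes independently with
#' probability `p` (Bernoulli variant), or gives every node exactly
#' `round(p * (n - 1))` out-edges to targets sampled without replacement
#' (fixed out-degree variant).  Node types are assigned with exact counts
#' (`round(n * frac_inhib)` inhibitory nodes at random positions).
#'
#' @param n Number of nodes.
#' @param p Connection probability in `[0, 1]`.
#' @param w_exc Integrated weight of excitatory connections (`>= 0`).
#' @param w_inh Integrated weight of inhibitory connections (`<= 0`).
#' @param frac_inhib Fraction of inhibitory nodes.
#' @param fixed_out_degree If `TRUE`, every node gets exactly
#'   `round(p * (n - 1))` out-edges (a regular out-degree network).
#' @param seed Integer seed for reproducibility; `NULL` uses the current RNG
#'   stream.
#'
#' @return A [hawkes_network()].
#' @examples
#' net <- make_random_network(100, p = 0.1, w_exc = 0.02, w_inh = -0.1, seed = 1)
#' glance(net)
#' @export
make_random_network <- function(n, p, w_exc, w_inh, frac_inhib = 0.2,
                                fixed_out_degree = FALSE, seed = NULL) {
  check_scalar(n, "n", lower = 1)
  check_prob(p, "p")
  check_prob(frac_inhib, "frac_inhib")
  check_weights(w_exc, w_inh)
  with_seed_if(seed, {
    types <- assign_types_exact(n, frac_inhib)
    k_out <- round(p * (n - 1))
    targets <- lapply(seq_len(n), function(j) {
      if (fixed_out_degree) {
        if (k_out == 0) integer(0) else sample(seq_len(n)[-j], k_out)
      } else {
        tg <- which(runif(n) < p)
        tg[tg != j]
      }
    })
    build_network(
      targets, n, types, w_exc, w_inh,
      positions = NULL,
      meta = list(
        generator = "random", seed = seed,
        params = list(
          p = p, w_exc = w_exc, w_inh = w_inh, frac_inhib = frac_inhib,
          fixed_out_degree = fixed_out_degree, k_out = if (fixed_out_degree) k_out else NULL
        ),
        expected_connectivity = if (fixed_out_degree) k_out / (n - 1) else p
      )
    )
  })
}

#' Regular network: fixed per-type in- and out-degrees
#'
#' The regular-graph construction behind the closed-form average
#' correlation: every neuron of type X projects to exactly `round(p * n_Y)`
#' neurons of each type Y, and every neuron of type Y receives exactly the
#' matching number of inputs from type X.  Synaptic partners are otherwise
#' random (a random biregular bipartite graph per type pair, built by stub
#' matching with collision repair; no multi-edges, no self-connections).
#' Because all per-type degrees are exact, the equilibrium rates are exactly
#' homogeneous and [avg_correlation_closed_form()] is exact for these
#' networks, not just approximate.
#'
#' @inheritParams make_random_network
#' @return A [hawkes_network()].
#' @section Errors: the per-type in-degrees `round(p * n_Y) * n_X / n_Y`
#'   must be integers; otherwise a parameter error is raised (choose `n`,
#'   `frac_inhib`, `p` accordingly, e.g. `n = 500`, `frac_inhib = 0.2`,
#'   `p = 0.1`).
#' @export
make_regular_network <- function(n, p, w_exc, w_inh, frac_inhib = 0.2, seed = NULL) {
  check_scalar(n, "n", lower = 2)
  check_prob(p, "p")
  check_prob(frac_inhib, "frac_inhib")
  check_weights(w_exc, w_inh)
  n_inh <- round(n * frac_inhib)
  idx <- list(E = seq_len(n - n_inh), I = n - n_inh + seq_len(n_inh))
  # validate divisibility before drawing anything
  for (X in c("E", "I")) {
    for (Y in c("E", "I")) {
      nx <- length(idx[[X]]); ny <- length(idx[[Y]])
      if (nx == 0 || ny == 0) next
      K <- round(p * ny)
      if (K == 0) next
      L <- K * nx / ny
      if (abs(L - round(L)) > 1e-9) {
        abort(sprintf(
          "Regular construction needs integer per-type in-degrees: block %s->%s gives %.3f. Adjust n, frac_inhib or p.",
          X, Y, L
        ), class = "hawkesnet_parameter_error")
      }
    }
  }
  with_seed_if(seed, {
    types <- rep("E", n)
    types[idx$I] <- "I"
    src <- integer(0); tgt <- integer(0)
    for (X in c("E", "I")) {
      for (Y in c("E", "I")) {
        S <- idx[[X]]; Tn <- idx[[Y]]
        if (!length(S) || !length(Tn)) next
        K <- round(p * length(Tn))
        if (K == 0) next
        L <- as.integer(round(K * length(S) / length(Tn)))
        bs <- rep(S, each = K)
        bt <- sample(rep(Tn, times = L))
        it <- 0L
        repeat {
          bad <- which(duplicated(paste(bs, bt)) | bs == bt)
          if (!length(bad)) break
          it <- it + 1L
          if (it > 200L) {
            # extremely unlikely at sensible densities; restart the block
            bt <- sample(rep(Tn, times = L))
            it <- 0L
            next
          }
          pool <- unique(c(bad, sample.int(length(bs), min(length(bs), 2L * length(bad)))))
          bt[pool] <- sample(bt[pool])
        }
        src <- c(src, bs); tgt <- c(tgt, bt)
      }
    }
    w <- ifelse(types[src] == "E", w_exc, w_inh)
    keep <- w != 0
    G <- Matrix::sparseMatrix(i = tgt[keep], j = src[keep], x = w[keep], dims = c(n, n))
    hawkes_network(
      G, types,
      meta = list(
        generator = "regular", seed = seed,
        params = list(p = p, w_exc = w_exc, w_inh = w_inh, frac_inhib = frac_inhib),
        n_exc = n - n_inh, n_inh = n_inh,
        expected_connectivity = p
      )
    )
  })
}

#' Ring network with distance-dependent connectivity
#'
#' Nodes sit on a ring; node types are drawn independently per node with
#' probability `frac_inhib` of being inhibitory (so realised counts
#' fluctuate).  A source of type X connects to the node at geodesic distance
#' `d` with probability `profile_X(d)` — a boxcar profile per population.
#'
#' @inheritParams make_random_network
#' @param profile_exc,profile_inh [ring_profile()] objects for excitatory and
#'   inhibitory sources.
#' @return A [hawkes_network()] with ring `positions`.
#' @examples
#' net <- make_ring_network(200,
#'   profile_exc = ring_profile(20, 0.5), profile_inh = ring_profile(100, 0.1),
#'   w_exc = 0.01, w_inh = -0.05, seed = 1
#' )
#' @export
make_ring_network <- function(n, profile_exc, profile_inh, w_exc, w_inh,
                              frac_inhib = 0.2, seed = NULL) {
  check_scalar(n, "n", lower = 2)
  check_prob(frac_inhib, "frac_inhib")
  check_weights(w_exc, w_inh)
  stopifnot(inherits(profile_exc, "ring_profile"), inherits(profile_inh, "ring_profile"))
  if (profile_exc$half_width > n / 2 || profile_inh$half_width > n / 2) {
    abort("Profile half width may not exceed n/2.", class = "hawkesnet_parameter_error")
  }
  with_seed_if(seed, {
    types <- ifelse(runif(n) < frac_inhib, "I", "E")
    offsets <- list(
      E = unique(c(seq_len(profile_exc$half_width), n - seq_len(profile_exc$half_width)) %% n),
      I = unique(c(seq_len(profile_inh$half_width), n - seq_len(profile_inh$half_width)) %% n)
    )
    heights <- c(E = profile_exc$height, I = profile_inh$height)
    targets <- lapply(seq_len(n), function(j) {
      off <- offsets[[types[j]]]
      cand <- ((j - 1L + off) %% n) + 1L
      cand[runif(length(cand)) < heights[[types[j]]]]
    })
    build_network(
      targets, n, types, w_exc, w_inh,
      positions = 0:(n - 1),
      meta = list(
        generator = "ring", seed = seed,
        params = list(
          profile_exc = unclass(profile_exc), profile_inh = unclass(profile_inh),
          w_exc = w_exc, w_inh = w_inh, frac_inhib = frac_inhib
        ),
        expected_connectivity =
          (1 - frac_inhib) * profile_exc$height * length(offsets$E) / (n - 1) +
            frac_inhib * profile_inh$height * length(offsets$I) / (n - 1)
      )
    )
  })
}

#' Network with excitatory hubs of geometric out-degree
#'
#' Out-degrees are drawn from the geometric law
#' \eqn{P(k) = (1-q) q^k,\; k = 0, 1, 2, \ldots} with mean
#' \eqn{\mu = q/(1-q)}.  Excitatory nodes with out-degree above
#' `hub_threshold` are hubs.  Each hub draws its number of excitatory targets
#' from a binomial with success probability `n_E/n`; a fraction `f` of those
#' go to other hubs, the rest to excitatory non-hubs; the remaining targets
#' go to inhibitory nodes.  Non-hubs and inhibitory nodes pick targets
#' uniformly at random.  All sampling is without replacement; if a requested
#' class of targets exceeds the available pool, the surplus falls back to the
#' remaining pools and a warning is logged.
#'
#' @inheritParams make_random_network
#' @param mu Mean out-degree of the geometric law (`> 0`).
#' @param f Fraction of a hub's excitatory targets that are other hubs.
#' @param hub_threshold Out-degree above which an excitatory node is a hub;
#'   defaults to `ceiling(mu)` (out-degree larger than the mean).
#' @return A [hawkes_network()]; `meta$hubs` records the hub node ids.
#' @export
make_hub_network <- function(n, mu, f, w_exc, w_inh, frac_inhib = 0.2,
                             hub_threshold = ceiling(mu), seed = NULL) {
  check_scalar(n, "n", lower = 2)
  check_scalar(mu, "mu", lower = .Machine$double.eps)
  check_prob(f, "f")
  check_prob(frac_inhib, "frac_inhib")
  check_weights(w_exc, w_inh)
  with_seed_if(seed, {
    types <- assign_types_exact(n, frac_inhib)
    exc <- which(types == "E")
    inh <- which(types == "I")
    k <- pmin(rgeom(n, prob = 1 / (1 + mu)), n - 1L)
    hubs <- intersect(exc, which(k > hub_threshold))
    nonhub_exc <- setdiff(exc, hubs)
    fell_back <- FALSE
    targets <- vector("list", n)
    for (j in seq_len(n)) {
      kj <- k[j]
      if (kj == 0) {
        targets[[j]] <- integer(0)
      } else if (j %in% hubs) {
        n_exc_t <- min(stats::rbinom(1, kj, length(exc) / n), length(exc) - 1L)
        n_inh_t <- min(kj - n_exc_t, length(inh))
        hub_pool <- setdiff(hubs, j)
        nh_pool <- nonhub_exc
        n_hub_t <- round(f * n_exc_t)
        n_nh_t <- n_exc_t - n_hub_t
        if (n_hub_t > length(hub_pool) || n_nh_t > length(nh_pool)) {
          fell_back <- TRUE
          # fall back: draw all excitatory targets from the pooled candidates
          pool <- c(hub_pool, nh_pool)
          exc_t <- sample(pool, min(n_exc_t, length(pool)))
        } else {
          exc_t <- c(
            if (n_hub_t > 0) sample(hub_pool, n_hub_t) else integer(0),
            if (n_nh_t > 0) sample(nh_pool, n_nh_t) else integer(0)
          )
        }
        inh_t <- if (n_inh_t > 0) sample(inh, n_inh_t) else integer(0)
        targets[[j]] <- c(exc_t, inh_t)
      } else {
        targets[[j]] <- sample(seq_len(n)[-j], min(kj, n - 1L))
      }
    }
    if (fell_back) {
      warn("Hub target pool exhausted for some sources; fell back to sampling the full excitatory pool.")
    }
    build_network(
      targets, n, types, w_exc, w_inh,
      positions = NULL,
      meta = list(
        generator = "hub", seed = seed,
        params = list(
          mu = mu, f = f, hub_threshold = hub_threshold,
          w_exc = w_exc, w_inh = w_inh, frac_inhib = frac_inhib
        ),
        hubs = hubs,
        expected_connectivity = mu / n
      )
    )
  })
}

#' Patchy ring network
#'
#' Every source gets one patch of `patch_size` contiguous ring positions at a
#' uniformly random offset; each patch member (other than the source itself)
#' becomes a target independently with probability `p_patch`.  With
#' `separated_types = TRUE` all inhibitory nodes occupy one contiguous block
#' of the ring; otherwise types are placed uniformly at random (exact
#' counts).
#'
#' @inheritParams make_random_network
#' @param patch_size Number of contiguous ring positions per patch (1..n).
#' @param p_patch Connection probability inside the patch.
#' @param separated_types If `TRUE`, inhibitory nodes form one contiguous
#'   block of the ring.
#' @return A [hawkes_network()] with ring `positions`;
#'   `meta$expected_connectivity` records `patch_size * p_patch / n`.
#' @export
make_patchy_network <- function(n, patch_size, p_patch, w_exc, w_inh,
                                frac_inhib = 0.2, separated_types = FALSE,
                                seed = NULL) {
  check_scalar(n, "n", lower = 2)
  check_scalar(patch_size, "patch_size", lower = 1, upper = n)
  check_prob(p_patch, "p_patch")
  check_prob(frac_inhib, "frac_inhib")
  check_weights(w_exc, w_inh)
  s <- as.integer(patch_size)
  with_seed_if(seed, {
    n_inh <- round(n * frac_inhib)
    types <- rep("E", n)
    if (n_inh > 0) {
      if (separated_types) {
        start <- sample.int(n, 1) - 1L
        block <- ((start + 0:(n_inh - 1L)) %% n) + 1L
        types[block] <- "I"
      } else {
        types[sample.int(n, n_inh)] <- "I"
      }
    }
    targets <- lapply(seq_len(n), function(j) {
      start <- sample.int(n, 1) - 1L
      members <- ((start + 0:(s - 1L)) %% n) + 1L
      members <- members[members != j]
      members[runif(length(members)) < p_patch]
    })
    build_network(
      targets, n, types, w_exc, w_inh,
      positions = 0:(n - 1),
      meta = list(
        generator = "patchy", seed = seed,
        params = list(
          patch_size = s, p_patch = p_patch, separated_types = separated_types,
          w_exc = w_exc, w_inh = w_inh, frac_inhib = frac_inhib
        ),
        expected_connectivity = s * p_patch / n
      )
    )
  })
}
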