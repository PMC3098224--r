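#' Weighted directed connectivity of a point-process network
#'
#' A `hawkes_network` bundles the matrix of integrated interaction kernels
#' `G` (sparse, `G[i, j]` is the integrated effect of presynaptic neuron `j`
#' on postsynaptic neuron `i`; rows index targets), the per-node types
#' (`"E"`/`"I"`), optional integer ring coordinates, and the generator
#' metadata (name, parameters, seed) needed to reproduce it.
#'
#' Invariants: the diagonal of `G` is zero (no self-connections); every
#' column has the single sign of its presynaptic neuron (excitatory columns
#' non-negative, inhibitory columns non-positive).
#'
#' @param G An `n x n` matrix (dense or `Matrix` sparse) of integrated kernel
#'   weights, rows = postsynaptic targets, columns = presynaptic sources.
#' @param types Character vector of `"E"`/`"I"` per node.
#' @param positions Optional integer ring coordinates (0-based, a permutation
#'   of `0:(n-1)`), or `NULL` for non-spatial networks.
#' @param meta List of generator metadata (free-form; generators record their
#'   name, parameter values, the seed and realised quantities here).
#'
#' @return An object of class `hawkes_network`.
#' @seealso [make_random_network()], [make_ring_network()],
#'   [make_hub_network()], [make_patchy_network()]
#' @export
hawkes_network <- function(G, types, positions = NULL, meta = list()) {
  G <- methods::as(methods::as(Matrix::Matrix(G, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  n <- nrow(G)
  if (ncol(G) != n) {
    abort("`G` must be square.", class = "hawkesnet_format_error")
  }
  types <- as.character(types)
  if (length(types) != n || !all(types %in% c("E", "I"))) {
    abort("`types` must be a length-n vector of \"E\"/\"I\".",
      class = "hawkesnet_format_error"
    )
  }
  if (any(Matrix::diag(G) != 0)) {
    abort("Self-connections are not allowed: the diagonal of `G` must be zero.",
      class = "hawkesnet_format_error"
    )
  }
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != n || !setequal(positions, 0:(n - 1))) {
      abort("`positions` must be a permutation of 0:(n-1).",
        class = "hawkesnet_format_error"
      )
    }
  }
  structure(
    list(n = n, types = types, G = Matrix::drop0(G), positions = positions, meta = meta),
    class = "hawkes_network"
  )
}

#' @export
print.hawkes_network <- function(x, ...) {
  ne <- sum(x$types == "E")
  nnz <- length(x$G@x)
  cat(sprintf(
    "<hawkes_network> %d nodes (%d E / %d I), %d edges (density %.4f)%s\n",
    x$n, ne, x$n - ne, nnz, nnz / (x$n * (x$n - 1)),
    if (!is.null(x$positions)) ", ring coordinates" else ""
  ))
  if (!is.null(x$meta$generator)) {
    cat("  generator:", x$meta$generator,
      if (!is.null(x$meta$seed)) sprintf("(seed %s)", x$meta$seed) else "", "\n"
    )
  }
  invisible(x)
}

# Extract a base dense matrix of integrated weights from a network, a Matrix,
# or a plain matrix.  Theory functions accept any of the three so that
# textbook examples (e.g. a single self-exciting node) can be written down
# directly even though the generators never produce self-connections.
as_G <- function(net) {
  if (inherits(net, "hawkes_network")) {
    as.matrix(net$G)
  } else if (inherits(net, "Matrix") || is.matrix(net)) {
    m <- as.matrix(net)
    if (nrow(m) != ncol(m)) {
      abort("Connectivity matrix must be square.", class = "hawkesnet_format_error")
    }
    m
  } else {
    abort("Expected a `hawkes_network` or a square matrix.",
      class = "hawkesnet_format_error"
    )
  }
}

#' Edge table of a network
#'
#' @param x A `hawkes_network`.
#' @param ... Unused.
#' @return A tibble with one row per directed edge: `source`, `target`,
#'   `weight`, `source_type`, `target_type` (1-based node indices).
#' @export
tidy.hawkes_network <- function(x, ...) {
  Gt <- methods::as(x$G, "TsparseMatrix")
  tibble(
    source = Gt@j + 1L,
    target = Gt@i + 1L,
    weight = Gt@x,
    source_type = x$types[Gt@j + 1L],
    target_type = x$types[Gt@i + 1L]
  ) |> dplyr::arrange(.data$source, .data$target)
}

#' One-row summary of a network
#'
#' @param x A `hawkes_network`.
#' @param ... Unused.
#' @return A one-row tibble: node and edge counts, density, mean absolute
#'   weight, realised excitatory/inhibitory counts.
#' @export
glance.hawkes_network <- function(x, ...) {
  nnz <- length(x$G@x)
  tibble(
    n_nodes = x$n,
    n_exc = sum(x$types == "E"),
    n_inh = sum(x$types == "I"),
    n_edges = nnz,
    density = nnz / (x$n * (x$n - 1)),
    mean_abs_weight = if (nnz) mean(abs(x$G@x)) else 0,
    generator = x$meta$generator %||% NA_character_
  )
}

# out-degree (number of targets) per node
out_degrees <- function(net) {
  Matrix::colSums(net$G != 0)
}

in_degrees <- function(net) {
  Matrix::rowSums(net$G != 0)
}
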