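# Reading and writing networks and spike trains.  Connectivity travels as
# Matrix Market coordinate files or 3-column TSV edge lists, each with a
# JSON sidecar carrying node types, ring positions and generator metadata;
# spikes as 2-column TSV.  Round trips are lossless.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a network to disk
#'
#' Writes the connectivity as Matrix Market coordinate format (`.mtx`) or a
#' 3-column TSV edge list (`source`, `target`, `weight`; any other
#' extension), plus a JSON sidecar `<stem>.json` with node types, positions
#' and metadata.
#'
#' @param net A [hawkes_network()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "hawkes_network"))
  if (tolower(tools::file_ext(path)) == "mtx") {
    Matrix::writeMM(net$G, path)
  } else {
    readr::write_tsv(
      tidy(net)[, c("source", "target", "weight")],
      path, progress = FALSE
    )
  }
  jsonlite::write_json(
    list(
      n = net$n, types = net$types, positions = net$positions,
      meta = net$meta
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a network from disk
#'
#' Counterpart of [write_network()].  Explicit zero entries in a Matrix
#' Market file are dropped (the edge set is defined by non-zero weights).
#' Node ids outside `1..n` raise a format error.
#'
#' @param path Path to a `.mtx` or TSV edge-list file with its JSON sidecar.
#' @return A [hawkes_network()].
#' @export
read_network <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort(sprintf("Missing sidecar %s.", sc), class = "hawkesnet_format_error")
  }
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  n <- side$n
  if (tolower(tools::file_ext(path)) == "mtx") {
    G <- Matrix::readMM(path)
    if (nrow(G) != n || ncol(G) != n) {
      abort("Matrix dimensions disagree with the sidecar.",
        class = "hawkesnet_format_error"
      )
    }
    G <- Matrix::drop0(G)
  } else {
    edges <- readr::read_tsv(path,
      col_types = readr::cols(
        source = readr::col_integer(), target = readr::col_integer(),
        weight = readr::col_double()
      ), progress = FALSE
    )
    if (any(edges$source < 1 | edges$source > n | edges$target < 1 | edges$target > n)) {
      abort("Edge list contains node ids outside 1..n.",
        class = "hawkesnet_format_error"
      )
    }
    edges <- edges[edges$weight != 0, , drop = FALSE]
    G <- Matrix::sparseMatrix(
      i = edges$target, j = edges$source, x = edges$weight, dims = c(n, n)
    )
  }
  positions <- side$positions
  if (length(positions) == 0) positions <- NULL
  hawkes_network(G, side$types, positions = positions, meta = as.list(side$meta))
}

#' Write spike trains to TSV
#'
#' Two columns (`neuron`, `time`) plus a JSON sidecar with the neuron count
#' and recording duration, so the estimators can be re-run on the file.
#'
#' @param spikes A `spike_trains` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  readr::write_tsv(as_tibble(spikes)[, c("neuron", "time")], path, progress = FALSE)
  jsonlite::write_json(
    list(n = attr(spikes, "n"), duration = attr(spikes, "duration")),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read spike trains from TSV
#'
#' @param path Path written by [write_spikes()].
#' @return A `spike_trains` tibble with `n` and `duration` attributes.
#' @export
read_spikes <- function(path) {
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      neuron = readr::col_integer(), time = readr::col_double()
    ), progress = FALSE
  )
  if (any(out$neuron < 1 | out$neuron > side$n)) {
    abort("Spike table contains neuron ids outside 1..n.",
      class = "hawkesnet_format_error"
    )
  }
  out <- as_tibble(out)
  attr(out, "n") <- side$n
  attr(out, "duration") <- side$duration
  class(out) <- c("spike_trains", class(out))
  out
}
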