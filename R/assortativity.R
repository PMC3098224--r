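#' Weighted assortativity coefficient
#'
#' Correlation between the total weighted degrees of the two endpoints of the
#' directed edges of a network.  For each edge the total weighted degree
#' (in-strength plus out-strength, computed from absolute weights) of the
#' source and of the target enter a Newman-style symmetric Pearson
#' correlation in which both edge ends are pooled:
#' \deqn{r = \frac{\langle x y \rangle - \langle (x+y)/2 \rangle^2}
#'            {\langle (x^2+y^2)/2 \rangle - \langle (x+y)/2 \rangle^2}}
#' with the averages over edges.  Positive values mean that strongly
#' connected nodes preferentially attach to each other (assortative mixing);
#' the geometric-degree hub networks of [make_hub_network()] are mildly
#' disassortative, the more so the smaller the hub-to-hub fraction `f`.
#'
#' @param net A [hawkes_network()] with at least 2 edges.
#' @return A single number in `[-1, 1]`.
#' @section Errors: If the pooled endpoint degrees have zero variance (for
#'   example in a degree-regular graph with uniform weights) the coefficient
#'   is undefined and an error of class `"hawkesnet_degenerate"` is raised —
#'   it is never silently reported as 0.
#' @export
weighted_assortativity <- function(net) {
  stopifnot(inherits(net, "hawkes_network"))
  Gt <- methods::as(net$G, "TsparseMatrix")
  if (length(Gt@x) < 2) {
    abort("Need at least 2 edges.", class = "hawkesnet_parameter_error")
  }
  A <- abs(net$G)
  strength <- as.numeric(Matrix::rowSums(A) + Matrix::colSums(A))
  x <- strength[Gt@j + 1L] # source end
  y <- strength[Gt@i + 1L] # target end
  mid <- mean((x + y) / 2)
  den <- mean((x^2 + y^2) / 2) - mid^2
  if (den <= .Machine$double.eps * max(1, mean(strength)^2)) {
    abort(
      "Weighted assortativity is undefined: endpoint degrees have zero variance.",
      class = "hawkesnet_degenerate"
    )
  }
  (mean(x * y) - mid^2) / den
}
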