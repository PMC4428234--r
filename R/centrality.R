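#' Degree and normalized betweenness centrality
#'
#' Computes, for every node `j`, the degree centrality `d_j` (number of
#' distinct interaction partners, self excluded) and the betweenness
#' centrality `b_j` = sum over unordered pairs `{i,k}` (`i != j != k`) of
#' `sigma_ik(j) / sigma_ik`, where `sigma_ik` counts shortest paths between
#' `i` and `k` and `sigma_ik(j)` those passing through `j`. Betweenness is
#' normalized by `(n-1)(n-2)/2`, the number of pairs a node could lie
#' between, so `b_j` lies in `[0, 1]`. For `n < 3` the normalizer vanishes
#' and all `b_j` are defined as 0.
#'
#' @param net A connected `igraph` graph (extract the LCC first with
#'   [largest_connected_component()]).
#' @return A data frame with columns `node`, `degree`, `betweenness`, one
#'   row per vertex in stored order.
#' @export
node_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n >= 2L && igraph::components(net)$no > 1L) {
    stop("network is disconnected; extract the largest connected component ",
         "with largest_connected_component() first", call. = FALSE)
  }
  deg <- as.integer(igraph::degree(net, loops = FALSE))
  if (n < 3L) {
    btw <- rep(0, n)
  } else {
    raw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
    btw <- as.numeric(raw) / ((n - 1) * (n - 2) / 2)
  }
  data.frame(node = node_labels(net), degree = deg, betweenness = btw,
             stringsAsFactors = FALSE)
}

#' Centrality weights for the corrected domination objective
#'
#' The centrality-corrected model replaces the unit objective coefficients of
#' the minimum dominating set program with `w_j = (d_j * b_j)^(-gamma)`, so
#' that high-degree, high-betweenness nodes become cheap to select. Because
#' the power is undefined when `b_j = 0` (every degree-1 node of a graph with
#' at least 3 nodes has zero betweenness), zero betweenness is floored at
#' `eps = 0.5 / ((n-1)(n-2)/2)` -- half the smallest achievable positive
#' normalized betweenness -- which keeps all weights finite while ranking any
#' zero-betweenness node strictly below every positive-betweenness node of
#' equal degree. The floor actually used is returned for provenance.
#'
#' @param centrality A data frame from [node_centrality()].
#' @param gamma Non-negative exponent; `gamma = 0` gives unit weights and
#'   recovers the plain minimum dominating set.
#' @param betweenness_floor Positive floor applied to zero betweenness;
#'   default as described above (`0.5` for degenerate `n < 3` graphs).
#' @return An object of class `ccmds_weights`: a list with `weights` (named
#'   numeric vector, one entry per node), `gamma`, and `betweenness_floor`.
#' @examples
#' g <- make_figure1_fixture()
#' w <- compute_weights(node_centrality(g), gamma = 0.05)
#' round(w$weights, 4)
#' @export
compute_weights <- function(centrality, gamma,
                            betweenness_floor = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0) {
    stop("gamma must be a single non-negative number", call. = FALSE)
  }
  n <- nrow(centrality)
  if (is.null(betweenness_floor)) {
    norm <- (n - 1) * (n - 2) / 2
    betweenness_floor <- if (norm > 0) 0.5 / norm else 0.5
  }
  if (betweenness_floor <= 0) {
    stop("betweenness_floor must be positive", call. = FALSE)
  }
  b <- pmax(centrality$betweenness, betweenness_floor)
  w <- (centrality$degree * b)^(-gamma)
  names(w) <- centrality$node
  structure(
    list(weights = w, gamma = gamma, betweenness_floor = betweenness_floor),
    class = "ccmds_weights"
  )
}

#' @export
print.ccmds_weights <- function(x, ...) {
  cat("Centrality-corrected weights: ", length(x$weights), " nodes, gamma = ",
      x$gamma, ", betweenness floor = ", format(x$betweenness_floor), "\n",
      sep = "")
  invisible(x)
}

#' Export a centrality/weight table as TSV
#'
#' Writes one row per node with columns `node`, `degree`, `betweenness`,
#' `weight` at 12 significant digits.
#'
#' @param centrality Data frame from [node_centrality()].
#' @param weights A `ccmds_weights` object aligned with `centrality`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centrality_table <- function(centrality, weights, path) {
  tab <- data.frame(
    node = centrality$node,
    degree = centrality$degree,
    betweenness = signif(centrality$betweenness, 12),
    weight = signif(unname(weights$weights[centrality$node]), 12),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
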