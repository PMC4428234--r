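#' The 10-node worked-example network
#'
#' A small two-hub network (hubs 5 and 6 bridged by a single edge, each hub
#' sharing its periphery with a secondary hub, 1 and 10 respectively) whose
#' minimum dominating sets are exactly the four pairs
#' `{1,6}`, `{1,10}`, `{5,6}`, `{5,10}`: the plain domination objective
#' cannot tell them apart, while the centrality-corrected objective uniquely
#' prefers `{5,6}`, the pair with the highest degree-times-betweenness
#' products. Used throughout the tests and examples as a fully worked
#' fixture.
#'
#' @return An undirected `igraph` graph with 10 vertices (named `"1"` ..
#'   `"10"`) and 15 edges.
#' @examples
#' g <- make_figure1_fixture()
#' igraph::ecount(g)
#' @export
make_figure1_fixture <- function() {
  edges <- c(
    "1", "2", "1", "3", "1", "4", "1", "5",
    "5", "2", "5", "3", "5", "4", "5", "6",
    "6", "7", "6", "8", "6", "9", "6", "10",
    "10", "7", "10", "8", "10", "9"
  )
  m <- matrix(edges, ncol = 2, byrow = TRUE)
  g <- edge_list_network(m[, 1L], m[, 2L])
  # canonical vertex order 1..10
  igraph::permute(g, match(igraph::V(g)$name, as.character(1:10)))
}

#' Seeded random test networks
#'
#' Generates a random graph and returns its largest connected component,
#' standing in for sparse PPI topology in tests and simulations. Two models:
#' `"preferential-attachment"` (Barabasi-Albert growth, heavy-tailed
#' degrees; `param` = edges added per new vertex) and `"uniform-random"`
#' (Erdos-Renyi G(n, p); `param` = edge probability). Output is fully
#' determined by `(model, n, param, seed)`; vertices are labeled
#' `"v1", "v2", ...`.
#'
#' @param model `"preferential-attachment"` or `"uniform-random"`.
#' @param n Number of vertices before LCC extraction (`>= 2`).
#' @param param Density parameter for the chosen model.
#' @param seed Integer seed.
#' @return An undirected simple `igraph` graph (the LCC).
#' @export
random_network <- function(model = c("preferential-attachment",
                                     "uniform-random"),
                           n, param, seed) {
  model <- match.arg(model)
  if (!is.numeric(n) || n < 2) stop("n must be at least 2", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- switch(model,
    "preferential-attachment" = {
      if (!is.numeric(param) || param < 1) {
        stop("attachment parameter must be >= 1", call. = FALSE)
      }
      igraph::sample_pa(n, m = param, directed = FALSE)
    },
    "uniform-random" = {
      if (!is.numeric(param) || param < 0 || param > 1) {
        stop("edge probability must be in [0,1]", call. = FALSE)
      }
      igraph::sample_gnp(n, param)
    }
  )
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g <- igraph::simplify(g)
  largest_connected_component(g)
}

#' Annotation set with planted enrichment
#'
#' Draws a synthetic annotated gene list over the network's nodes: each node
#' of `target` is annotated with probability `inside_rate`, every other node
#' with probability `outside_rate`. With `inside_rate > outside_rate` the
#' target set carries genuine enrichment of a known strength; with equal
#' rates there is no signal, giving the null for type-I-error checks.
#'
#' @param net An `igraph` graph with named vertices.
#' @param target Character vector of node labels (subset of the network).
#' @param inside_rate,outside_rate Annotation probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Character vector of annotated node labels.
#' @export
planted_annotation <- function(net, target, inside_rate, outside_rate, seed) {
  labs <- node_labels(net)
  target <- as.character(target)
  if (length(setdiff(target, labs)) > 0L) {
    stop("target must be a subset of the network's nodes", call. = FALSE)
  }
  if (any(c(inside_rate, outside_rate) < 0) ||
      any(c(inside_rate, outside_rate) > 1)) {
    stop("rates must lie in [0,1]", call. = FALSE)
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rate <- ifelse(labs %in% target, inside_rate, outside_rate)
  labs[stats::runif(length(labs)) < rate]
}
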