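#' @useDynLib ccmds, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_dominating_set <- function(members, objective, gamma, proven_optimal,
                               solver_id) {
  structure(
    list(members = sort(members), objective = objective, gamma = gamma,
         proven_optimal = proven_optimal, solver_id = solver_id),
    class = "dominating_set"
  )
}

#' @export
print.dominating_set <- function(x, ...) {
  cat("Dominating set: ", length(x$members), " members, objective = ",
      format(x$objective), if (!is.null(x$gamma)) paste0(", gamma = ", x$gamma),
      "\n  solver: ", x$solver_id,
      if (x$proven_optimal) " (proven optimal)" else " (heuristic)", "\n",
      sep = "")
  cat("  members: ", paste(utils::head(x$members, 10L), collapse = ", "),
      if (length(x$members) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Test the domination property
#'
#' A node set `S` dominates the network when every node is either in `S` or
#' adjacent to a member of `S` -- equivalently, every closed neighborhood
#' `N[i]` intersects `S`.
#'
#' @param net An `igraph` graph with named vertices.
#' @param candidate Character vector of node labels.
#' @return `TRUE` iff `candidate` is a dominating set.
#' @export
is_dominating <- function(net, candidate) {
  labs <- node_labels(net)
  candidate <- as.character(candidate)
  unknown <- setdiff(candidate, labs)
  if (length(unknown) > 0L) {
    stop("candidate contains labels not in the network: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  idx <- match(candidate, labs)
  in_set <- logical(length(labs))
  in_set[idx] <- TRUE
  adj <- closed_adjacency_idx(net)
  all(vapply(adj, function(nb) any(in_set[nb]), logical(1L)))
}

solve_wds <- function(net, weights) {
  adj <- closed_adjacency_idx(net)
  res <- solve_wds_cpp(adj, weights)
  labs <- node_labels(net)
  list(members = labs[res$members], objective = res$objective)
}

#' Solve the minimum dominating set program exactly
#'
#' Finds a smallest dominating set by solving the binary integer program
#' `min sum_j x_j` subject to `sum_{j in N[i]} x_j >= 1` for every node,
#' with an exact branch-and-bound search (zero optimality gap). The optimum
#' cardinality is unique even though the optimal set usually is not; the
#' solver is deterministic, so repeated runs return the same set.
#'
#' @param net A connected `igraph` graph with named vertices.
#' @return A `dominating_set` object with `objective` equal to the domination
#'   number and `proven_optimal = TRUE`.
#' @examples
#' g <- make_figure1_fixture()
#' solve_mds(g)
#' @export
solve_mds <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  res <- solve_wds(net, rep(1, igraph::vcount(net)))
  new_dominating_set(res$members, round(res$objective), gamma = NULL,
                     proven_optimal = TRUE, solver_id = "bnb")
}

#' Solve the centrality-corrected minimum dominating set program exactly
#'
#' Minimizes `sum_j w_j x_j` over dominating sets, with weights
#' `w_j = (d_j b_j)^(-gamma)` from [compute_weights()]. For `gamma = 0` the
#' weights are all 1 and the objective coincides with [solve_mds()]; for
#' `gamma > 0` the optimizer is biased toward high-degree, high-betweenness
#' nodes, which largely removes the degeneracy of the unweighted optimum.
#'
#' @param net A connected `igraph` graph with named vertices.
#' @param weights A `ccmds_weights` object covering every node of `net`.
#' @return A `dominating_set` with the weighted objective, the gamma used,
#'   and `proven_optimal = TRUE`.
#' @examples
#' g <- make_figure1_fixture()
#' w <- compute_weights(node_centrality(g), gamma = 0.05)
#' solve_ccmds(g, w)$members
#' @export
solve_ccmds <- function(net, weights) {
  labs <- node_labels(net)
  if (!inherits(weights, "ccmds_weights")) {
    stop("weights must be a ccmds_weights object from compute_weights()",
         call. = FALSE)
  }
  missing <- setdiff(labs, names(weights$weights))
  if (length(missing) > 0L) {
    stop("weights missing for nodes: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  res <- solve_wds(net, unname(weights$weights[labs]))
  new_dominating_set(res$members, res$objective, gamma = weights$gamma,
                     proven_optimal = TRUE, solver_id = "bnb")
}

#' Enumerate all minimum dominating sets of a small graph
#'
#' Brute-force oracle: tests node subsets in increasing size until dominating
#' sets appear, then returns all dominating sets of that minimum size. Used
#' to surface the non-uniqueness of the unweighted optimum and to verify the
#' exact solvers on small graphs.
#'
#' @param net An `igraph` graph with named vertices.
#' @param max_n Size guard; enumeration is refused above this many nodes
#'   (default 20).
#' @return A list of character vectors (each sorted), ordered canonically.
#' @examples
#' enumerate_minimum_dominating_sets(make_figure1_fixture())
#' @export
enumerate_minimum_dominating_sets <- function(net, max_n = 20L) {
  n <- igraph::vcount(net)
  if (n > max_n) {
    stop("enumeration limited to networks with at most ", max_n, " nodes",
         call. = FALSE)
  }
  labs <- node_labels(net)
  adj <- closed_adjacency_idx(net)
  dominates <- function(idx) {
    in_set <- logical(n)
    in_set[idx] <- TRUE
    all(vapply(adj, function(nb) any(in_set[nb]), logical(1L)))
  }
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    hits <- Filter(dominates, combos)
    if (length(hits) > 0L) {
      out <- lapply(hits, function(idx) sort(labs[idx]))
      ord <- order(vapply(out, paste, "", collapse = "\r"))
      return(out[ord])
    }
  }
  list()
}

#' Weighted-best sets among the minimum dominating sets
#'
#' Companion oracle to [enumerate_minimum_dominating_sets()]: among all
#' minimum-cardinality dominating sets, returns those minimizing the total
#' node weight, together with that total. Verifies [solve_ccmds()] on small
#' graphs at a gamma where the corrected optimum retains minimum cardinality.
#'
#' @param net An `igraph` graph with named vertices.
#' @param weights A `ccmds_weights` object.
#' @param max_n Size guard (default 20).
#' @return A list with `sets` (list of sorted character vectors) and
#'   `objective` (the minimal weight sum).
#' @export
enumerate_weighted_best <- function(net, weights, max_n = 20L) {
  all_min <- enumerate_minimum_dominating_sets(net, max_n = max_n)
  obj <- vapply(all_min, function(s) sum(weights$weights[s]), 0)
  best <- obj <= min(obj) + 1e-12
  list(sets = all_min[best], objective = min(obj))
}

#' Greedy dominating set guided by a node ranking
#'
#' The degree-centrality heuristic comparator (DS-DC): repeatedly add the
#' node covering the most still-uncovered nodes, breaking ties by the higher
#' ranking score and then by label order, until every node is covered. The
#' result is a dominating set but carries no optimality guarantee.
#'
#' @param net An `igraph` graph with named vertices.
#' @param ranking Named numeric vector of scores covering all nodes; default
#'   is the degree centrality.
#' @return A `dominating_set` with `proven_optimal = FALSE` and
#'   `solver_id = "greedy"`.
#' @export
greedy_dominating_set <- function(net, ranking = NULL) {
  labs <- node_labels(net)
  n <- length(labs)
  if (is.null(ranking)) {
    ranking <- igraph::degree(net, loops = FALSE)
    names(ranking) <- labs
  }
  missing <- setdiff(labs, names(ranking))
  if (length(missing) > 0L) {
    stop("ranking missing for nodes: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  score <- unname(ranking[labs])
  adj <- closed_adjacency_idx(net)
  covered <- logical(n)
  chosen <- integer(0)
  while (!all(covered)) {
    gain <- vapply(adj, function(nb) sum(!covered[nb]), 0L)
    # max new coverage, then higher score, then earlier label
    ord <- order(-gain, -score, labs, method = "radix")
    pick <- ord[1L]
    chosen <- c(chosen, pick)
    covered[adj[[pick]]] <- TRUE
  }
  new_dominating_set(labs[chosen], length(chosen), gamma = NULL,
                     proven_optimal = FALSE, solver_id = "greedy")
}
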