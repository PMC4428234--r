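#' Read an undirected PPI network from an edge list
#'
#' Parses a plain-text edge list (one interaction per line) into an undirected
#' simple [igraph][igraph::igraph-package] graph. Lines beginning with `#` are
#' ignored. Duplicate edges -- including reversed duplicates -- are collapsed
#' to a single undirected edge, and self-interaction lines are dropped from
#' the edge set while the node label itself is retained (the dominating-set
#' constraints add the self-coverage convention `A_ii = 1` uniformly later,
#' so input self-loops carry no extra information). Node identity is the raw
#' label after whitespace trimming; node order is first-appearance order.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter; the default `""` splits on any run of
#'   whitespace (tabs or spaces).
#' @param sif Logical; if `TRUE` the file is read as SIF
#'   (`nodeA relation nodeB`), taking fields 1 and 3 of each line.
#' @return An undirected simple `igraph` graph whose vertices carry `name`
#'   attributes. The number of collapsed duplicate lines is attached as the
#'   graph attribute `collapsed_lines`.
#' @examples
#' f <- tempfile()
#' writeLines(c("P1\tP2", "P2\tP3", "P3\tP1"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)
#' @export
read_edge_list <- function(path, delimiter = "", sif = FALSE) {
  if (!file.exists(path)) {
    stop("network file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no edges found in ", path, call. = FALSE)
  }
  if (identical(delimiter, "")) {
    fields <- strsplit(trimws(lines[idx]), "\\s+")
  } else {
    fields <- strsplit(trimws(lines[idx]), delimiter, fixed = TRUE)
  }
  need <- if (sif) 3L else 2L
  nf <- lengths(fields)
  if (any(nf < need)) {
    bad <- idx[which(nf < need)[1L]]
    stop("malformed line ", bad, " in ", path,
         ": expected at least ", need, " fields", call. = FALSE)
  }
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", if (sif) 3L else 2L))
  edge_list_network(a, b)
}

#' Build a network from two vectors of endpoint labels
#'
#' Workhorse behind [read_edge_list()]; useful for constructing test graphs
#' directly in code. Applies the same canonicalization: self-pairs dropped
#' from the edge set (label retained as an isolated or connected node),
#' duplicates and reversed duplicates collapsed, vertex order by first
#' appearance in the concatenated label stream.
#'
#' @param from,to Character vectors of equal length with edge endpoints.
#' @return An undirected simple `igraph` graph.
#' @export
edge_list_network <- function(from, to) {
  stopifnot(length(from) == length(to))
  from <- as.character(from)
  to <- as.character(to)
  # vertex order: first appearance scanning each line left-to-right
  labels <- unique(as.vector(rbind(from, to)))
  loop <- from == to
  from2 <- from[!loop]
  to2 <- to[!loop]
  # canonical unordered key for dedup
  key <- ifelse(from2 < to2, paste0(from2, "\r", to2), paste0(to2, "\r", from2))
  dup <- duplicated(key)
  n_collapsed <- sum(dup) + sum(loop)
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  igraph::V(g)$name <- labels
  if (any(!dup)) {
    g <- igraph::add_edges(g, rbind(from2[!dup], to2[!dup]))
  }
  g$collapsed_lines <- n_collapsed
  g
}

#' Write a network as a plain-text edge list
#'
#' One edge per line, tab-delimited, endpoints in stored order. Reading the
#' file back with [read_edge_list()] reproduces the same node and edge sets
#' (isolated nodes are not representable in an edge list and are omitted).
#'
#' @param net An `igraph` graph with named vertices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Extract the largest connected component
#'
#' All downstream analyses (centralities, domination programs) run on the
#' largest connected component (LCC) of the interaction network. Ties in
#' component size are broken deterministically in favour of the component
#' containing the earliest-appearing vertex.
#'
#' @param net An `igraph` graph with at least one vertex.
#' @return The induced subgraph on the largest component, vertex order
#'   preserved.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) {
    stop("cannot take the largest component of an empty network",
         call. = FALSE)
  }
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # earliest first-appearance vertex wins
    first_vertex <- vapply(best, function(cid) min(which(comp$membership == cid)), 0L)
    best <- best[which.min(first_vertex)]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Closed neighborhoods of every node
#'
#' The domination constraints use the closed neighborhood
#' `N[i] = {i} + neighbors(i)`: by convention every node covers itself
#' (`A_ii = 1`), so `|N[i]| = d_i + 1`.
#'
#' @param net An `igraph` graph with named vertices.
#' @return A named list mapping each vertex label to the character vector of
#'   labels in its closed neighborhood (self first, then neighbors in stored
#'   order).
#' @export
closed_adjacency <- function(net) {
  labs <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  out <- lapply(seq_along(labs), function(i) {
    c(labs[i], setdiff(labs[as.integer(adj[[i]])], labs[i]))
  })
  names(out) <- labs
  out
}

# Integer (1-based) closed-neighborhood lists, used by the solvers.
closed_adjacency_idx <- function(net) {
  n <- igraph::vcount(net)
  adj <- igraph::adjacent_vertices(net, seq_len(n))
  lapply(seq_len(n), function(i) unique(c(i, as.integer(adj[[i]]))))
}

node_labels <- function(net) {
  labs <- igraph::V(net)$name
  if (is.null(labs)) as.character(seq_len(igraph::vcount(net))) else labs
}
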