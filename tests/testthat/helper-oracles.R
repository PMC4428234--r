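# Independent oracles used to verify the package's implementations.
# Each is written from first principles (enumeration / direct summation),
# deliberately sharing no algorithmic machinery with the code under test.

# Betweenness by exhaustive simple-path enumeration (n <= 8 graphs):
# enumerate every simple path between each unordered pair with a DFS, keep
# the shortest ones, and credit interior nodes with sigma_ik(j)/sigma_ik.
oracle_betweenness <- function(g) {
  labs <- igraph::V(g)$name
  n <- length(labs)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  all_simple_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (v in which(A[last, ])) {
        if (!(v %in% path)) walk(c(path, v))
      }
    }
    walk(s)
    out
  }
  b <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (k in seq(i + 1L, n)) {
      paths <- all_simple_paths(i, k)
      if (length(paths) == 0L) next
      len <- vapply(paths, length, 0L)
      geodesics <- paths[len == min(len)]
      sigma <- length(geodesics)
      for (p in geodesics) {
        interior <- p[-c(1L, length(p))]
        b[interior] <- b[interior] + 1 / sigma
      }
    }
  }
  norm <- (n - 1) * (n - 2) / 2
  stats::setNames(if (norm > 0) b / norm else b, labs)
}

# Brute-force domination number and all minimum dominating sets, from the
# adjacency matrix alone (no closed_adjacency / solver code reused).
oracle_min_dominating <- function(g) {
  labs <- igraph::V(g)$name
  n <- length(labs)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  diag(A) <- TRUE
  for (k in seq_len(n)) {
    sets <- utils::combn(n, k, simplify = FALSE)
    hits <- Filter(function(s) {
      all(rowSums(A[, s, drop = FALSE]) >= 1)
    }, sets)
    if (length(hits) > 0L) {
      return(list(size = k, sets = lapply(hits, function(s) sort(labs[s]))))
    }
  }
}

# Hypergeometric upper tail P(X >= k) by direct summation of choose() terms.
oracle_hyper_tail <- function(k, n_annot, bigN, bigK) {
  hi <- min(bigK, n_annot)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(n_annot, i) * choose(bigN - n_annot, bigK - i)) /
    choose(bigN, bigK)
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled observations to the two groups.
oracle_ranksum_perm <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  ew <- n1 * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - ew)
  combos <- utils::combn(length(pooled), n1, simplify = FALSE)
  hits <- vapply(combos, function(idx) abs(sum(r[idx]) - ew) >= obs - 1e-9,
                 logical(1L))
  mean(hits)
}

# Small random connected graph for property tests.
random_connected_gnp <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::components(g)$no == 1L) break
  }
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}
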