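#' Jaccard overlap between two node sets
#'
#' `|a intersect b| / |a union b|`, the overlap rate used to compare driver
#' sets (across solvers, gamma values, or models). Both arguments are treated
#' as sets; two empty sets have overlap 1 by convention.
#'
#' @param a,b Character vectors of node labels.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Targeted-attack robustness curve
#'
#' Deletes the given nodes one at a time (callers attacking a driver set
#' should order it by decreasing degree, ties by label) and records, after
#' each deletion, the number of connected components and the size of the
#' largest connected component as a fraction of the *original* node count.
#' A more disruptive node set fragments the network into more components and
#' a smaller largest component, sooner.
#'
#' @param net An `igraph` graph with named vertices.
#' @param targets Character vector of distinct node labels, in deletion
#'   order.
#' @return A data frame with columns `k` (number deleted, starting at 0),
#'   `components`, and `lcc_fraction`.
#' @export
attack_curve <- function(net, targets) {
  labs <- node_labels(net)
  targets <- as.character(targets)
  if (anyDuplicated(targets)) {
    stop("targets must be distinct", call. = FALSE)
  }
  unknown <- setdiff(targets, labs)
  if (length(unknown) > 0L) {
    stop("targets not in the network: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  n0 <- length(labs)
  g <- net
  rows <- vector("list", length(targets) + 1L)
  comp <- igraph::components(g)
  rows[[1L]] <- data.frame(k = 0L, components = comp$no,
                           lcc_fraction = max(comp$csize) / n0)
  for (k in seq_along(targets)) {
    g <- igraph::delete_vertices(g, targets[k])
    if (igraph::vcount(g) == 0L) {
      rows[[k + 1L]] <- data.frame(k = k, components = 0L, lcc_fraction = 0)
    } else {
      comp <- igraph::components(g)
      rows[[k + 1L]] <- data.frame(k = k, components = comp$no,
                                   lcc_fraction = max(comp$csize) / n0)
    }
  }
  do.call(rbind, rows)
}

#' Order a node set for a degree-targeted attack
#'
#' Sorts labels by decreasing degree in `net`, breaking ties by label order,
#' the deletion order used in the robustness analysis.
#'
#' @param net An `igraph` graph with named vertices.
#' @param nodes Character vector of node labels.
#' @return `nodes`, reordered.
#' @export
attack_order <- function(net, nodes) {
  nodes <- as.character(nodes)
  deg <- igraph::degree(net, loops = FALSE)
  names(deg) <- node_labels(net)
  nodes[order(-deg[nodes], nodes, method = "radix")]
}

#' Two-sided Wilcoxon rank-sum comparison of two value populations
#'
#' Compares, e.g., the degrees (or betweenness, or annotation counts) of
#' driver versus non-driver proteins. Mid-ranks are used for ties. When
#' `length(group_in) * length(group_out) <= 400` the exact two-sided p-value
#' is computed from the full permutation null of the rank-sum statistic
#' (a count-by-sum dynamic program equivalent to enumerating all
#' `choose(n, n_in)` group assignments, exact also under ties); otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param group_in,group_out Non-empty numeric vectors.
#' @return A list of class `rank_sum_result` with `statistic` (the rank-sum
#'   `W` of `group_in`), `u` (the Mann-Whitney U), `p_value`, `exact`,
#'   `sidedness` (`"two-sided"`), `n_in`, `n_out`, and `median_difference`
#'   (`median(group_in) - median(group_out)`, the reported direction).
#' @export
rank_sum_compare <- function(group_in, group_out) {
  if (length(group_in) == 0L || length(group_out) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(group_in)
  n2 <- length(group_out)
  r <- rank(c(group_in, group_out)) # mid-ranks
  w <- sum(r[seq_len(n1)])
  ew <- n1 * (n1 + n2 + 1) / 2
  exact <- (n1 * n2) <= 400
  if (exact) {
    # distribution of the rank-sum over all choose(n, n1) assignments;
    # double ranks so mid-ranks become integers
    r2 <- as.integer(round(2 * r))
    maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    counts <- matrix(0, nrow = n1 + 1L, ncol = maxs + 1L)
    counts[1L, 1L] <- 1
    for (x in r2) {
      for (k in rev(seq_len(n1))) {
        nz <- which(counts[k, ] > 0)
        if (length(nz) > 0L) {
          tgt <- nz + x
          keep <- tgt <= maxs + 1L
          counts[k + 1L, tgt[keep]] <- counts[k + 1L, tgt[keep]] +
            counts[k, nz[keep]]
        }
      }
    }
    dist <- counts[n1 + 1L, ]
    sums <- (seq_along(dist) - 1) / 2
    dev <- abs(w - ew)
    p <- sum(dist[abs(sums - ew) >= dev - 1e-9]) / sum(dist)
  } else {
    tie <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(w - ew) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  structure(
    list(statistic = w, u = w - n1 * (n1 + 1) / 2, p_value = p, exact = exact,
         sidedness = "two-sided", n_in = n1, n_out = n2,
         median_difference = stats::median(group_in) - stats::median(group_out)),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat("Wilcoxon rank-sum (", x$sidedness, if (x$exact) ", exact" else
        ", normal approx.", "): W = ", format(x$statistic),
      ", p = ", format(x$p_value),
      ", median difference = ", format(x$median_difference), "\n", sep = "")
  invisible(x)
}

#' One-sided Fisher enrichment of a node set in an annotated gene list
#'
#' Tests over-representation of an annotated gene list (essential genes,
#' aging genes, disease genes, ...) within a driver set, by the one-sided
#' Fisher's exact test: the hypergeometric upper tail `P(X >= k)` of the
#' observed overlap `k` when `|driver|` nodes are drawn from a universe of
#' `N` nodes containing `n_a` annotated ones. Annotations are intersected
#' with the universe (the network's node set) before testing.
#'
#' @param driver Character vector, a subset of `universe`.
#' @param annotated Character vector of annotated labels.
#' @param universe Character vector, the background node set.
#' @return A list of class `enrichment_result` with `overlap_count`,
#'   `set_size`, `annotated_in_universe`, `universe_size`, `odds_ratio`
#'   (sample odds ratio, 0.5 added to every cell when any cell is 0), and
#'   `p_value`.
#' @export
enrichment_test <- function(driver, annotated, universe) {
  driver <- unique(as.character(driver))
  universe <- unique(as.character(universe))
  if (length(setdiff(driver, universe)) > 0L) {
    stop("driver set must be a subset of the universe", call. = FALSE)
  }
  annotated <- intersect(unique(as.character(annotated)), universe)
  k <- length(intersect(driver, annotated))
  bigK <- length(driver)
  na <- length(annotated)
  bigN <- length(universe)
  p <- stats::phyper(k - 1L, na, bigN - na, bigK, lower.tail = FALSE)
  a <- k; b <- bigK - k; cc <- na - k; d <- bigN - bigK - na + k
  if (min(a, b, cc, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  structure(
    list(overlap_count = k, set_size = bigK, annotated_in_universe = na,
         universe_size = bigN, odds_ratio = (a * d) / (b * cc),
         p_value = p, corrected_p = NULL),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment: ", x$overlap_count, "/", x$set_size, " annotated (",
      x$annotated_in_universe, "/", x$universe_size, " in universe), ",
      "OR = ", signif(x$odds_ratio, 4), ", p = ",
      format(x$p_value, digits = 3), sep = "")
  if (!is.null(x$corrected_p)) {
    cat(", Bonferroni p = ", format(x$corrected_p, digits = 3), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Build an annotation map from term-to-protein assignments
#'
#' @param term2proteins Named list mapping each term to a character vector
#'   of protein labels.
#' @return An object of class `annotation_map` with the forward map and its
#'   inverse (`protein2terms`), kept mutually consistent.
#' @export
annotation_map <- function(term2proteins) {
  stopifnot(is.list(term2proteins), !is.null(names(term2proteins)))
  term2proteins <- lapply(term2proteins, function(p) unique(as.character(p)))
  prot <- rep(names(term2proteins), lengths(term2proteins))
  inv <- split(prot, unlist(term2proteins, use.names = FALSE))
  inv <- lapply(inv, unique)
  structure(list(term2proteins = term2proteins, protein2terms = inv),
            class = "annotation_map")
}

#' Read annotations from a TSV or flat gene list
#'
#' Two formats: a two-column TSV (`protein TAB term`) giving a multi-term
#' map, or a flat one-gene-per-line list treated as a single term.
#'
#' @param path Annotation file path.
#' @param flat If `TRUE`, read as a flat gene list.
#' @param term Term label used for a flat list.
#' @return An `annotation_map`.
#' @export
read_annotations <- function(path, flat = FALSE, term = "geneset") {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (flat) {
    m <- list(trimws(lines))
    names(m) <- term
    return(annotation_map(m))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("malformed annotation line (need 'protein TAB term')",
         call. = FALSE)
  }
  prot <- trimws(vapply(fields, `[[`, "", 1L))
  trm <- trimws(vapply(fields, `[[`, "", 2L))
  annotation_map(split(prot, trm))
}

#' Per-term enrichment with Bonferroni correction
#'
#' Runs [enrichment_test()] once per annotation term (terms with no
#' annotated member in the universe are skipped), then applies the
#' Bonferroni correction `min(1, m * p)` with `m` the number of terms
#' actually tested. A term is flagged significant when its corrected
#' p-value falls below `alpha` (default 0.01).
#'
#' @param driver Character vector, a subset of `universe`.
#' @param annotations An `annotation_map`.
#' @param universe Character vector, the background node set.
#' @param alpha Significance level in `(0, 1)` applied to corrected
#'   p-values.
#' @return A data frame with one row per tested term: `term`,
#'   `overlap_count`, `annotated_in_universe`, `odds_ratio`, `p_value`,
#'   `corrected_p`, `significant`; ordered by increasing p-value.
#' @export
term_enrichment <- function(driver, annotations, universe, alpha = 0.01) {
  stopifnot(inherits(annotations, "annotation_map"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  universe <- unique(as.character(universe))
  keep <- vapply(annotations$term2proteins,
                 function(p) length(intersect(p, universe)) > 0L, logical(1L))
  terms <- names(annotations$term2proteins)[keep]
  m <- length(terms)
  if (m == 0L) {
    return(data.frame(term = character(0), overlap_count = integer(0),
                      annotated_in_universe = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      corrected_p = numeric(0), significant = logical(0)))
  }
  rows <- lapply(terms, function(t) {
    e <- enrichment_test(driver, annotations$term2proteins[[t]], universe)
    data.frame(term = t, overlap_count = e$overlap_count,
               annotated_in_universe = e$annotated_in_universe,
               odds_ratio = e$odds_ratio, p_value = e$p_value)
  })
  out <- do.call(rbind, rows)
  out$corrected_p <- pmin(1, m * out$p_value)
  out$significant <- out$corrected_p < alpha
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Count annotation memberships per protein
#'
#' For each protein, the number of terms (complexes, GO annotations, ...)
#' it belongs to; proteins absent from the map count 0. Used to ask whether
#' driver proteins sit in more complexes or carry more functions than
#' non-drivers.
#'
#' @param proteins Character vector of protein labels.
#' @param annotations An `annotation_map`.
#' @return A named integer vector aligned with `proteins`.
#' @export
membership_counts <- function(proteins, annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  proteins <- as.character(proteins)
  counts <- lengths(annotations$protein2terms)
  out <- as.integer(counts[proteins])
  out[is.na(out)] <- 0L
  names(out) <- proteins
  out
}
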