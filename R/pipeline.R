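#' End-to-end driver-protein pipeline
#'
#' Runs the full workflow on one network file: read + canonicalize, extract
#' the largest connected component, compute centralities, select the
#' correction exponent (fixed value or grid search), solve the chosen
#' domination model, and evaluate: per-annotation-file enrichment and a
#' degree-targeted attack curve. All artifacts are written to `out_dir` as
#' deterministic plain-text tables (driver sets sorted by label, fixed
#' column orders), together with a `manifest.txt` recording every numeric
#' choice that affects the result (model, gamma, betweenness floor, grid,
#' solver, seed, package version).
#'
#' @param network Path to an edge-list network file.
#' @param out_dir Output directory (created if missing).
#' @param model `"ccmds"` (default) or `"mds"`.
#' @param gamma `"auto"` (grid search; default) or a fixed non-negative
#'   number. Ignored for `model = "mds"`.
#' @param grid Gamma grid used when `gamma = "auto"`.
#' @param annotations Named character vector of annotation file paths
#'   (flat one-gene-per-line lists); names label the report files.
#' @param sif Pass-through to [read_edge_list()].
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters only for seeded fixture generation
#'   upstream).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the solved `dominating_set`, the selected
#'   gamma, the centrality table, and the paths written.
#' @export
run_pipeline <- function(network, out_dir, model = c("ccmds", "mds"),
                         gamma = "auto", grid = seq(0, 1, by = 0.05),
                         annotations = character(0), sif = FALSE,
                         seed = 1L, quiet = FALSE) {
  model <- match.arg(model)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  net <- read_edge_list(network, sif = sif)
  say("network_io", igraph::vcount(net), " nodes, ", igraph::ecount(net),
      " edges read")
  lcc <- largest_connected_component(net)
  say("network_io", "LCC: ", igraph::vcount(lcc), " nodes, ",
      igraph::ecount(lcc), " edges")

  cent <- node_centrality(lcc)
  say("centrality", "degree and betweenness computed")

  scan <- NULL
  if (model == "mds") {
    gstar <- NA_real_
    ds <- solve_mds(lcc)
  } else if (identical(gamma, "auto")) {
    if (!any(grid == 0)) stop("auto gamma grid must contain 0", call. = FALSE)
    scan <- gamma_scan(lcc, grid = grid, centrality = cent)
    gstar <- select_gamma(scan)
    ds <- scan$sets[[which(scan$grid == gstar)[1L]]]
    say("gamma_selection", "gamma* = ", gstar, " (grid of ", length(grid),
        " points)")
  } else {
    gstar <- as.numeric(gamma)
    ds <- solve_ccmds(lcc, compute_weights(cent, gamma = gstar))
  }
  say("dominating_set", length(ds$members), " driver nodes, objective = ",
      format(ds$objective))

  paths <- list()
  paths$drivers <- file.path(out_dir, "drivers.txt")
  writeLines(sort(ds$members), paths$drivers)

  w_used <- compute_weights(cent, gamma = if (is.na(gstar)) 0 else gstar)
  paths$centrality <- file.path(out_dir, "centrality.tsv")
  write_centrality_table(cent, w_used, paths$centrality)

  if (!is.null(scan)) {
    paths$gamma_scan <- file.path(out_dir, "gamma_scan.tsv")
    write_gamma_scan(scan, paths$gamma_scan)
  }

  universe <- node_labels(lcc)
  for (nm in names(annotations)) {
    ann <- read_annotations(annotations[[nm]], flat = TRUE, term = nm)
    e <- enrichment_test(ds$members, ann$term2proteins[[nm]], universe)
    p <- file.path(out_dir, paste0("enrichment_", nm, ".tsv"))
    tab <- data.frame(annotation = nm, overlap = e$overlap_count,
                      set_size = e$set_size,
                      annotated_in_universe = e$annotated_in_universe,
                      universe_size = e$universe_size,
                      odds_ratio = signif(e$odds_ratio, 6),
                      p_value = signif(e$p_value, 6))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("enrichment_", nm)]] <- p
    say("evaluation", nm, ": overlap ", e$overlap_count, ", p = ",
        format(e$p_value, digits = 3))
  }

  curve <- attack_curve(lcc, attack_order(lcc, ds$members))
  paths$attack <- file.path(out_dir, "attack_curve.tsv")
  utils::write.table(curve, paths$attack, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths$manifest <- file.path(out_dir, "manifest.txt")
  manifest <- c(
    paste0("network=", network),
    paste0("model=", model),
    paste0("gamma=", if (is.na(gstar)) "NA" else format(gstar)),
    paste0("gamma_policy=", if (identical(gamma, "auto")) "auto" else "fixed"),
    paste0("grid=", paste(grid, collapse = ",")),
    paste0("betweenness_floor=", format(w_used$betweenness_floor)),
    paste0("solver=", ds$solver_id),
    paste0("proven_optimal=", ds$proven_optimal),
    paste0("objective=", format(ds$objective)),
    paste0("n_drivers=", length(ds$members)),
    paste0("seed=", seed),
    paste0("version=", as.character(utils::packageVersion("ccmds"))),
    paste0("elapsed_s=", round(as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")), 3))
  )
  writeLines(manifest, paths$manifest)
  say("cli", "artifacts written to ", out_dir)
  invisible(list(dominating_set = ds, gamma = gstar, centrality = cent,
                 scan = scan, paths = paths))
}

#' Write synthetic fixture files
#'
#' Emits the worked-example toy network, a seeded scale-free test network,
#' and a planted-enrichment annotation list as plain-text files, so the
#' command-line workflow can be exercised without any external data.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the random network and annotation draw.
#' @return Invisibly, the named list of paths written.
#' @export
write_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    toy = file.path(out_dir, "toy_network.tsv"),
    random = file.path(out_dir, "random_network.tsv"),
    annotation = file.path(out_dir, "planted_annotation.txt")
  )
  write_edge_list(make_figure1_fixture(), paths$toy)
  g <- random_network("preferential-attachment", n = 200, param = 2,
                      seed = seed)
  write_edge_list(g, paths$random)
  deg <- igraph::degree(g)
  target <- node_labels(g)[order(-deg)][seq_len(50)]
  ann <- planted_annotation(g, target, inside_rate = 0.5, outside_rate = 0.1,
                            seed = seed + 1L)
  writeLines(ann, paths$annotation)
  invisible(paths)
}
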