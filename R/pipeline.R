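#' Configuration for an end-to-end pipeline run
#'
#' Collects every knob of the analysis: the cohort source (a synthetic draw
#' or a delimited file), the three domain variable subsets with their edge
#' thresholds, the visualization threshold used only for exports, bootstrap
#' settings, the missing-data policy and the hyperedge rule. All randomness
#' flows from the single `seed`: the cohort draw and each domain's bootstrap
#' use named substreams derived from it.
#'
#' @param input `"synthetic"` or a path to a cohort CSV (with its metadata
#'   sidecar, see [read_cohort()]).
#' @param n synthetic cohort size (default 93, the study size).
#' @param seed master seed.
#' @param dependence optional [dependence_spec()] for synthesis.
#' @param domains named list of variable subsets (default [domain_presets()];
#'   each subset must include the FA node).
#' @param thresholds named per-domain edge thresholds (defaults 0.2 / 0.2 /
#'   0.3).
#' @param viz_threshold threshold for the visualization GraphML export
#'   (default 0.5).
#' @param bootstrap_B bootstrap replicates per domain (study default 500).
#' @param bootstrap_scheme see [bootstrap_centrality()].
#' @param policy missing-data policy, see [build_matrix()].
#' @param hyperedge_mode see [build_hypergraph()].
#' @param prune_cutoff collinearity cutoff, see [prune_collinear()].
#' @param out_dir output directory, or `NULL` to skip writing artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(input = "synthetic", n = 93L, seed = 1L,
                       dependence = NULL,
                       domains = domain_presets()$domains,
                       thresholds = domain_presets()$thresholds,
                       viz_threshold = 0.5,
                       bootstrap_B = 500L,
                       bootstrap_scheme = "matrix_nodes",
                       policy = "pairwise_complete",
                       hyperedge_mode = "maximal_clique",
                       prune_cutoff = 0.90,
                       out_dir = NULL) {
  stopifnot(all(thresholds >= 0), viz_threshold >= 0, viz_threshold <= 1)
  if (any(thresholds > 1))
    warning("threshold(s) above 1 produce empty-edge networks")
  if (!setequal(names(domains), names(thresholds)))
    stop("domains and thresholds must cover the same names")
  fa_in <- vapply(domains, function(v) "food_addiction" %in% v, logical(1))
  if (!all(fa_in))
    stop("every domain must contain the food_addiction node: ",
         paste(names(domains)[!fa_in], collapse = ", "))
  structure(list(input = input, n = as.integer(n), seed = as.integer(seed),
                 dependence = dependence, domains = domains,
                 thresholds = thresholds, viz_threshold = viz_threshold,
                 bootstrap_B = as.integer(bootstrap_B),
                 bootstrap_scheme = bootstrap_scheme, policy = policy,
                 hyperedge_mode = hyperedge_mode,
                 prune_cutoff = prune_cutoff, out_dir = out_dir),
            class = "run_config")
}

## Named seed substreams: deterministic small offsets from the master seed,
## kept inside 32-bit integer range.
substream_seed <- function(seed, stream) {
  offsets <- c(synthesis = 1L, sociodemographic = 101L, nutritional = 102L,
               metabolic = 103L)
  off <- offsets[[stream]]
  if (is.null(off)) off <- 997L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629)
}

#' Run the full analysis pipeline
#'
#' Synthesizes or loads the cohort, writes the descriptive table, and for
#' each configured domain: builds the mixed-type association matrix, prunes
#' collinear variables, constructs the thresholded graph and hypergraph,
#' computes graph and hypergraph centrality reports, and bootstraps the
#' stability summary. When `config$out_dir` is set, all artifacts are written
#' as delimited text / GraphML / JSON, together with a machine-readable run
#' manifest sufficient to reproduce the run.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with `cohort`, `descriptives`, per-domain results
#'   (`matrix`, `removed`, `graph`, `hypergraph`, `graph_report`,
#'   `hypergraph_report`, `stability`) and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  cohort <- if (identical(config$input, "synthetic")) {
    specs <- default_study_specs()
    dep <- config$dependence %||% default_study_dependence(specs)
    generate_cohort(specs, dep, n = config$n,
                    seed = substream_seed(config$seed, "synthesis"))
  } else {
    read_cohort(config$input)
  }
  say("cohort: ", nrow(cohort$data), " subjects, ", ncol(cohort$data),
      " variables")
  missing_vars <- unlist(lapply(config$domains, setdiff,
                                y = names(cohort$data)))
  if (length(missing_vars))
    stop("domain variable(s) absent from cohort: ",
         paste(unique(missing_vars), collapse = ", "))
  desc <- descriptive_table(cohort)
  results <- list()
  for (dom in names(config$domains)) {
    vars <- config$domains[[dom]]
    thr <- unname(config$thresholds[[dom]])
    sub <- cohort
    sub$data <- cohort$data[, vars, drop = FALSE]
    sub$specs <- cohort$specs[vars]
    m <- build_matrix(sub, policy = config$policy)
    pr <- prune_collinear(m, cutoff = config$prune_cutoff)
    g <- build_graph(pr$matrix, thr)
    h <- build_hypergraph(g, mode = config$hyperedge_mode)
    say(sprintf("%s: %d nodes, %d edges, %d hyperedges (threshold %.2f%s)",
                dom, length(g$nodes), nrow(g$edges), length(h$hyperedges),
                thr,
                if (nrow(pr$removed)) paste0("; pruned ",
                                             nrow(pr$removed)) else ""))
    boot <- bootstrap_centrality(pr$matrix, B = config$bootstrap_B,
                                 scheme = config$bootstrap_scheme,
                                 threshold = thr,
                                 seed = substream_seed(config$seed, dom),
                                 mode = config$hyperedge_mode)
    results[[dom]] <- list(
      matrix = pr$matrix, removed = pr$removed, graph = g, hypergraph = h,
      graph_report = centrality_report(g),
      hypergraph_report = centrality_report(h),
      stability = summarize_stability(boot))
  }
  manifest <- list(
    package_version = as.character(packageVersion("fanet")),
    config = list(
      input = config$input, n = config$n, seed = config$seed,
      thresholds = as.list(config$thresholds),
      viz_threshold = config$viz_threshold,
      bootstrap_B = config$bootstrap_B,
      bootstrap_scheme = config$bootstrap_scheme,
      policy = config$policy, hyperedge_mode = config$hyperedge_mode,
      prune_cutoff = config$prune_cutoff,
      domains = config$domains),
    substream_seeds = c(
      synthesis = substream_seed(config$seed, "synthesis"),
      vapply(names(config$domains), function(d)
        substream_seed(config$seed, d), integer(1))),
    counts = lapply(results, function(r)
      list(nodes = length(r$graph$nodes), edges = nrow(r$graph$edges),
           hyperedges = length(r$hypergraph$hyperedges),
           pruned = nrow(r$removed))))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(config$out_dir, paste0(...))
    write_cohort(cohort, fp("cohort.csv"))
    utils::write.table(desc, fp("descriptives.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (dom in names(results)) {
      r <- results[[dom]]
      utils::write.table(
        data.frame(r$matrix$values, check.names = FALSE),
        fp(dom, "_matrix.tsv"), sep = "\t", quote = FALSE)
      utils::write.table(r$removed, fp(dom, "_pruned.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_edge_list(r$graph, fp(dom, "_edges.tsv"))
      write_graphml(r$graph, fp(dom, "_graph.graphml"))
      viz <- build_graph(r$matrix, config$viz_threshold)
      write_graphml(viz, fp(dom, "_graph_viz.graphml"))
      write_incidence(r$hypergraph, fp(dom, "_hyperedges.json"))
      write_centrality_report(r$graph_report, fp(dom, "_centrality_graph.tsv"))
      write_centrality_report(r$hypergraph_report,
                              fp(dom, "_centrality_hypergraph.tsv"))
      write_stability_summary(r$stability, fp(dom, "_stability.tsv"))
    }
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(c(list(cohort = cohort, descriptives = desc,
                   manifest = manifest), results))
}
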