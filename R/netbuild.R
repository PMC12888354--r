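#' Threshold an association matrix into a graph
#'
#' Nodes are the matrix variables; an edge joins `i` and `j` (i != j) exactly
#' when `|value(i, j)| >= threshold`. Undefined (sentinel) entries never form
#' edges. Isolated nodes are retained.
#'
#' @param matrix an `assoc_matrix` (or plain symmetric numeric matrix).
#' @param threshold edge threshold on the absolute association; associations
#'   lie in `[0, 1]`, so a threshold above 1 yields an edgeless graph (warned
#'   about, but allowed so degenerate configurations propagate cleanly).
#' @return object of class `fa_graph`: list with `nodes`, `adjacency`
#'   (logical matrix), `weights` (absolute association per edge) and `edges`
#'   (data.frame `from`, `to`, `weight`).
#' @examples
#' m <- as_fixture_matrix(c(0.25, 0.15, 0.30), c("A", "B", "C"))
#' build_graph(m, 0.2)$edges
#' @export
build_graph <- function(matrix, threshold) {
  stopifnot(threshold >= 0)
  if (threshold > 1)
    warning("threshold > 1: no association can reach it; graph has no edges")
  vals <- if (inherits(matrix, "assoc_matrix")) matrix$values else
    as.matrix(matrix)
  nodes <- rownames(vals)
  if (is.null(nodes)) {
    nodes <- paste0("V", seq_len(nrow(vals)))
    dimnames(vals) <- list(nodes, nodes)
  }
  a <- abs(vals)
  a[is.na(a)] <- -Inf
  adj <- a >= threshold
  diag(adj) <- FALSE
  w <- abs(vals) * adj
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                      weight = abs(vals)[idx], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, adjacency = adj, weights = w, edges = edges),
            class = "fa_graph")
}

#' @export
print.fa_graph <- function(x, ...) {
  cat("<fa_graph> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

## Small helper to build a named symmetric fixture matrix from the upper
## triangle (row-major), unit diagonal. Exported because tests and examples
## lean on it.
#' Symmetric fixture matrix from upper-triangle values
#' @param upper numeric vector filling the upper triangle row by row.
#' @param nodes node names.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
as_fixture_matrix <- function(upper, nodes) {
  p <- length(nodes)
  m <- diag(p)
  m[upper.tri(m)] <- 0
  k <- 1L
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    m[i, j] <- m[j, i] <- upper[k]; k <- k + 1L
  }
  dimnames(m) <- list(nodes, nodes)
  m
}

#' Build a hypergraph from a thresholded association matrix
#'
#' Hyperedges group variables that are mutually (or jointly) associated above
#' the threshold. Two derivation rules are supported:
#'
#' * `"maximal_clique"` (default): hyperedges are the maximal cliques of the
#'   thresholded graph, size >= 2 — every hyperedge is a set of pairwise
#'   associated variables, capturing polyadic interactions;
#' * `"ego"`: one hyperedge per non-isolated node, the node plus its
#'   neighbors (star-like hyperedges); duplicate sets are collapsed.
#'
#' @param matrix an `assoc_matrix`, plain matrix, or an `fa_graph`.
#' @param threshold edge threshold (ignored when a graph is supplied).
#' @param mode hyperedge derivation rule.
#' @return object of class `fa_hypergraph`: list with `nodes` and
#'   `hyperedges` (named list of sorted character vectors, ids `e1`, `e2`,
#'   ...).
#' @export
build_hypergraph <- function(matrix, threshold = NULL,
                             mode = c("maximal_clique", "ego")) {
  mode <- match.arg(mode)
  g <- if (inherits(matrix, "fa_graph")) matrix else
    build_graph(matrix, threshold)
  edges_list <- if (mode == "maximal_clique") {
    ig <- as_igraph(g)
    lapply(igraph::max_cliques(ig, min = 2),
           function(cl) sort(igraph::V(ig)$name[cl]))
  } else {
    deg <- rowSums(g$adjacency)
    lapply(g$nodes[deg > 0], function(v)
      sort(c(v, g$nodes[g$adjacency[v, ]])))
  }
  edges_list <- unique(edges_list)
  # deterministic ordering: by size then lexicographic member string
  if (length(edges_list)) {
    key <- vapply(edges_list, paste, "", collapse = "|")
    edges_list <- edges_list[order(lengths(edges_list), key)]
    names(edges_list) <- paste0("e", seq_along(edges_list))
  } else names(edges_list) <- character()
  structure(list(nodes = g$nodes, hyperedges = edges_list),
            class = "fa_hypergraph")
}

#' @export
print.fa_hypergraph <- function(x, ...) {
  cat("<fa_hypergraph> ", length(x$nodes), " nodes, ",
      length(x$hyperedges), " hyperedges (sizes: ",
      paste(lengths(x$hyperedges), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Two-section (clique-expansion) graph of a hypergraph
#'
#' Nodes are adjacent exactly when they co-occur in at least one hyperedge.
#' For a maximal-clique hypergraph this reconstructs the thresholded graph it
#' was built from.
#'
#' @param h an `fa_hypergraph`.
#' @return an `fa_graph` (unit edge weights).
#' @export
two_section <- function(h) {
  stopifnot(inherits(h, "fa_hypergraph"))
  p <- length(h$nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(h$nodes, h$nodes))
  for (e in h$hyperedges) {
    adj[e, e] <- TRUE
  }
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = h$nodes[idx[, 1L]], to = h$nodes[idx[, 2L]],
                      weight = rep(1, nrow(idx)), stringsAsFactors = FALSE)
  structure(list(nodes = h$nodes, adjacency = adj,
                 weights = adj * 1, edges = edges),
            class = "fa_graph")
}

## fa_graph -> igraph (named, undirected).
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency * 1, mode = "undirected")
}

#' Export a graph as a tab-separated edge list or GraphML
#'
#' @param g an `fa_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(g, path) {
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = data.frame(name = g$nodes))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export a hypergraph as a JSON incidence list
#'
#' One entry per hyperedge id, listing its member variable names.
#'
#' @param h an `fa_hypergraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(h, path) {
  jsonlite::write_json(
    list(nodes = h$nodes, hyperedges = h$hyperedges),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Domain presets used in the study
#'
#' Variable subsets (each including the FA node) and edge thresholds for the
#' three analysis domains, plus the stricter threshold used only for
#' visualization exports.
#'
#' @param include_sex add `sex` to the sociodemographic domain (the
#'   hypergraph table of the study lists it; the graph table does not).
#' @return list with `domains` (named list of variable-name vectors),
#'   `thresholds` (named numeric) and `viz_threshold`.
#' @export
domain_presets <- function(include_sex = FALSE) {
  socio <- c("food_addiction", "age", "race", "socioeconomic_class")
  if (include_sex) socio <- c(socio, "sex")
  list(
    domains = list(
      sociodemographic = socio,
      nutritional = c("food_addiction", "weight", "height",
                      "waist_circumference", "bmi", "bmi_for_age",
                      "body_fat_pct", "lean_mass", "fat_mass"),
      metabolic = c("food_addiction", "total_cholesterol", "hdl", "ldl",
                    "triglycerides", "glucose", "sbp", "dbp")),
    thresholds = c(sociodemographic = 0.2, nutritional = 0.2,
                   metabolic = 0.3),
    viz_threshold = 0.5)
}
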