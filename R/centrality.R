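## BFS shortest-path distances from every node over a logical adjacency
## matrix. Returns an n x n matrix of hop counts, Inf where unreachable.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ]))
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(nbr[frontier]))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- dist[frontier[1L]] + 1
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Degree centrality
#'
#' Number of direct connections of each node, normalized by `n - 1`.
#'
#' @param g an `fa_graph`.
#' @return named numeric vector in `[0, 1]`.
#' @export
degree_centrality <- function(g) {
  n <- length(g$nodes)
  stopifnot(n >= 2)
  rowSums(g$adjacency) / (n - 1)
}

#' Closeness centrality (Wasserman--Faust)
#'
#' Within-component closeness with component-size scaling: for node `i` in a
#' component of size `n_i`,
#' `CC(i) = ((n_i - 1) / (n - 1)) * ((n_i - 1) / sum_j d(i, j))`, summing
#' shortest-path distances over the component. Isolated nodes have no defined
#' closeness and are returned as `NA`.
#'
#' @param g an `fa_graph`.
#' @return named numeric vector in `[0, 1]`, `NA` for isolated nodes.
#' @export
closeness_centrality <- function(g) {
  n <- length(g$nodes)
  stopifnot(n >= 2)
  d <- bfs_distances(g$adjacency)
  out <- setNames(rep(NA_real_, n), g$nodes)
  for (i in seq_len(n)) {
    reach <- is.finite(d[i, ]) & seq_len(n) != i
    ni <- sum(reach) + 1L
    if (ni == 1L) next  # isolated: undefined
    out[i] <- ((ni - 1) / (n - 1)) * ((ni - 1) / sum(d[i, reach]))
  }
  out
}

#' Betweenness centrality (shortest-path, endpoints excluded)
#'
#' Fraction of shortest paths between other node pairs passing through each
#' node, computed by Brandes' dependency accumulation on the unweighted
#' graph and normalized by `(n - 1)(n - 2) / 2`.
#'
#' @param g an `fa_graph`.
#' @return named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(g) {
  n <- length(g$nodes)
  stopifnot(n >= 2)
  nbr <- lapply(seq_len(n), function(i) which(g$adjacency[i, ]))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    pred <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in nbr[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in pred[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each undirected pair counted from both endpoints
  norm <- (n - 1) * (n - 2) / 2
  setNames(if (norm > 0) bc / norm else bc * 0, g$nodes)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the unweighted adjacency matrix, computed by
#' power iteration from a uniform start (tolerance 1e-10, at most 1000
#' iterations; the iteration runs on `A + I`, which shares eigenvectors with
#' `A` and converges on bipartite graphs too), returned nonnegative with unit
#' Euclidean norm. A graph with
#' no edges has no meaningful eigenvector; an all-zero vector is returned
#' with a warning.
#'
#' @param g an `fa_graph`.
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter iteration cap.
#' @return named numeric vector, unit Euclidean norm (or all zeros).
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 1000L) {
  n <- length(g$nodes)
  a <- g$adjacency * 1
  if (sum(a) == 0) {
    warning("graph has no edges; eigenvector centrality undefined (zeros)")
    return(setNames(numeric(n), g$nodes))
  }
  v <- rep(1 / sqrt(n), n)
  # iterate on A + I: same principal eigenvector as A, but the dominant
  # eigenvalue is strictly largest in magnitude, so the iteration cannot
  # oscillate on bipartite graphs
  for (it in seq_len(max_iter)) {
    nv <- as.vector(a %*% v) + v
    nv <- nv / sqrt(sum(nv^2))
    if (max(abs(nv - v)) < tol) { v <- nv; break }
    v <- nv
  }
  v <- abs(v)
  setNames(v / sqrt(sum(v^2)), g$nodes)
}

#' Centrality of hypergraph nodes
#'
#' Computes one of the four measures on a representation of the hypergraph:
#'
#' * `"two_section"` (default): the clique-expansion graph — nodes adjacent
#'   iff they share at least one hyperedge — with the same normalizations as
#'   the plain-graph measures;
#' * `"bipartite"`: the node--hyperedge incidence graph; the measure is
#'   computed on the bipartite graph and restricted back to the variable
#'   nodes (hyperedge vertices are dropped from the result).
#'
#' @param h an `fa_hypergraph`.
#' @param measure one of `"degree"`, `"closeness"`, `"betweenness"`,
#'   `"eigenvector"`.
#' @param representation `"two_section"` or `"bipartite"`.
#' @return named numeric vector over the hypergraph nodes.
#' @export
hypergraph_centrality <- function(h,
                                  measure = c("degree", "closeness",
                                              "betweenness", "eigenvector"),
                                  representation = c("two_section",
                                                     "bipartite")) {
  measure <- match.arg(measure)
  representation <- match.arg(representation)
  fn <- switch(measure,
               degree = degree_centrality,
               closeness = closeness_centrality,
               betweenness = betweenness_centrality,
               eigenvector = eigenvector_centrality)
  if (representation == "two_section") {
    g <- two_section(h)
    if (measure == "eigenvector" && nrow(g$edges) == 0)
      return(setNames(numeric(length(h$nodes)), h$nodes))
    return(fn(g))
  }
  # bipartite incidence graph: variable nodes + one vertex per hyperedge
  enames <- names(h$hyperedges)
  all_v <- c(h$nodes, enames)
  p <- length(all_v)
  adj <- matrix(FALSE, p, p, dimnames = list(all_v, all_v))
  for (e in enames) {
    adj[e, h$hyperedges[[e]]] <- TRUE
    adj[h$hyperedges[[e]], e] <- TRUE
  }
  g <- structure(list(nodes = all_v, adjacency = adj, weights = adj * 1,
                      edges = data.frame()), class = "fa_graph")
  if (measure == "eigenvector" && sum(adj) == 0)
    return(setNames(numeric(length(h$nodes)), h$nodes))
  fn(g)[h$nodes]
}

#' Classify centrality strength
#'
#' Values at or below 0.3 are `"weak"`, at or above 0.7 `"strong"`, and the
#' stated moderate band is 0.4--0.6; values falling in the unstated gaps
#' (0.3, 0.4) and (0.6, 0.7) are completed to the nearest band, `"moderate"`.
#' `NA` values (undefined closeness) stay `NA`.
#'
#' @param v numeric vector in `[0, 1]`.
#' @return character vector of labels.
#' @export
classify_strength <- function(v) {
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("centrality values must lie in [0, 1]")
  ifelse(is.na(v), NA_character_,
         ifelse(v <= 0.3, "weak", ifelse(v >= 0.7, "strong", "moderate")))
}

#' Four-measure centrality report with strength labels
#'
#' One row per node with degree, closeness, betweenness and eigenvector
#' centrality plus a weak/moderate/strong label per value (the published
#' table layout).
#'
#' @param x an `fa_graph` or `fa_hypergraph`.
#' @param representation hypergraph representation passed to
#'   [hypergraph_centrality()].
#' @return data.frame with columns `node`, the four measures and
#'   `<measure>_strength` labels.
#' @export
centrality_report <- function(x, representation = "two_section") {
  measures <- c("degree", "closeness", "betweenness", "eigenvector")
  vals <- if (inherits(x, "fa_hypergraph")) {
    lapply(measures, function(m)
      hypergraph_centrality(x, m, representation))
  } else if (inherits(x, "fa_graph")) {
    if (nrow(x$edges) == 0) {
      ecv <- setNames(numeric(length(x$nodes)), x$nodes)
      list(degree_centrality(x), closeness_centrality(x),
           betweenness_centrality(x), ecv)
    } else {
      list(degree_centrality(x), closeness_centrality(x),
           betweenness_centrality(x), eigenvector_centrality(x))
    }
  } else stop("x must be an fa_graph or fa_hypergraph")
  names(vals) <- measures
  nodes <- if (inherits(x, "fa_hypergraph")) x$nodes else x$nodes
  out <- data.frame(node = nodes, stringsAsFactors = FALSE)
  for (m in measures) {
    out[[m]] <- unname(vals[[m]][nodes])
    out[[paste0(m, "_strength")]] <- classify_strength(out[[m]])
  }
  out
}

#' Write a centrality report as delimited text
#'
#' @param report data.frame from [centrality_report()].
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_centrality_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
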