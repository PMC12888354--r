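# Shared fixtures: small graphs, random generators and independent oracles.

# fa_graph from an explicit adjacency matrix (logical or 0/1)
graph_from_adj <- function(adj, nodes = NULL) {
  adj <- adj > 0
  diag(adj) <- FALSE
  if (is.null(nodes)) nodes <- rownames(adj) %||% paste0("n", seq_len(nrow(adj)))
  dimnames(adj) <- list(nodes, nodes)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure(list(nodes = nodes, adjacency = adj, weights = adj * 1,
                 edges = data.frame(from = nodes[idx[, 1]],
                                    to = nodes[idx[, 2]],
                                    weight = rep(1, nrow(idx)),
                                    stringsAsFactors = FALSE)),
            class = "fa_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# star with a hub and k leaves
star_graph <- function(k = 3) {
  n <- k + 1
  adj <- matrix(FALSE, n, n)
  adj[1, -1] <- adj[-1, 1] <- TRUE
  graph_from_adj(adj, c("hub", paste0("leaf", seq_len(k))))
}

complete_graph <- function(n) {
  adj <- matrix(TRUE, n, n)
  graph_from_adj(adj, LETTERS[seq_len(n)])
}

path_graph <- function(n = 3) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  graph_from_adj(adj, LETTERS[seq_len(n)])
}

# adjacency matrix of the graph with edge bitmask `mask` on n nodes
adj_from_mask <- function(mask, n) {
  adj <- matrix(FALSE, n, n)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  on <- as.logical(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)))
  for (k in which(on)) {
    adj[pairs[k, 1], pairs[k, 2]] <- TRUE
    adj[pairs[k, 2], pairs[k, 1]] <- TRUE
  }
  adj
}

random_symmetric_matrix <- function(p, seed) {
  set.seed(seed)
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- runif(p * (p - 1) / 2)
  m <- m + t(m)
  diag(m) <- 1
  dimnames(m) <- list(paste0("V", seq_len(p)), paste0("V", seq_len(p)))
  m
}

# --- independent oracles (igraph-based, C implementations) ---

igraph_of <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency * 1, mode = "undirected")
}

oracle_betweenness <- function(g) {
  n <- length(g$nodes)
  raw <- igraph::betweenness(igraph_of(g), directed = FALSE)
  norm <- (n - 1) * (n - 2) / 2
  setNames(if (norm > 0) as.numeric(raw) / norm else raw * 0, g$nodes)
}

# Wasserman-Faust closeness from an independent distance computation
oracle_closeness <- function(g) {
  n <- length(g$nodes)
  d <- igraph::distances(igraph_of(g))
  out <- setNames(rep(NA_real_, n), g$nodes)
  for (i in seq_len(n)) {
    reach <- is.finite(d[i, ]) & seq_len(n) != i
    ni <- sum(reach) + 1
    if (ni > 1)
      out[i] <- ((ni - 1) / (n - 1)) * ((ni - 1) / sum(d[i, reach]))
  }
  out
}

oracle_eigenvector <- function(g) {
  v <- igraph::eigen_centrality(igraph_of(g))$vector
  v <- abs(as.numeric(v))
  setNames(v / sqrt(sum(v^2)), g$nodes)
}

# endorsement vector helper: logical(25) with the given items endorsed
endorsed <- function(items = integer()) {
  e <- rep(FALSE, 25)
  e[items] <- TRUE
  e
}

# tiny all-continuous cohort from a data.frame
continuous_cohort <- function(df) {
  specs <- lapply(names(df), function(nm)
    variable_spec(nm, "continuous",
                  list(shape = "symmetric", mean = 0, sd = 1)))
  names(specs) <- names(df)
  structure(list(data = df, specs = specs), class = "fa_cohort")
}
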