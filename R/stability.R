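CENTRALITY_MEASURES <- c("degree", "closeness", "betweenness", "eigenvector")

## All four hypergraph centralities of an association (sub)matrix at a
## threshold; returns a named list of named vectors, or NULL when the
## submatrix has fewer than 2 variables.
hypergraph_centralities_of <- function(values, threshold, mode,
                                       representation = "two_section") {
  if (nrow(values) < 2L) return(NULL)
  h <- build_hypergraph(values, threshold, mode = mode)
  setNames(lapply(CENTRALITY_MEASURES, function(m)
    suppressWarnings(hypergraph_centrality(h, m, representation))),
    CENTRALITY_MEASURES)
}

#' Bootstrap hypergraph centralities
#'
#' Generates `B` bootstrap replicates of the network and recomputes the four
#' hypergraph centrality measures on each. Resampling schemes:
#'
#' * `"matrix_nodes"` (default): the rows/columns of the association matrix
#'   are resampled with replacement; the replicate network is built on the
#'   unique set of drawn variables (a duplicated node adds no structure to an
#'   unweighted graph);
#' * `"subjects"`: subjects are resampled with replacement and the
#'   association matrix is rebuilt from scratch (requires an `fa_cohort`);
#' * `"identity"`: a test hook that returns the full node set unchanged in
#'   every replicate.
#'
#' Replicates with fewer than 2 unique nodes are recorded as degenerate and
#' excluded from summaries. Each replicate draws from an independent
#' substream of the master seed, so the same seed reproduces the same
#' replicate set exactly.
#'
#' @param input an `assoc_matrix` (schemes `"matrix_nodes"`, `"identity"`)
#'   or an `fa_cohort` (any scheme; the matrix is built with `policy`).
#' @param B number of bootstrap replicates (study default 500).
#' @param scheme resampling scheme.
#' @param threshold edge threshold for network construction.
#' @param seed master seed.
#' @param mode hyperedge derivation rule, see [build_hypergraph()].
#' @param policy missing-data policy when building matrices from a cohort.
#' @return object of class `fa_bootstrap`: list with `original` (list of four
#'   named centrality vectors), `replicates` (per-replicate lists),
#'   `indices` (B x 4 matrix of Spearman stability indices vs the original),
#'   `degenerate` (logical vector) and the call parameters.
#' @export
bootstrap_centrality <- function(input, B = 500L,
                                 scheme = c("matrix_nodes", "subjects",
                                            "identity"),
                                 threshold = 0.2, seed = 1L,
                                 mode = "maximal_clique",
                                 policy = "pairwise_complete") {
  scheme <- match.arg(scheme)
  stopifnot(B >= 1L)
  if (scheme == "subjects" && !inherits(input, "fa_cohort"))
    stop("scheme 'subjects' needs an fa_cohort input")
  base_matrix <- if (inherits(input, "fa_cohort"))
    build_matrix(input, policy = policy) else input
  stopifnot(inherits(base_matrix, "assoc_matrix"))
  vals <- base_matrix$values
  original <- hypergraph_centralities_of(vals, threshold, mode)
  if (is.null(original)) stop("need at least 2 variables")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  p <- nrow(vals)
  replicates <- vector("list", B)
  degenerate <- logical(B)
  indices <- matrix(NA_real_, B, 4L,
                    dimnames = list(NULL, CENTRALITY_MEASURES))
  for (r in seq_len(B)) {
    set.seed(rep_seeds[r])
    cent <- switch(scheme,
      identity = original,
      matrix_nodes = {
        u <- sort(unique(sample.int(p, p, replace = TRUE)))
        if (length(u) < 2L) NULL else
          hypergraph_centralities_of(vals[u, u, drop = FALSE], threshold,
                                     mode)
      },
      subjects = {
        n <- nrow(input$data)
        boot <- input
        boot$data <- input$data[sample.int(n, n, replace = TRUE), ,
                                drop = FALSE]
        m <- build_matrix(boot, policy = policy)
        hypergraph_centralities_of(m$values, threshold, mode)
      })
    if (is.null(cent)) { degenerate[r] <- TRUE; next }
    replicates[[r]] <- cent
    for (m in CENTRALITY_MEASURES)
      indices[r, m] <- stability_index(original[[m]], cent[[m]])
  }
  structure(list(original = original, replicates = replicates,
                 indices = indices, degenerate = degenerate,
                 B = B, scheme = scheme, threshold = threshold,
                 mode = mode, seed = seed),
            class = "fa_bootstrap")
}

#' @export
print.fa_bootstrap <- function(x, ...) {
  cat("<fa_bootstrap> B = ", x$B, " (", sum(x$degenerate),
      " degenerate), scheme = ", x$scheme, ", threshold = ", x$threshold,
      "\n", sep = "")
  invisible(x)
}

#' Spearman stability index between original and replicate centralities
#'
#' Spearman rank correlation (ties mid-ranked) over the nodes present and
#' defined in both vectors. Replicates sharing fewer than 3 defined nodes
#' with the original have no meaningful rank correlation and return `NA`.
#'
#' @param original,replicate named numeric centrality vectors.
#' @return Spearman correlation in `[-1, 1]`, or `NA`.
#' @export
stability_index <- function(original, replicate) {
  shared <- intersect(names(original), names(replicate))
  x <- original[shared]; y <- replicate[shared]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  suppressWarnings(cor(x, y, method = "spearman"))
}

#' Summarize bootstrap stability indices
#'
#' One row per centrality measure plus a pooled row across measures, in the
#' published summary layout: mean, SD (sample), median, 25th and 75th
#' percentiles (linear interpolation), min, max and the number of valid
#' replicates.
#'
#' @param x an `fa_bootstrap`, or a numeric matrix of per-replicate indices
#'   with one column per measure.
#' @return data.frame with columns `centrality`, `mean_rs`, `sd`, `median`,
#'   `p25`, `p75`, `min`, `max`, `n`.
#' @export
summarize_stability <- function(x) {
  idx <- if (inherits(x, "fa_bootstrap")) x$indices else as.matrix(x)
  if (is.null(colnames(idx)))
    colnames(idx) <- CENTRALITY_MEASURES[seq_len(ncol(idx))]
  row_of <- function(v, label) {
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(centrality = label, mean_rs = NA, sd = NA,
                        median = NA, p25 = NA, p75 = NA, min = NA, max = NA,
                        n = 0L, stringsAsFactors = FALSE))
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(centrality = label, mean_rs = mean(v),
               sd = if (length(v) > 1) sd(v) else 0,
               median = median(v), p25 = q[1L], p75 = q[2L],
               min = min(v), max = max(v), n = length(v),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(colnames(idx), function(m)
    row_of(idx[, m], m)))
  rbind(out, row_of(as.vector(idx), "pooled"))
}

#' Write a stability summary as delimited text
#'
#' @param summary data.frame from [summarize_stability()].
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_stability_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
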