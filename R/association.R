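#' Pearson product-moment correlation with pairwise-complete handling
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @return the correlation in `[-1, 1]`, or `NA` (undefined-entry sentinel)
#'   when fewer than 3 complete pairs remain or either vector has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Cramer's V for a contingency table
#'
#' `V = sqrt(chi^2 / (N * min(r - 1, c - 1)))` with the chi-square statistic
#' computed *without* continuity correction; rows and columns with zero
#' margins are dropped first.
#'
#' @param table matrix of contingency counts (or a `table`).
#' @return V in `[0, 1]`, or `NA` when fewer than 2 rows or columns with
#'   nonzero margins remain.
#' @examples
#' cramers_v(matrix(c(8, 34, 16, 35), nrow = 2, byrow = TRUE))  # ~0.140
#' @export
cramers_v <- function(table) {
  tab <- as.matrix(table)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  chi2 <- suppressWarnings(
    unname(chisq.test(tab, correct = FALSE)$statistic))
  v2 <- chi2 / (sum(tab) * min(nrow(tab) - 1L, ncol(tab) - 1L))
  sqrt(max(0, min(1, v2)))
}

#' Eta-squared from one-way ANOVA
#'
#' The proportion of the continuous variable's variance explained by group
#' membership: `SS_between / SS_total`.
#'
#' @param x numeric vector.
#' @param g group labels (factor or coercible); pairs with a missing value in
#'   either are dropped.
#' @return eta-squared in `[0, 1]`, or `NA` when fewer than 2 non-empty
#'   groups remain or the total variance is zero.
#' @export
eta_squared <- function(x, g) {
  ok <- complete.cases(x, g)
  x <- x[ok]; g <- droplevels(factor(g[ok]))
  if (nlevels(g) < 2L || length(x) < 3L) return(NA_real_)
  ss_total <- sum((x - mean(x))^2)
  if (ss_total == 0) return(NA_real_)
  gm <- tapply(x, g, mean)
  gn <- tapply(x, g, length)
  ss_between <- sum(gn * (gm - mean(x))^2)
  max(0, min(1, ss_between / ss_total))
}

#' Build the mixed-type association matrix of a cohort
#'
#' Per-pair method selection follows the declared variable kinds:
#' continuous--continuous pairs use Pearson's r, categorical--categorical
#' pairs Cramer's V, and continuous--categorical pairs eta-squared from
#' one-way ANOVA. The missing-data policy is applied before computation:
#'
#' * `"pairwise_complete"` (default): complete-case analysis per entry —
#'   each pair uses all subjects observed on both variables;
#' * `"listwise"`: subjects with any missing value are dropped up front;
#' * `"mean_impute"`: missing continuous cells are replaced by the column
#'   mean (sensitivity-analysis policy).
#'
#' Independently of the continuous policy, missing cells of *binary*
#' variables are replaced by the variable's first (reference) level when
#' `binary_zero_fill = TRUE`, reading absence of a record as absence of the
#' condition.
#'
#' @param cohort an `fa_cohort`.
#' @param policy missing-data policy for continuous variables.
#' @param binary_zero_fill replace missing binary cells with the reference
#'   level (default `TRUE`).
#' @return object of class `assoc_matrix`: list with `values` (symmetric
#'   numeric matrix, unit diagonal; Pearson entries keep their sign),
#'   `method` (character matrix of per-entry method labels), `n_used`
#'   (integer matrix of subjects contributing per entry), `variables` and
#'   `kinds`.
#' @export
build_matrix <- function(cohort,
                         policy = c("pairwise_complete", "listwise",
                                    "mean_impute"),
                         binary_zero_fill = TRUE) {
  policy <- match.arg(policy)
  stopifnot(inherits(cohort, "fa_cohort"))
  kinds <- cohort_kinds(cohort)
  if (length(kinds) < 2L) stop("need at least 2 variables")
  d <- cohort$data
  all_missing <- vapply(d, function(col) all(is.na(col)), logical(1))
  if (any(all_missing))
    stop("variable(s) entirely missing: ",
         paste(names(d)[all_missing], collapse = ", "))
  if (binary_zero_fill) {
    for (nm in names(kinds)[kinds == "binary"]) {
      lv <- levels(d[[nm]])
      d[[nm]][is.na(d[[nm]])] <- lv[1L]
    }
  }
  if (policy == "listwise") d <- d[complete.cases(d), , drop = FALSE]
  if (policy == "mean_impute") {
    for (nm in names(kinds)[kinds == "continuous"]) {
      miss <- is.na(d[[nm]])
      d[[nm]][miss] <- mean(d[[nm]], na.rm = TRUE)
    }
  }
  p <- length(kinds)
  vars <- names(kinds)
  values <- diag(p)
  method <- matrix("", p, p, dimnames = list(vars, vars))
  n_used <- matrix(nrow(d), p, p, dimnames = list(vars, vars))
  dimnames(values) <- list(vars, vars)
  diag(method) <- "identity"
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    xi <- d[[i]]; xj <- d[[j]]
    ok <- complete.cases(xi, xj)
    n_used[i, j] <- n_used[j, i] <- sum(ok)
    ci <- kinds[i] == "continuous"; cj <- kinds[j] == "continuous"
    if (ci && cj) {
      v <- pearson_r(xi, xj); m <- "pearson"
    } else if (!ci && !cj) {
      v <- cramers_v(table(xi, xj)); m <- "cramers_v"
    } else {
      if (ci) v <- eta_squared(xi, xj) else v <- eta_squared(xj, xi)
      m <- "eta_squared"
    }
    values[i, j] <- values[j, i] <- v
    method[i, j] <- method[j, i] <- m
  }
  structure(list(values = values, method = method, n_used = n_used,
                 variables = vars, kinds = kinds),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, digits = 3, ...) {
  cat("<assoc_matrix> ", length(x$variables), " variables (",
      sum(x$method == "pearson") / 2, " pearson, ",
      sum(x$method == "cramers_v") / 2, " cramers_v, ",
      sum(x$method == "eta_squared") / 2, " eta_squared)\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

## Construct an assoc_matrix directly from a numeric matrix (tests, fixtures).
as_assoc_matrix <- function(values, method = "pearson") {
  values <- as.matrix(values)
  vars <- rownames(values)
  if (is.null(vars)) {
    vars <- paste0("V", seq_len(nrow(values)))
    dimnames(values) <- list(vars, vars)
  }
  p <- nrow(values)
  structure(list(values = values,
                 method = matrix(method, p, p, dimnames = dimnames(values)),
                 n_used = matrix(NA_integer_, p, p,
                                 dimnames = dimnames(values)),
                 variables = vars,
                 kinds = setNames(rep("continuous", p), vars)),
            class = "assoc_matrix")
}

#' Remove collinear variables from an association matrix
#'
#' While any off-diagonal entry satisfies `|value| >= cutoff`, the pair with
#' the largest absolute association is located and *one* of its members is
#' removed: the variable with the larger mean absolute association to all
#' other remaining variables (ties broken toward the later variable in
#' declared order). The result never contains an off-diagonal entry at or
#' above the cutoff, and the operation is idempotent.
#'
#' @param matrix an `assoc_matrix`.
#' @param cutoff collinearity cutoff on the absolute association
#'   (default 0.90).
#' @return list with `matrix` (the pruned `assoc_matrix`) and `removed`
#'   (data.frame of dropped variables, their triggering partner and the
#'   offending value).
#' @export
prune_collinear <- function(matrix, cutoff = 0.90) {
  stopifnot(inherits(matrix, "assoc_matrix"))
  keep <- matrix$variables
  removed <- data.frame(variable = character(), partner = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  repeat {
    v <- abs(matrix$values[keep, keep, drop = FALSE])
    diag(v) <- 0
    v[is.na(v)] <- 0
    if (length(keep) < 2L || max(v) < cutoff) break
    idx <- which(v == max(v), arr.ind = TRUE)[1L, ]
    a <- keep[idx[1L]]; b <- keep[idx[2L]]
    mean_abs <- function(nm) mean(v[nm, setdiff(keep, nm)])
    drop_var <- if (mean_abs(a) > mean_abs(b)) a
    else if (mean_abs(b) > mean_abs(a)) b
    else keep[max(idx)]  # tie: later variable in declared order
    partner <- if (drop_var == a) b else a
    removed <- rbind(removed, data.frame(
      variable = drop_var, partner = partner,
      value = matrix$values[drop_var, partner], stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop_var)
  }
  out <- matrix
  out$values <- matrix$values[keep, keep, drop = FALSE]
  out$method <- matrix$method[keep, keep, drop = FALSE]
  out$n_used <- matrix$n_used[keep, keep, drop = FALSE]
  out$variables <- keep
  out$kinds <- matrix$kinds[keep]
  list(matrix = out, removed = removed)
}

#' Per-node centrality shift between two analysis variants
#'
#' Convenience for sensitivity analyses (e.g. mean imputation vs complete
#' case): computes the absolute per-node difference for each centrality
#' measure between two [centrality_report()] data.frames.
#'
#' @param a,b centrality reports over the same nodes.
#' @return data.frame of per-node absolute deltas per measure.
#' @export
centrality_shift <- function(a, b) {
  stopifnot(setequal(a$node, b$node))
  b <- b[match(a$node, b$node), ]
  measures <- c("degree", "closeness", "betweenness", "eigenvector")
  out <- data.frame(node = a$node, stringsAsFactors = FALSE)
  for (m in measures) out[[paste0("delta_", m)]] <- abs(a[[m]] - b[[m]])
  out
}
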