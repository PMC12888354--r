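#' Normality verdict for a continuous variable
#'
#' Default method is the one-sample Kolmogorov--Smirnov test against a normal
#' distribution with the sample mean and SD; the variable is called normal
#' when `p > alpha`. KS with estimated parameters is anti-conservative;
#' the Lilliefors correction is available as `method = "lilliefors"`
#' (requires the nortest package).
#'
#' @param x numeric vector, `n >= 4` after dropping missing values.
#' @param alpha significance level (default 0.05).
#' @param method `"ks"` (default) or `"lilliefors"`.
#' @return list with `normal` (logical), `statistic`, `p_value`, `method`.
#' @export
normality_check <- function(x, alpha = 0.05, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 4L) stop("need at least 4 non-missing observations")
  if (sd(x) == 0) {
    warning("constant vector: treated as non-normal")
    return(list(normal = FALSE, statistic = NA_real_, p_value = 0,
                method = method))
  }
  if (method == "lilliefors") {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("method 'lilliefors' requires the nortest package")
    t <- nortest::lillie.test(x)
  } else {
    t <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  }
  list(normal = t$p.value > alpha, statistic = unname(t$statistic),
       p_value = t$p.value, method = method)
}

#' Two-group comparison with automatic test selection
#'
#' Categorical variables are compared with the chi-square test of
#' independence *without* continuity correction (the dialect that reproduces
#' the published p-values); continuous variables use Student's t-test when
#' both groups pass the normality check and the Mann--Whitney test otherwise
#' (exact when both groups have at most 20 untied observations, normal
#' approximation with tie correction above that).
#'
#' @param x variable values (numeric, or factor/character for categorical).
#' @param g grouping vector with exactly two non-empty groups.
#' @param kind optional explicit kind (`"continuous"` or a categorical kind);
#'   inferred from `x` when missing.
#' @param alpha normality significance level.
#' @param normal optional externally supplied normality verdict for a
#'   continuous variable (e.g. the pooled verdict that also chose the summary
#'   style); when `NULL`, both groups are checked separately.
#' @return list with `test` (name), `statistic`, `p_value` and, for
#'   continuous variables, `normal` (the verdict driving selection).
#' @export
group_compare <- function(x, g, kind = NULL, alpha = 0.05, normal = NULL) {
  ok <- complete.cases(x, g)
  x <- x[ok]
  g <- droplevels(factor(g[ok]))
  if (nlevels(g) != 2L) stop("need exactly two non-empty groups")
  if (is.null(kind))
    kind <- if (is.numeric(x)) "continuous" else "categorical"
  if (kind != "continuous") {
    t <- suppressWarnings(chisq.test(table(x, g), correct = FALSE))
    return(list(test = "chi-square", statistic = unname(t$statistic),
                p_value = t$p.value))
  }
  xs <- split(x, g)
  if (any(lengths(xs) < 2L)) stop("degenerate group sizes")
  if (is.null(normal))
    normal <- all(vapply(xs, function(v)
      length(v) >= 4L && normality_check(v, alpha)$normal, logical(1)))
  if (normal) {
    t <- t.test(xs[[1L]], xs[[2L]], var.equal = TRUE)
    list(test = "t-test", statistic = unname(t$statistic),
         p_value = t$p.value, normal = TRUE)
  } else {
    small <- max(lengths(xs)) <= 20L && !anyDuplicated(x)
    t <- suppressWarnings(
      wilcox.test(xs[[1L]], xs[[2L]], exact = small, correct = !small))
    list(test = "mann-whitney", statistic = unname(t$statistic),
         p_value = t$p.value, normal = FALSE)
  }
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k - 1) * (1 - sum(item variances) / variance(total score))`
#' with sample variances.
#'
#' @param items numeric matrix or data.frame, subjects x items (k >= 2
#'   items, >= 2 subjects).
#' @return alpha (at most 1; can be negative for incoherent item sets).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2L || nrow(m) < 2L)
    stop("need at least 2 items and 2 subjects")
  m <- m[complete.cases(m), , drop = FALSE]
  total_var <- var(rowSums(m))
  if (total_var == 0) stop("zero total-score variance")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

## Exact power of the two-sided two-sample t-test at equal group size n,
## effect size d, via the noncentral t distribution.
ttest_power <- function(n_per_group, d, alpha) {
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  crit <- qt(1 - alpha / 2, df)
  pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
}

#' A priori sample size for a two-sample t-test
#'
#' Smallest equal per-group size whose two-sided two-sample t-test power
#' (noncentral-t, exact) reaches the target; returns the total sample size
#' (twice the per-group size).
#'
#' @param effect_size_d standardized mean difference (Cohen's d), > 0.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return total sample size (integer, 2 x per-group n).
#' @examples
#' sample_size_ttest(0.6, 0.05, 0.8)  # 90
#' @export
sample_size_ttest <- function(effect_size_d, alpha = 0.05, power = 0.8) {
  stopifnot(effect_size_d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  while (ttest_power(n, effect_size_d, alpha) < power) n <- n + 1L
  2L * n
}

#' Minimum sample size from the participants-per-node rule
#'
#' Network analyses commonly require a fixed number of participants per
#' network node; the minimum sample is the product of the largest network
#' size and the per-node requirement.
#'
#' @param max_network_size number of nodes in the largest analyzed network.
#' @param per_node participants required per node (default 10).
#' @return minimum total sample size.
#' @export
nodes_rule_min_n <- function(max_network_size, per_node = 10L) {
  stopifnot(max_network_size >= 1, per_node >= 1)
  as.integer(max_network_size) * as.integer(per_node)
}

#' The published food-addiction by sex contingency table
#'
#' Counts from the study's descriptive table: 8 of 42 girls and 16 of 51
#' boys with a positive FA diagnosis.
#'
#' @return 2 x 2 integer matrix, FA status (yes/no) by sex (girls/boys).
#' @export
study_fa_by_sex <- function() {
  matrix(c(8L, 34L, 16L, 35L), nrow = 2,
         dimnames = list(fa = c("yes", "no"), sex = c("girls", "boys")))
}

#' Descriptive cohort table with group comparisons
#'
#' One row per variable: categorical variables report per-group counts and
#' percentages with a chi-square p-value; continuous variables report
#' mean (SD) when the pooled normality check passes and median (min--max)
#' otherwise, with the matching t-test / Mann--Whitney p-value.
#'
#' @param cohort an `fa_cohort`.
#' @param group name of the two-level grouping variable (default `"sex"`).
#' @param alpha normality significance level.
#' @return data.frame with columns `variable`, `level`, per-group summary
#'   strings, `style`, `test` and `p_value` (3 decimals).
#' @export
descriptive_table <- function(cohort, group = "sex", alpha = 0.05) {
  stopifnot(inherits(cohort, "fa_cohort"), group %in% names(cohort$data))
  g <- droplevels(factor(cohort$data[[group]]))
  if (nlevels(g) != 2L) stop("grouping variable must have two levels")
  glev <- levels(g)
  kinds <- cohort_kinds(cohort)
  rows <- list()
  for (nm in setdiff(names(kinds), group)) {
    x <- cohort$data[[nm]]
    # one pooled normality verdict drives both the summary style and the
    # choice between t-test and Mann-Whitney
    pooled_normal <- if (kinds[nm] == "continuous")
      isTRUE(tryCatch(normality_check(x, alpha)$normal,
                      error = function(e) FALSE)) else NULL
    cmp <- tryCatch(group_compare(x, g, kind = kinds[nm], alpha = alpha,
                                  normal = pooled_normal),
                    error = function(e) list(test = "none",
                                             p_value = NA_real_))
    pstr <- ifelse(is.na(cmp$p_value), NA_character_,
                   sprintf("%.3f", cmp$p_value))
    if (kinds[nm] != "continuous") {
      tab <- table(x, g)
      for (lv in rownames(tab)) {
        cell <- function(grp) sprintf("%d (%.1f)", tab[lv, grp],
                                      100 * tab[lv, grp] / sum(tab[, grp]))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = nm, level = lv,
          group1 = cell(glev[1L]), group2 = cell(glev[2L]),
          style = "n (%)", test = cmp$test, p_value = pstr,
          stringsAsFactors = FALSE)
      }
    } else {
      normal <- pooled_normal
      cell <- function(grp) {
        v <- x[g == grp & !is.na(x)]
        if (normal) sprintf("%.1f ± %.1f", mean(v), sd(v))
        else sprintf("%.1f (%.1f–%.1f)", median(v), min(v), max(v))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = "",
        group1 = cell(glev[1L]), group2 = cell(glev[2L]),
        style = if (normal) "mean (SD)" else "median (min-max)",
        test = cmp$test, p_value = pstr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group1"] <- glev[1L]
  names(out)[names(out) == "group2"] <- glev[2L]
  out
}
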