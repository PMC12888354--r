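test_that("pearson_r matches hand computations and guards degeneracy", {
  expect_equal(pearson_r(1:3, 1:3), 1.0)
  expect_equal(pearson_r(1:3, 3:1), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))   # zero variance
  expect_true(is.na(pearson_r(c(1, 2, NA), c(1, 2, 3))))  # < 3 complete pairs
})

test_that("pearson_r equals the mean of population-standardized products", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
    expect_lt(abs(pearson_r(x, y) - mean(zx * zy)), 1e-12)
  }
})

test_that("cramers_v reproduces the closed-form examples", {
  # FA-by-sex counts from the published cohort table
  obs <- matrix(c(8, 34, 16, 35), nrow = 2, byrow = TRUE)
  v <- cramers_v(obs)
  exp_counts <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi2 <- sum((obs - exp_counts)^2 / exp_counts)
  expect_equal(v, sqrt(chi2 / 93), tolerance = 1e-10)
  expect_lt(abs(v - 0.140), 1e-3)
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2)), 1.0)
  expect_equal(cramers_v(matrix(c(5, 5, 5, 5), 2)), 0.0)
  expect_true(is.na(cramers_v(matrix(c(5, 5, 0, 0), 2))))  # degenerate margin
})

test_that("eta_squared is the ANOVA variance ratio", {
  expect_equal(eta_squared(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1.0)
  expect_equal(eta_squared(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0.0)
  expect_equal(eta_squared(c(1, 2, 3, 4), c("a", "a", "b", "b")), 0.8)
  expect_true(is.na(eta_squared(c(1, 2, 3), c("a", "a", "a"))))  # one group
  # cross-check against aov on random data
  set.seed(9)
  x <- rnorm(40); g <- sample(letters[1:3], 40, replace = TRUE)
  ss <- summary(aov(x ~ g))[[1]]$`Sum Sq`
  expect_equal(eta_squared(x, g), ss[1] / sum(ss), tolerance = 1e-12)
})

test_that("categorical associations ignore the label permutation", {
  set.seed(4)
  a <- sample(letters[1:3], 120, replace = TRUE)
  b <- sample(LETTERS[1:2], 120, replace = TRUE, prob = c(0.3, 0.7))
  x <- rnorm(120) + (b == "A")
  relab <- c(a = "z", b = "y", c = "x")[a]
  expect_equal(cramers_v(table(a, b)), cramers_v(table(relab, b)))
  expect_equal(eta_squared(x, a), eta_squared(x, relab))
})

test_that("build_matrix dispatches on kinds and stays symmetric", {
  set.seed(21)
  n <- 80
  df <- data.frame(
    wt = rnorm(n, 30, 5), ht = rnorm(n, 135, 9),
    fa = factor(sample(c("no", "yes"), n, replace = TRUE),
                levels = c("no", "yes")))
  specs <- list(
    wt = variable_spec("wt", "continuous",
                       list(shape = "symmetric", mean = 30, sd = 5)),
    ht = variable_spec("ht", "continuous",
                       list(shape = "symmetric", mean = 135, sd = 9)),
    fa = variable_spec("fa", "binary",
                       list(labels = c("no", "yes"), freq = c(0.7, 0.3))))
  coh <- structure(list(data = df, specs = specs), class = "fa_cohort")
  m <- build_matrix(coh)
  expect_identical(m$method["wt", "ht"], "pearson")
  expect_identical(m$method["wt", "fa"], "eta_squared")
  expect_identical(m$method["ht", "fa"], "eta_squared")
  expect_identical(m$values, t(m$values))
  expect_equal(unname(diag(m$values)), rep(1, 3))
  expect_true(all(m$n_used == n))
  # no missing cells: all policies agree
  m2 <- build_matrix(coh, policy = "listwise")
  m3 <- build_matrix(coh, policy = "mean_impute")
  expect_equal(m$values, m2$values)
  expect_equal(m$values, m3$values)
})

test_that("missing-data policies act as declared", {
  set.seed(31)
  n <- 60
  df <- data.frame(a = rnorm(n), b = rnorm(n),
                   fa = factor(sample(c("no", "yes"), n, replace = TRUE),
                               levels = c("no", "yes")))
  df$a[1:6] <- NA
  df$fa[1:4] <- NA
  specs <- list(
    a = variable_spec("a", "continuous",
                      list(shape = "symmetric", mean = 0, sd = 1)),
    b = variable_spec("b", "continuous",
                      list(shape = "symmetric", mean = 0, sd = 1)),
    fa = variable_spec("fa", "binary",
                       list(labels = c("no", "yes"), freq = c(0.5, 0.5))))
  coh <- structure(list(data = df, specs = specs), class = "fa_cohort")
  m <- build_matrix(coh)  # pairwise complete + binary zero-fill
  expect_equal(m$n_used["a", "b"], n - 6)
  expect_equal(m$n_used["b", "fa"], n)  # fa zero-filled to "no"
  expect_equal(m$values["a", "b"],
               cor(df$a, df$b, use = "complete.obs"))
  mlw <- build_matrix(coh, policy = "listwise")
  expect_true(all(mlw$n_used == n - 6))
  # all-missing column rejected
  df2 <- df; df2$b <- NA_real_
  coh2 <- coh; coh2$data <- df2
  expect_error(build_matrix(coh2), "entirely missing")
})

test_that("collinearity pruning removes one member per violating pair", {
  m <- fanet:::as_assoc_matrix(
    as_fixture_matrix(c(0.95, 0.2, 0.3), c("A", "B", "C")))
  pr <- prune_collinear(m)
  expect_equal(nrow(pr$removed), 1L)
  expect_true(pr$removed$variable %in% c("A", "B"))
  expect_true(all(abs(pr$matrix$values[upper.tri(pr$matrix$values)]) < 0.9))

  # below cutoff: untouched
  m2 <- fanet:::as_assoc_matrix(
    as_fixture_matrix(c(0.5, 0.2, 0.3), c("A", "B", "C")))
  pr2 <- prune_collinear(m2)
  expect_equal(nrow(pr2$removed), 0L)
  expect_identical(pr2$matrix$values, m2$values)

  # three mutually collinear: at most one survives
  m3 <- fanet:::as_assoc_matrix(
    as_fixture_matrix(c(0.95, 0.92, 0.1, 0.93, 0.1, 0.1),
                      c("A", "B", "C", "D")))
  pr3 <- prune_collinear(m3)
  expect_lte(sum(c("A", "B", "C") %in% pr3$matrix$variables), 1L)
  expect_true("D" %in% pr3$matrix$variables)

  # idempotence
  pr3b <- prune_collinear(pr3$matrix)
  expect_identical(pr3b$matrix$values, pr3$matrix$values)
  expect_equal(nrow(pr3b$removed), 0L)
})

test_that("pruned matrices never violate the cutoff (random property)", {
  for (seed in 1:10) {
    m <- fanet:::as_assoc_matrix(random_symmetric_matrix(8, seed))
    pr <- prune_collinear(m, cutoff = 0.7)
    v <- abs(pr$matrix$values); diag(v) <- 0
    expect_lt(max(v), 0.7)
  }
})

test_that("imputation sensitivity is reported as a per-node delta", {
  specs <- default_study_specs()
  coh <- inject_missing(
    generate_cohort(specs, default_study_dependence(specs), n = 200,
                    seed = 8), 0.05, seed = 9)
  doms <- domain_presets()$domains$nutritional
  sub <- coh
  sub$data <- coh$data[, doms]; sub$specs <- coh$specs[doms]
  g_cc <- build_graph(build_matrix(sub, policy = "pairwise_complete"), 0.2)
  g_mi <- build_graph(build_matrix(sub, policy = "mean_impute"), 0.2)
  delta <- centrality_shift(centrality_report(g_cc), centrality_report(g_mi))
  expect_identical(names(delta),
                   c("node", "delta_degree", "delta_closeness",
                     "delta_betweenness", "delta_eigenvector"))
  expect_equal(nrow(delta), length(doms))
  expect_true(all(delta$delta_degree >= 0, na.rm = TRUE))
})
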