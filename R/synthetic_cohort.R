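#' Declare a cohort variable and its marginal distribution
#'
#' A `variable_spec` describes one column of a cohort table: its measurement
#' kind and a marginal distribution descriptor sufficient to synthesize it.
#' Continuous variables reported as mean and SD use a `"symmetric"` (normal)
#' descriptor; continuous variables reported as median (min--max) use a
#' `"skewed"` descriptor, synthesized as a shifted log-normal; categorical
#' variables carry labels and frequencies.
#'
#' @param name variable identifier (syntactic column name).
#' @param kind one of `"continuous"`, `"binary"`, `"nominal"`, `"ordinal"`.
#' @param marginal for continuous kinds, either
#'   `list(shape = "symmetric", mean =, sd =)` or
#'   `list(shape = "skewed", median =, min =, max =)`; for categorical kinds,
#'   `list(labels =, freq =)` with frequencies summing to 1.
#' @param units free-text units, for reporting only.
#'
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind, marginal, units = "") {
  kind <- match.arg(kind, c("continuous", "binary", "nominal", "ordinal"))
  if (kind == "continuous") {
    shape <- match.arg(marginal$shape, c("symmetric", "skewed"))
    if (shape == "symmetric") {
      if (!is.finite(marginal$sd) || marginal$sd <= 0)
        stop("variable '", name, "': SD must be > 0")
    } else {
      with(marginal, {
        if (!(min < median && median < max))
          stop("variable '", name, "': need min < median < max")
      })
    }
  } else {
    if (length(marginal$labels) != length(marginal$freq))
      stop("variable '", name, "': labels and freq lengths differ")
    if (kind == "binary" && length(marginal$labels) != 2L)
      stop("variable '", name, "': binary variables need exactly 2 labels")
    if (abs(sum(marginal$freq) - 1) > 1e-9)
      stop("variable '", name, "': frequencies must sum to 1")
    if (any(marginal$freq < 0))
      stop("variable '", name, "': negative frequency")
  }
  structure(list(name = name, kind = kind, marginal = marginal, units = units),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat("<variable_spec>", x$name, "(", x$kind, ")\n")
  invisible(x)
}

is_categorical <- function(kind) kind %in% c("binary", "nominal", "ordinal")

## Pool a continuous marginal reported separately for two strata.
## Symmetric: mixture mean and mixture variance (within + between component).
## Skewed: frequency-weighted median approximation, min of mins, max of maxes
## (the strata overlap heavily, so the pooled median is well approximated by
## the weighted average of stratum medians).
pool_symmetric <- function(n1, m1, s1, n2, m2, s2) {
  w1 <- n1 / (n1 + n2); w2 <- n2 / (n1 + n2)
  m <- w1 * m1 + w2 * m2
  v <- w1 * (s1^2 + (m1 - m)^2) + w2 * (s2^2 + (m2 - m)^2)
  list(shape = "symmetric", mean = m, sd = sqrt(v))
}

pool_skewed <- function(n1, med1, lo1, hi1, n2, med2, lo2, hi2) {
  w1 <- n1 / (n1 + n2)
  list(shape = "skewed",
       median = w1 * med1 + (1 - w1) * med2,
       min = min(lo1, lo2), max = max(hi1, hi2))
}

#' Variable specifications matching the published study cohort
#'
#' Returns one [variable_spec()] per study variable, with marginals taken from
#' the published descriptive table (n = 93 children, 42 girls and 51 boys).
#' Sex-stratified continuous marginals are pooled as two-component mixtures;
#' categorical frequencies are pooled counts. The food-addiction prevalence
#' implied by the specs is 24/93 (25.8%).
#'
#' @return named list of `variable_spec` objects, in reporting order.
#' @examples
#' specs <- default_study_specs()
#' specs$food_addiction$marginal$freq  # 69/93, 24/93
#' @export
default_study_specs <- function() {
  n_g <- 42; n_b <- 51; n <- n_g + n_b
  cat_spec <- function(name, labels, counts, units = "") {
    variable_spec(name, if (length(labels) == 2L) "binary" else "nominal",
                  list(labels = labels, freq = counts / sum(counts)), units)
  }
  sym <- function(name, m1, s1, m2, s2, units = "") {
    variable_spec(name, "continuous", pool_symmetric(n_g, m1, s1, n_b, m2, s2),
                  units)
  }
  skw <- function(name, med1, lo1, hi1, med2, lo2, hi2, units = "") {
    variable_spec(name, "continuous",
                  pool_skewed(n_g, med1, lo1, hi1, n_b, med2, lo2, hi2), units)
  }
  specs <- list(
    cat_spec("sex", c("girls", "boys"), c(n_g, n_b)),
    cat_spec("food_addiction", c("no", "yes"), c(34 + 35, 8 + 16)),
    cat_spec("race", c("white", "black", "brown"),
             c(8 + 11, 11 + 10, 23 + 30)),
    cat_spec("socioeconomic_class", c("B/C", "D/E"), c(24 + 21, 18 + 30)),
    cat_spec("nutritional_status", c("eutrophic", "overweight_obesity"),
             c(22 + 36, 20 + 15)),
    # cohort-wide age is reported directly: mean 9.13, SD 1.0
    variable_spec("age", "continuous",
                  list(shape = "symmetric", mean = 9.13, sd = 1.0), "years"),
    skw("weight", 32.4, 20.1, 76.6, 30.5, 18.2, 65.8, "kg"),
    sym("height", 135.9, 9.3, 136.7, 9.6, "cm"),
    skw("waist_circumference", 63.0, 52.0, 98.0, 61.0, 47.0, 93.0, "cm"),
    skw("bmi", 17.3, 13.5, 32.8, 16.8, 11.5, 29.0, "kg/m2"),
    sym("bmi_for_age", 1.0, 1.6, 0.3, 1.3, "z-score"),
    skw("body_fat_pct", 19.1, 10.1, 43.9, 20.9, 9.1, 42.8, "%"),
    sym("lean_mass", 26.9, 5.5, 25.5, 5.1, "kg"),
    skw("fat_mass", 6.0, 0.0, 33.6, 6.2, 0.0, 28.2, "kg"),
    sym("total_cholesterol", 142.5, 26.7, 140.8, 27.9, "mg/dL"),
    sym("hdl", 42.2, 14.0, 37.6, 12.2, "mg/dL"),
    skw("ldl", 85.0, 46.0, 307.0, 81.5, 37.0, 141.0, "mg/dL"),
    skw("triglycerides", 70, 45.0, 192.0, 70, 45.0, 178.0, "mg/dL"),
    sym("glucose", 89.2, 7.2, 83.6, 6.2, "mg/dL"),
    skw("sbp", 50, 8.2, 121.2, 49.8, 11.6, 70.7, "percentile"),
    skw("dbp", 97.1, 63.0, 140.0, 98.6, 72.0, 146.6, "percentile"))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Plausible latent dependence for the default study cohort
#'
#' The raw study data are not public, so the true inter-variable dependence
#' is unobserved. This default encodes well-established physiological and
#' sociodemographic relationships at conventional magnitudes: a strongly
#' interrelated anthropometric block (weight, waist circumference, BMI, body
#' fat, fat and lean mass, with height and BMI-for-age attached), age tied to
#' body size, lipid coherence (total cholesterol with LDL/HDL/triglycerides,
#' HDL inversely related to triglycerides), a systolic--diastolic blood
#' pressure pair, adiposity-linked blood pressure, and weak links from food
#' addiction to age, socioeconomic class and adiposity. Magnitudes stay below
#' the 0.90 collinearity cutoff so no default variable is pruned. The matrix
#' is PSD-repaired by [dependence_spec()].
#'
#' The dependence is a latent factor model `R = L L' + diag(uniqueness)`
#' with six interpretable factors — body *size* (age, height, lean mass),
#' *adiposity* (weight, waist, BMI, BMI-for-age, body fat, fat mass,
#' nutritional status), two *lipid* axes (giving the HDL--triglyceride
#' inversion), *blood pressure*, and a *social* factor shared by
#' socioeconomic class and food addiction — so it is positive-semidefinite
#' by construction. Race and sex load on nothing and stay independent.
#'
#' @param specs spec list defining the variable set (default
#'   [default_study_specs()]).
#' @return a [dependence_spec()].
#' @export
default_study_dependence <- function(specs = default_study_specs()) {
  vars <- names(specs)
  factors <- c("size", "adiposity", "lipid1", "lipid2", "bp", "social")
  L <- matrix(0, length(vars), length(factors),
              dimnames = list(vars, factors))
  # loadings for variables absent from `specs` are silently skipped, so the
  # default dependence restricts cleanly to any variable subset
  load <- function(v, f, x) if (v %in% vars) L[v, f] <<- x
  load("age", "size", 0.60)
  load("height", "size", 0.80)
  load("lean_mass", "size", 0.75); load("lean_mass", "adiposity", 0.30)
  load("weight", "size", 0.60); load("weight", "adiposity", 0.65)
  load("waist_circumference", "size", 0.35)
  load("waist_circumference", "adiposity", 0.75)
  load("bmi", "size", 0.20); load("bmi", "adiposity", 0.85)
  load("bmi_for_age", "adiposity", 0.85)
  load("body_fat_pct", "adiposity", 0.80)
  load("fat_mass", "size", 0.25); load("fat_mass", "adiposity", 0.85)
  load("nutritional_status", "adiposity", 0.75)
  load("total_cholesterol", "lipid1", 0.85)
  load("ldl", "lipid1", 0.80)
  load("hdl", "lipid1", 0.50); load("hdl", "lipid2", -0.60)
  load("triglycerides", "lipid1", 0.50); load("triglycerides", "lipid2", 0.60)
  load("glucose", "adiposity", 0.20); load("glucose", "lipid1", 0.15)
  load("sbp", "bp", 0.70); load("sbp", "adiposity", 0.30)
  load("dbp", "bp", 0.70); load("dbp", "adiposity", 0.20)
  load("socioeconomic_class", "social", 0.70)
  load("food_addiction", "social", 0.40)
  load("food_addiction", "size", 0.30)
  load("food_addiction", "adiposity", 0.25)
  m <- tcrossprod(L)
  diag(m) <- 1
  dependence_spec(m)
}

#' Latent correlation structure for cohort synthesis
#'
#' A `dependence_spec` is a symmetric positive-semidefinite correlation matrix
#' over the latent Gaussian variables of the copula. Mild indefiniteness
#' (smallest eigenvalue down to `-1e-8`, or anything fixable by eigenvalue
#' clipping without moving an entry by more than `repair_tol`) is repaired by
#' clipping negative eigenvalues at zero and rescaling to unit diagonal.
#'
#' @param correlation square numeric matrix, unit diagonal, entries in
#'   `[-1, 1]`; row/column names are the variable names.
#' @param repair_tol maximum entrywise change allowed during PSD repair.
#' @return an object of class `dependence_spec` wrapping the repaired matrix.
#' @export
dependence_spec <- function(correlation, repair_tol = 0.1) {
  m <- as.matrix(correlation)
  if (nrow(m) != ncol(m)) stop("correlation must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("correlation must be symmetric")
  m <- (m + t(m)) / 2
  if (any(abs(m) > 1 + 1e-8)) stop("correlation entries must lie in [-1, 1]")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("correlation must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    vals <- pmax(ev$values, 0)
    rep_m <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(rep_m))
    rep_m <- rep_m / tcrossprod(d)
    diag(rep_m) <- 1
    if (max(abs(rep_m - m)) > repair_tol)
      stop("correlation is not PSD and repair would change entries by ",
           signif(max(abs(rep_m - m)), 3), " (> repair_tol)")
    m <- rep_m
  }
  structure(list(correlation = m), class = "dependence_spec")
}

#' Identity (independence) dependence over a spec list
#'
#' @param specs named list of [variable_spec()] objects.
#' @return a [dependence_spec()] with identity correlation.
#' @export
identity_dependence <- function(specs) {
  p <- length(specs)
  m <- diag(p)
  dimnames(m) <- list(names(specs), names(specs))
  dependence_spec(m)
}

#' Plant a correlated block into a dependence structure
#'
#' Sets every off-diagonal latent correlation among `members` to `strength`,
#' then repairs positive-semidefiniteness. Used to create a known hub of
#' mutually associated variables for parameter-recovery experiments.
#'
#' @param dependence a [dependence_spec()].
#' @param members character vector of at least two variable names.
#' @param strength latent correlation in (0, 1).
#' @return a new [dependence_spec()].
#' @export
plant_block <- function(dependence, members, strength) {
  stopifnot(inherits(dependence, "dependence_spec"))
  if (!(is.numeric(strength) && strength > 0 && strength < 1))
    stop("strength must lie in (0, 1)")
  m <- dependence$correlation
  if (!all(members %in% rownames(m)))
    stop("unknown member variable(s): ",
         paste(setdiff(members, rownames(m)), collapse = ", "))
  if (length(members) < 2L) stop("need at least two block members")
  idx <- match(members, rownames(m))
  m[idx, idx] <- strength
  diag(m) <- 1
  dependence_spec(m)
}

## Map standard-normal draws through a marginal descriptor.
## Skewed marginals: shifted log-normal X = min + exp(mu + sigma Z) with
## mu = log(median - min) (the log-normal median) and sigma chosen so the
## printed maximum sits at the 99th percentile of the fitted distribution.
marginal_transform <- function(z, spec) {
  mg <- spec$marginal
  if (spec$kind == "continuous") {
    if (mg$shape == "symmetric") return(mg$mean + mg$sd * z)
    mu <- log(mg$median - mg$min)
    sigma <- (log(mg$max - mg$min) - mu) / qnorm(0.99)
    return(mg$min + exp(mu + sigma * z))
  }
  # categorical: threshold the latent normal at the cumulative frequencies
  breaks <- qnorm(cumsum(mg$freq))
  breaks[length(breaks)] <- Inf
  idx <- findInterval(z, c(-Inf, breaks[-length(breaks)]))
  factor(mg$labels[idx], levels = mg$labels)
}

#' Generate a synthetic cohort from marginal specs and a latent copula
#'
#' Draws latent multivariate-normal scores with the given correlation and
#' pushes each column through its marginal: symmetric continuous variables are
#' rescaled normals, skewed ones shifted log-normals fitted to the printed
#' median/min/max, and categorical variables are produced by thresholding the
#' latent normal at the quantiles of the declared frequencies. Identical
#' inputs and seed give bit-identical tables.
#'
#' @param specs named list of [variable_spec()] objects.
#' @param dependence a [dependence_spec()] over the same variables (default:
#'   independence).
#' @param n number of subjects (default 93, the study size).
#' @param seed integer seed for the draw.
#' @return an object of class `fa_cohort`: a list with `data` (data.frame,
#'   subjects x variables, categorical columns as factors) and `specs`.
#' @examples
#' coh <- generate_cohort(default_study_specs(), n = 93, seed = 1)
#' table(coh$data$food_addiction)
#' @export
generate_cohort <- function(specs, dependence = identity_dependence(specs),
                            n = 93, seed = 1) {
  stopifnot(n >= 1, inherits(dependence, "dependence_spec"))
  p <- length(specs)
  if (nrow(dependence$correlation) != p)
    stop("dependence dimension (", nrow(dependence$correlation),
         ") does not match number of specs (", p, ")")
  if (!identical(rownames(dependence$correlation), names(specs)))
    dependence$correlation <-
      dependence$correlation[names(specs), names(specs)]
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n * p), nrow = n, ncol = p)
  ev <- eigen(dependence$correlation, symmetric = TRUE)
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- z %*% root
  cols <- lapply(seq_len(p), function(j) marginal_transform(z[, j], specs[[j]]))
  names(cols) <- names(specs)
  dat <- as.data.frame(cols, stringsAsFactors = FALSE)
  structure(list(data = dat, specs = specs), class = "fa_cohort")
}

#' @export
print.fa_cohort <- function(x, ...) {
  cat("<fa_cohort> ", nrow(x$data), " subjects x ", ncol(x$data),
      " variables\n", sep = "")
  kinds <- vapply(x$specs, `[[`, "", "kind")
  cat("  continuous: ", sum(kinds == "continuous"),
      ", categorical: ", sum(kinds != "continuous"),
      ", missing cells: ", sum(is.na(x$data)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.fa_cohort <- function(x, ...) x$data

#' Kind of each cohort variable
#' @param cohort an `fa_cohort`.
#' @return named character vector of kinds.
#' @export
cohort_kinds <- function(cohort) {
  vapply(cohort$specs, `[[`, "", "kind")
}

#' Inject missing cells completely at random
#'
#' Each cell is independently set to missing with probability `rate`.
#'
#' @param cohort an `fa_cohort`.
#' @param rate per-cell missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the cohort with `NA`s injected.
#' @export
inject_missing <- function(cohort, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  set.seed(as.integer(seed))
  d <- cohort$data
  mask <- matrix(stats::runif(nrow(d) * ncol(d)) < rate,
                 nrow = nrow(d))
  for (j in seq_len(ncol(d))) d[mask[, j], j] <- NA
  cohort$data <- d
  cohort
}

#' Write / read a cohort as delimited text with a metadata sidecar
#'
#' The table is comma-separated with a header row and `NA` for missing cells;
#' the sidecar is a JSON file declaring each variable's kind, marginal
#' descriptor and units, so the mixed-type machinery can re-dispatch on read.
#'
#' @param cohort an `fa_cohort`.
#' @param path CSV path for the values.
#' @param meta_path JSON path for the variable metadata (default: `path` with
#'   a `.meta.json` suffix).
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns an
#'   `fa_cohort`.
#' @export
write_cohort <- function(cohort, path,
                         meta_path = paste0(path, ".meta.json")) {
  write.csv(cohort$data, path, row.names = FALSE, na = "NA")
  meta <- lapply(cohort$specs, function(s)
    list(kind = s$kind, marginal = s$marginal, units = s$units))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, meta_path = paste0(path, ".meta.json")) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dat <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  specs <- lapply(names(meta), function(nm) {
    m <- meta[[nm]]
    variable_spec(nm, m$kind, as.list(m$marginal), m$units %||% "")
  })
  names(specs) <- names(meta)
  dat <- dat[, names(specs), drop = FALSE]
  for (nm in names(specs)) {
    if (is_categorical(specs[[nm]]$kind)) {
      raw <- dat[[nm]]
      dat[[nm]] <- factor(raw, levels = specs[[nm]]$marginal$labels)
      undeclared <- !is.na(raw) & is.na(dat[[nm]])
      if (any(undeclared))
        stop("undeclared category label(s) in '", nm, "': ",
             paste(unique(raw[undeclared]), collapse = ", "))
    }
  }
  structure(list(data = dat, specs = specs), class = "fa_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
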