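test_that("default study specs carry the published marginals and invariants", {
  specs <- default_study_specs()
  fa <- specs$food_addiction$marginal
  expect_equal(fa$freq[match("yes", fa$labels)], 24 / 93, tolerance = 1e-12)
  sx <- specs$sex$marginal
  expect_equal(sx$freq[match("boys", sx$labels)], 51 / 93, tolerance = 1e-12)
  expect_equal(specs$age$marginal$mean, 9.13)
  for (s in specs) {
    if (s$kind == "continuous") {
      if (s$marginal$shape == "symmetric") expect_gt(s$marginal$sd, 0)
      else {
        expect_lt(s$marginal$min, s$marginal$median)
        expect_lt(s$marginal$median, s$marginal$max)
      }
    } else {
      expect_equal(sum(s$marginal$freq), 1, tolerance = 1e-9)
    }
  }
})

test_that("cohort generation is seed-reproducible and marginally faithful", {
  specs <- default_study_specs()
  a <- generate_cohort(specs, n = 93, seed = 1)
  b <- generate_cohort(specs, n = 93, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(specs, n = 93, seed = 2)))

  big <- generate_cohort(specs, identity_dependence(specs),
                         n = 20000, seed = 7)
  expect_lt(abs(mean(big$data$food_addiction == "yes") - 24 / 93), 0.01)
  # every categorical frequency within +-0.01 of spec at n = 20000
  for (nm in names(specs)) {
    s <- specs[[nm]]
    if (s$kind == "continuous") {
      if (s$marginal$shape == "symmetric")
        expect_lt(abs(mean(big$data[[nm]]) - s$marginal$mean),
                  3 * s$marginal$sd / sqrt(20000))
      else
        expect_gt(min(big$data[[nm]]), s$marginal$min)
    } else {
      emp <- as.numeric(table(big$data[[nm]])[s$marginal$labels]) / 20000
      expect_true(all(abs(emp - s$marginal$freq) < 0.01), label = nm)
    }
  }
})

test_that("latent copula correlation carries through to the observations", {
  specs <- default_study_specs()[c("age", "height")]
  dep <- plant_block(identity_dependence(specs), c("age", "height"), 0.9)
  coh <- generate_cohort(specs, dep, n = 20000, seed = 3)
  r <- cor(coh$data$age, coh$data$height)
  expect_gt(r, 0.85)
  expect_lt(r, 0.95)
})

test_that("plant_block sets the block and preserves PSD", {
  specs <- default_study_specs()[c("age", "height", "weight")]
  dep <- plant_block(identity_dependence(specs),
                     c("age", "height", "weight"), 0.7)
  m <- dep$correlation
  expect_equal(unname(m[upper.tri(m)]), rep(0.7, 3))
  two <- plant_block(identity_dependence(specs[1:2]),
                     c("age", "height"), 0.99)
  expect_gte(min(eigen(two$correlation, symmetric = TRUE)$values), -1e-8)
  expect_error(plant_block(identity_dependence(specs), c("age", "height"),
                           1.2), "strength")
  expect_error(plant_block(identity_dependence(specs), "age", 0.5), "two")
})

test_that("dependence_spec validates, repairs mild indefiniteness, rejects gross", {
  expect_error(dependence_spec(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
  m <- matrix(c(1, 0.7, 0.7, 0.7, 1, -0.7, 0.7, -0.7, 1), 3)
  expect_error(dependence_spec(m), "not PSD")
  # mildly indefinite: repairable
  m2 <- matrix(c(1, 0.6, 0.6, 0.6, 1, 0.6, 0.6, 0.6, 1), 3)
  m2[1, 2] <- m2[2, 1] <- 0.55  # still PSD; passes through untouched
  expect_silent(dependence_spec(m2))
  expect_gte(min(eigen(default_study_dependence()$correlation,
                       symmetric = TRUE)$values), -1e-8)
})

test_that("missingness injection hits the requested expected count", {
  specs <- default_study_specs()
  coh <- generate_cohort(specs, n = 2000, seed = 5)
  rate <- 0.05
  out <- inject_missing(coh, rate, seed = 11)
  n_cells <- prod(dim(coh$data))
  n_miss <- sum(is.na(out$data))
  sigma <- sqrt(n_cells * rate * (1 - rate))
  expect_lt(abs(n_miss - n_cells * rate), 3 * sigma)
})

test_that("cohort csv + metadata sidecar round-trips", {
  specs <- default_study_specs()
  coh <- inject_missing(generate_cohort(specs, n = 50, seed = 2), 0.03,
                        seed = 3)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_identical(names(back$data), names(coh$data))
  expect_identical(cohort_kinds(back), cohort_kinds(coh))
  for (nm in names(coh$data)) {
    if (is.factor(coh$data[[nm]])) {
      expect_identical(levels(back$data[[nm]]), levels(coh$data[[nm]]))
      expect_identical(as.character(back$data[[nm]]),
                       as.character(coh$data[[nm]]))
    } else {
      expect_equal(back$data[[nm]], coh$data[[nm]], tolerance = 1e-10)
    }
  }
  # undeclared labels are rejected
  bad <- coh$data
  lines <- readLines(path)
  writeLines(gsub("\\bgirls\\b", "martians", lines), path)
  expect_error(read_cohort(path), "undeclared")
})
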