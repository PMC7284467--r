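test_that("generation is deterministic and respects the requested size", {
  co1 <- small_cohort(n = 150, seed = 11)
  co2 <- small_cohort(n = 150, seed = 11)
  expect_identical(co1$intakes, co2$intakes)
  expect_identical(co1$covariates, co2$covariates)
  expect_identical(co1$proteins$values, co2$proteins$values)
  expect_identical(co1$metabolites$values, co2$metabolites$values)
  co3 <- small_cohort(n = 150, seed = 12)
  expect_false(identical(co1$metabolites$values, co3$metabolites$values))

  big <- generate_cohort(cohort_spec(n_participants = 2208, seed = 3,
                                     n_proteins = 5, n_metabolites = 5))
  expect_equal(nrow(big$intakes), 2208)
  expect_equal(nrow(big$covariates), 2208)
  expect_equal(nrow(big$proteins$values), 2208)
})

test_that("spec and plan inputs are validated", {
  expect_error(cohort_spec(n_participants = 0), "positive")
  expect_error(cohort_spec(sex_fraction_female = 1.2), "\\[0, 1\\]")
  expect_error(effect_plan(data.frame(index = "XYZ", marker = "met_0001",
                                      beta_per_sd = 1)), "AHEI")
  expect_error(effect_plan(data.frame(index = c("AHEI", "AHEI"),
                                      marker = c("m", "m"),
                                      beta_per_sd = c(1, 2))), "unique")
  plan <- effect_plan(data.frame(index = "AHEI", marker = "nope_001",
                                 beta_per_sd = 1))
  expect_error(generate_cohort(small_spec(), plan), "unknown marker")
})

test_that("marginals: intakes nonnegative, energy mean within 3 SD/sqrt(n)", {
  co <- small_cohort(n = 2000, seed = 5)
  intake_cols <- setdiff(names(co$intakes), c("participant_id", "blank_items"))
  expect_true(all(as.matrix(co$intakes[intake_cols]) >= 0))
  for (s in c("male", "female")) {
    i <- co$covariates$sex == s
    par <- if (s == "male") c(1992, 642) else c(1742, 566)
    tol <- 3 * par[2] / sqrt(sum(i))
    # truncation at zero is negligible at these means; mean must agree
    expect_lt(abs(mean(co$covariates$energy_kcal[i]) - par[1]), tol)
  }
})

test_that("protein batches alternate deterministically and can be fixed", {
  co <- small_cohort(n = 100)
  expect_identical(co$proteins$batch, rep_len(c(1L, 2L), 100))
  co2 <- generate_cohort(small_spec(n = 100,
                                    protein_batch_sizes = c(40L, 60L)))
  expect_identical(co2$proteins$batch, rep(c(1L, 2L), c(40, 60)))
  expect_error(generate_cohort(small_spec(n = 100,
                                          protein_batch_sizes = c(40L, 50L))),
               "sum")
})

test_that("zero-noise planted effects are recovered exactly by OLS", {
  plan <- effect_plan(data.frame(index = c("DASH", "MDS"),
                                 marker = c("met_0003", "met_0003"),
                                 beta_per_sd = c(0.4, -0.2)),
                      noise_sd = 0)
  co <- small_cohort(n = 300, seed = 8, plan = plan)
  z <- co$true_scores
  fit <- lm(co$metabolites$values[, "met_0003"] ~ z[, "DASH"] + z[, "MDS"])
  expect_equal(unname(coef(fit)[2]), 0.4, tolerance = 1e-8)
  expect_equal(unname(coef(fit)[3]), -0.2, tolerance = 1e-8)
  # null markers are exactly zero under zero noise
  expect_true(all(co$metabolites$values[, "met_0001"] == 0))
})

test_that("covariate effects are applied to markers", {
  plan <- effect_plan(noise_sd = 1e-8,
                      covariate_effects = c(age = 0.5))
  co <- small_cohort(n = 250, seed = 13, plan = plan)
  r <- cor(co$metabolites$values[, 1], co$covariates$age)
  expect_gt(r, 0.999)
})

test_that("inject_missingness: identity at zero rates, deterministic mask,
           heavy blanking fails the validity filter", {
  co <- small_cohort(n = 120, seed = 21)
  same <- inject_missingness(co, 0, 0, seed = 1)
  expect_identical(same$intakes, co$intakes)
  expect_identical(same$covariates, co$covariates)
  expect_equal(same$missingness$n_with_blanks, 0L)

  m1 <- inject_missingness(co, 0.05, 0.1, seed = 99)
  m2 <- inject_missingness(co, 0.05, 0.1, seed = 99)
  expect_identical(m1$intakes, m2$intakes)
  expect_identical(m1$covariates, m2$covariates)
  expect_gt(m1$missingness$n_with_blanks, 0)
  expect_gt(m1$missingness$n_missing_covariate, 0)

  # blank rate high enough that everyone has >= 13 blank items
  mh <- inject_missingness(co, 0.5, 0, seed = 2)
  v <- validate_ffq(mh$intakes$blank_items, mh$intakes$energy_kcal,
                    mh$covariates$sex)
  expect_true(any(mh$intakes$blank_items >= 13))
  expect_true(all(!v$valid[mh$intakes$blank_items >= 13]))
  expect_true(all(v$reason[mh$intakes$blank_items >= 13] == "blank_items"))

  expect_error(inject_missingness(co, 1, 0), "rates")
})

test_that("write_cohort emits the four tables plus a truth echo", {
  co <- small_cohort(n = 30)
  d <- tempfile()
  paths <- write_cohort(co, d)
  expect_true(all(file.exists(paths)))
  intk <- read.delim(file.path(d, "intakes.tsv"))
  expect_equal(nrow(intk), 30)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$noise_sd, 1)
})
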