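test_that("FFQ validity filter enforces blank and energy rules", {
  v <- validate_ffq(blank_items = c(12, 0, 13, 5, 0, 0),
                    energy_kcal = c(3999, 4200, 2000, 599, 600, 4199),
                    sex = c("female", "male", "male", "female", "male",
                            "male"))
  expect_equal(v$valid, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(v$reason[2], "energy_above_limit")
  expect_equal(v$reason[3], "blank_items")
  expect_equal(v$reason[4], "energy_below_600")
  # female upper bound is 4000, exclusive
  v2 <- validate_ffq(0, 4000, "female")
  expect_false(v2$valid)
  expect_error(validate_ffq(0, 2000, "other"), "unknown sex")
})

test_that("anchored components interpolate and clamp; direction via anchors", {
  cs <- component_spec("veg", "vegetables", "anchored_linear",
                       anchors = c(0, 5))
  expect_equal(score_anchored_component(c(0, 5, 2.5, 10, -1), cs),
               c(0, 10, 5, 10, 0))
  rev <- component_spec("sodium", "sodium_mg_d", "anchored_linear",
                        direction = "reverse", anchors = c(4000, 1500))
  expect_equal(score_anchored_component(c(4000, 1500, 2750, 6000, 0), rev),
               c(0, 10, 5, 0, 10))
  # monotonicity property over a grid
  x <- seq(-2, 12, by = 0.25)
  expect_true(all(diff(score_anchored_component(x, cs)) >= 0))
  expect_true(all(diff(score_anchored_component(x, rev)) <= 0))
  expect_error(component_spec("bad", "f", "anchored_linear"), "anchors")
})

test_that("quantile rank scores match a sort-and-split oracle on distinct data", {
  set.seed(1)
  x <- sample(1:100)  # 100 distinct values
  pts <- quantile_rank_scores(x, 5L, "direct", 1:5)
  expect_equal(as.vector(table(pts)), rep(20L, 5))  # exactly 20 per level
  # brute-force oracle: sort, split into 5 equal blocks
  oracle <- ceiling(rank(x) / 20)
  expect_equal(pts, oracle)
  # top-quintile participant scores 5; reverse maps Q1 -> 5, Q5 -> 1
  expect_equal(pts[which.max(x)], 5)
  rpts <- quantile_rank_scores(x, 5L, "reverse", 1:5)
  expect_equal(rpts[which.min(x)], 5)
  expect_equal(rpts[which.max(x)], 1)
  expect_equal(pts + rpts, rep(6, 100))
})

test_that("quantile ranks: tie-at-cutpoint falls lower, permutation equivariance,
           degenerate zero-inflation merges bins with a warning", {
  x <- 1:9  # type-7 quartile cut-points land exactly on 3, 5, 7
  pts <- quantile_rank_scores(x, 4L, "direct", 0:3)
  expect_equal(pts[3], 0)  # tied with the Q1 cut-point -> lower bin
  expect_equal(pts[c(5, 7, 9)], c(1, 2, 3))

  set.seed(2)
  y <- rnorm(57)
  perm <- sample(57)
  p1 <- quantile_rank_scores(y, 5L, "direct", 1:5)
  expect_equal(quantile_rank_scores(y[perm], 5L, "direct", 1:5), p1[perm])

  z <- c(rep(0, 80), runif(20, 1, 2))  # zero-inflated: duplicate cut-points
  expect_warning(pz <- quantile_rank_scores(z, 5L, "direct", 1:5), "merged")
  expect_equal(unique(pz[z == 0]), 1)       # lowest applicable bin
  expect_true(all(pz[z > 0] > 1))

  expect_error(quantile_rank_scores(1:3, 5L, "direct", 1:5), "fewer")
  expect_error(quantile_rank_scores(1:10, 3L, "direct", 1:3), "n_bins")
})

test_that("sex-stratified quartiles use within-stratum cut-points", {
  sex <- rep(c("female", "male"), each = 40)
  x <- c(1:40, 101:140)  # male intakes uniformly higher
  pts <- quantile_rank_scores(x, 4L, "direct", 0:3, by_sex = sex)
  expect_equal(as.vector(table(pts[sex == "female"])), rep(10L, 4))
  expect_equal(as.vector(table(pts[sex == "male"])), rep(10L, 4))
  # lowest male intake far exceeds every female value yet still scores 0
  expect_equal(pts[sex == "male"][1], 0)
})

test_that("MDS alcohol window is inclusive and sex-specific", {
  w <- list(female = c(5, 15), male = c(10, 25))
  expect_equal(score_alcohol_mds(c(5, 15, 4.9, 15.1, 0), rep("female", 5), w),
               c(1L, 1L, 0L, 0L, 0L))
  expect_equal(score_alcohol_mds(c(10, 25, 26, 5), rep("male", 4), w),
               c(1L, 1L, 0L, 0L))
  expect_error(score_alcohol_mds(5, "male", NULL), "window")
})

test_that("index composition is verified at config build time", {
  comps <- ahei_config()$components
  expect_error(diet_index_config("AHEI", comps[-1], 110L), "sum to 100")
  expect_error(diet_index_config("AHEI", comps[-1], 100L), "composition")
  expect_equal(sum(vapply(dash_config()$components, `[[`, 0L, "points_max")),
               40L)
  expect_equal(sum(vapply(mds_config()$components, `[[`, 0L, "points_max")),
               25L)
})

test_that("score_index bounds hold on adversarial cohorts and extremes hit
           the exact maxima and minima", {
  df <- adversarial_intakes(100)
  sex <- rep(c("female", "male"), 50)

  # best-case participant: dominate direct fields, zero on reverse fields,
  # alcohol inside the sex window
  best <- df
  direct_max <- c("vegetables", "fruits", "nuts", "legumes", "nuts_legumes",
                  "whole_grains", "fish", "low_fat_dairy", "fruit_juice",
                  "fruits_juice", "mufa_sfa_ratio", "pufa_pct_kcal",
                  "omega3_mg_d")
  best[1, direct_max] <- 1e6
  best[1, c("ssb", "ssb_fruit_juice", "red_processed_meat",
            "trans_pct_kcal", "sodium_mg_d")] <- 0
  best[1, "alcohol_g_d"] <- 10  # inside female window 5-15
  a <- score_index(best, ahei_config(), sex)
  d <- score_index(best, dash_config(), sex)
  m <- score_index(best, mds_config(), sex)
  expect_equal(a$total[1], 110)
  expect_equal(d$total[1], 40)
  expect_equal(m$total[1], 25)

  # worst-case participant: zero on direct fields, dominate reverse fields,
  # heavy alcohol
  worst <- df
  worst[2, direct_max] <- 0
  worst[2, c("ssb", "ssb_fruit_juice", "red_processed_meat",
             "trans_pct_kcal", "sodium_mg_d")] <- 1e6
  worst[2, "alcohol_g_d"] <- 200
  a <- score_index(worst, ahei_config(), sex)
  d <- score_index(worst, dash_config(), sex)
  m <- score_index(worst, mds_config(), sex)
  expect_equal(a$total[2], 0)
  expect_equal(d$total[2], 8)   # DASH floor: 8 components x 1 point
  expect_equal(m$total[2], 0)

  # bounds on a full scored cohort, including the adversarial rows
  for (case in list(best, worst)) {
    expect_true(all(score_index(case, ahei_config(), sex)$total >= 0))
    expect_true(all(score_index(case, ahei_config(), sex)$total <= 110))
    dt <- score_index(case, dash_config(), sex)$total
    expect_true(all(dt >= 8 & dt <= 40))
    mt <- score_index(case, mds_config(), sex)$total
    expect_true(all(mt >= 0 & mt <= 25))
  }
})

test_that("component totals equal the sum of component points", {
  co <- small_cohort(n = 80)
  sc <- score_index(co$intakes, mds_config(), co$covariates$sex)
  comp_cols <- setdiff(names(sc), c("participant_id", "total"))
  expect_equal(sc$total, rowSums(sc[comp_cols]))
})

test_that("standardize_index: closed form, normalization, shift invariance", {
  expect_equal(standardize_index(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  x <- rnorm(50, 20, 5)
  z <- standardize_index(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(standardize_index(x + 100), z, tolerance = 1e-10)
  expect_equal(order(z), order(x))
  expect_error(standardize_index(rep(3, 10)), "constant")
})
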