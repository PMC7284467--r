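# brute-force step-up definition: q_(i) = min_{j >= i} m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  q
}

test_that("fit_marker_model matches lm() and the closed form", {
  set.seed(10)
  n <- 60
  x <- rnorm(n)
  C <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- 0.3 * x + 0.5 * C$a + rnorm(n)
  f <- fit_marker_model(y, x, C)
  ref <- summary(lm(y ~ x + a + b, data = cbind(C, y = y, x = x)))
  expect_equal(f$beta, ref$coefficients["x", "Estimate"], tolerance = 1e-10)
  expect_equal(f$se, ref$coefficients["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(f$p, ref$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
  # closed form (X'X)^-1 X'y
  X <- cbind(1, x, C$a, C$b)
  beta_cf <- solve(crossprod(X), crossprod(X, y))
  expect_equal(f$beta, beta_cf[2], tolerance = 1e-10)

  # exact fit: y = 2 * index, no covariates
  x10 <- rnorm(10)
  f2 <- fit_marker_model(2 * x10, x10)
  expect_equal(f2$beta, 2, tolerance = 1e-12)
  expect_lt(sum(lm(2 * x10 ~ x10)$residuals^2), 1e-20)

  # adding a covariate orthogonal to every other regressor leaves beta
  # unchanged (block-diagonal normal equations)
  z <- unname(residuals(lm(rnorm(n) ~ x + C$a + C$b)))
  f3 <- fit_marker_model(y, x, cbind(C, z = z))
  expect_equal(f3$beta, f$beta, tolerance = 1e-10)

  expect_error(fit_marker_model(rep(1, n), x), "degenerate")
  expect_error(fit_marker_model(y, x, data.frame(d = x)), "singular")
})

test_that("bh_fdr equals the step-up oracle on 1000 random vectors", {
  set.seed(123)
  for (rep in 1:1000) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)  # mix of null-ish and signal-ish
    p[p == 0] <- 1e-12
    expect_identical(bh_fdr(p), bh_oracle(p))
  }
  # and equals R's reference implementation
  set.seed(5)
  p <- runif(500)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-14)
})

test_that("bh_fdr edge cases and validation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_true(all(bh_fdr(runif(20)) >= sort(runif(20))[0]))  # q >= 0 trivially
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))            # q >= p always for BH
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_identical(bh_fdr(numeric()), numeric())
})

test_that("run_scan emits one record per (index, marker) with per-family q", {
  plan <- effect_plan(data.frame(index = "DASH", marker = "met_0002",
                                 beta_per_sd = 1.5))
  co <- small_cohort(n = 400, seed = 31, n_met = 30, plan = plan)
  sc <- std_scores(co)
  rec <- run_scan(sc, co$metabolites, co$covariates)
  expect_equal(nrow(rec), 3 * 30)
  expect_setequal(unique(rec$index), c("AHEI", "DASH", "MDS"))
  expect_true(all(rec$platform == "metabolite"))
  expect_true(all(rec$q >= rec$p - 1e-15))
  # family-wise q recomputation
  for (ix in unique(rec$index)) {
    i <- rec$index == ix
    expect_equal(rec$q[i], bh_fdr(rec$p[i]))
  }
  expect_true(rec$fdr_sig[rec$index == "DASH" & rec$marker == "met_0002"])
  # significance flag definitions
  expect_equal(rec$fdr_sig, rec$q <= 0.05)
  expect_equal(rec$bonferroni_sig, rec$p <= 0.05 / 30)

  pooled <- run_scan(sc, co$metabolites, co$covariates,
                     fdr_family = "pooled")
  expect_equal(pooled$q, bh_fdr(pooled$p))
})

test_that("degenerate markers are flagged, not fatal", {
  co <- small_cohort(n = 100, seed = 32, n_met = 5)
  co$metabolites$values[, 3] <- 7
  sc <- std_scores(co)
  rec <- run_scan(sc, co$metabolites, co$covariates)
  expect_equal(unique(rec$status[rec$marker == "met_0003"]), "degenerate")
  expect_true(all(is.na(rec$p[rec$marker == "met_0003"])))
  expect_true(all(rec$status[rec$marker != "met_0003"] == "ok"))
})

test_that("overlap_sets equals brute-force set enumeration", {
  # hand case
  rec <- data.frame(index = c("AHEI", "AHEI", "DASH", "DASH", "MDS"),
                    marker = c("m1", "m2", "m2", "m3", "m2"),
                    fdr_sig = TRUE)
  ov <- overlap_sets(rec)
  expect_equal(ov$counts$`AHEI&DASH&MDS`, 1)
  expect_equal(ov$counts$union, 3)
  expect_equal(ov$counts$`AHEI&DASH`, 1)

  # randomized flags vs exhaustive enumeration + inclusion-exclusion
  set.seed(9)
  for (rep in 1:20) {
    rec <- expand.grid(index = c("AHEI", "DASH", "MDS"),
                       marker = sprintf("m%02d", 1:15),
                       stringsAsFactors = FALSE)
    rec$fdr_sig <- runif(nrow(rec)) < 0.4
    ov <- overlap_sets(rec)
    sets <- lapply(c("AHEI", "DASH", "MDS"), function(ix)
      rec$marker[rec$index == ix & rec$fdr_sig])
    names(sets) <- c("AHEI", "DASH", "MDS")
    expect_equal(ov$counts$union, length(unique(unlist(sets))))
    # inclusion-exclusion identity
    incl_excl <- with(ov$counts,
      AHEI + DASH + MDS - `AHEI&DASH` - `AHEI&MDS` - `DASH&MDS` +
        `AHEI&DASH&MDS`)
    expect_equal(ov$counts$union, incl_excl)
  }
})
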