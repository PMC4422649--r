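test_that("noiseless balanced data return the generating effects exactly", {
  sp <- two_locus_spec()
  truth <- two_locus_truth()
  cfg <- simulation_config(sp, truth, var_cohort = 0, var_family = 0,
                           var_residual = 0, n_per_cell = 2L, n_cohorts = 2L,
                           seed = 1L)
  dat <- simulate_phenotypes(cfg)
  fit <- suppressWarnings(noia_fit(dat, sp, "trait"))
  expect_equal(coef(fit)[names(truth)], truth, tolerance = 1e-8)
})

test_that("OLS sampling covariance matches the closed-form oracle", {
  sp <- two_locus_spec()
  truth <- two_locus_truth()
  sigma2 <- 0.8
  cfg <- simulation_config(sp, truth, 0, 0, sigma2,
                           n_per_cell = 6L, n_cohorts = 1L, n_families = 1L)
  dat0 <- simulate_phenotypes(cfg, seed = 1L)
  X <- cbind(1, build_design(as.matrix(dat0[, sp$loci]), sp))
  oracle_diag <- sigma2 * diag(solve(crossprod(X)))
  # average the model-based diag(S) over replicates: E[s^2] = sigma^2
  set.seed(99)
  reps <- 200L
  diags <- matrix(NA_real_, reps, ncol(X))
  est <- matrix(NA_real_, reps, ncol(X))
  for (r in seq_len(reps)) {
    d <- simulate_phenotypes(cfg, seed = 1000L + r)
    f <- noia_fit(d, sp, "trait", engine = "ols")
    diags[r, ] <- diag(vcov(f))
    est[r, ] <- coef(f)
  }
  expect_equal(colMeans(diags), oracle_diag, tolerance = 0.05,
               ignore_attr = TRUE)
  # empirical sampling variance of the estimates agrees with the oracle too
  emp <- apply(est, 2L, var)
  expect_true(all(abs(emp - oracle_diag) < 5 * oracle_diag / sqrt(reps / 2)))
})

test_that("fixed effects are invariant to relabelling cohorts and families", {
  sp <- two_locus_spec()
  cfg <- simulation_config(sp, two_locus_truth(), 0.2, 0.1, 0.5,
                           n_per_cell = 4L, n_cohorts = 3L, n_families = 2L,
                           seed = 11L)
  dat <- simulate_phenotypes(cfg)
  fit1 <- noia_fit(dat, sp, "trait")
  dat2 <- dat
  dat2$cohort <- paste0("Z", match(dat$cohort, sort(unique(dat$cohort))))
  dat2$family <- paste0("fam.", as.integer(factor(dat$family)))
  fit2 <- noia_fit(dat2, sp, "trait")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-6)
})

test_that("full-data a/d estimates agree with single-locus-subset estimates", {
  # the functional parameterization's stability property: both fits share the
  # reference point, so a/d estimates agree within joint standard errors
  sp <- two_locus_spec()
  cfg <- simulation_config(sp, two_locus_truth(), 0.1, 0.05, 0.4,
                           n_per_cell = 10L, n_cohorts = 2L, n_families = 2L,
                           seed = 21L)
  dat <- simulate_phenotypes(cfg)
  full <- noia_fit(dat, sp, "trait")
  nil <- noia_fit(dat, sp, "trait", scope = "single_locus")
  for (lab in c("a_x1", "d_x1", "a_x2", "d_x2")) {
    se2 <- vcov(full)[lab, lab] + vcov(nil)[lab, lab]
    expect_lt(abs(coef(full)[lab] - coef(nil)[lab]), 2 * sqrt(se2) + 1e-8)
  }
  expect_false(nil$spec$epistasis)
  expect_lt(nil$n_obs, full$n_obs)
})

test_that("likelihood-ratio test behaves as a nested-model comparison", {
  sp <- two_locus_spec()
  cfg <- simulation_config(sp, two_locus_truth(), 0.1, 0.05, 0.5,
                           n_per_cell = 6L, n_cohorts = 2L, n_families = 2L,
                           seed = 31L)
  dat <- simulate_phenotypes(cfg)
  full <- noia_fit(dat, sp, "trait")
  red <- noia_fit(dat, noiavar:::reduce_spec(sp), "trait")
  lrt <- lr_test(full, red)
  expect_equal(lrt$df, 4L)
  expect_gte(lrt$chi2, 0)
  expect_gte(full$loglik_ml, red$loglik_ml - 1e-6)  # ML never decreases
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  # identical models: chi2 = 0, p = 1
  self <- lr_test(full, full)
  expect_equal(self$chi2, 0)
  expect_equal(self$p_value, 1)
  # mismatched observation counts are refused
  red2 <- noia_fit(dat[-1, ], noiavar:::reduce_spec(sp), "trait")
  expect_error(lr_test(full, red2), "different numbers of observations")
})

test_that("missing trait values are dropped per trait, not per plant", {
  sp <- two_locus_spec()
  cfg <- simulation_config(sp, two_locus_truth(), 0.1, 0.05, 0.5,
                           n_per_cell = 4L, n_cohorts = 2L, n_families = 2L,
                           seed = 41L)
  dat <- simulate_phenotypes(cfg)
  dat$other <- dat$trait + rnorm(nrow(dat))
  dat$trait[1:10] <- NA
  fit_a <- noia_fit(dat, sp, "trait")
  fit_b <- noia_fit(dat, sp, "other")
  expect_equal(fit_a$n_obs, nrow(dat) - 10L)
  expect_equal(fit_b$n_obs, nrow(dat))
})

test_that("rank-deficient designs raise an error naming a column", {
  sp <- two_locus_spec()
  cfg <- simulation_config(sp, two_locus_truth(), 0, 0, 0.5,
                           n_per_cell = 4L, n_cohorts = 1L, n_families = 1L,
                           seed = 51L)
  dat <- simulate_phenotypes(cfg)
  dat <- dat[dat$x2 == 0L, ]  # no contrast left for locus x2
  expect_error(noia_fit(dat, sp, "trait"), "rank deficient")
})

test_that("parametric-bootstrap replicates mirror the fitted structure", {
  sp <- two_locus_spec()
  cfg <- simulation_config(sp, two_locus_truth(), 0.1, 0.05, 0.5,
                           n_per_cell = 3L, n_cohorts = 2L, n_families = 2L,
                           seed = 61L)
  dat <- simulate_phenotypes(cfg)
  fit <- noia_fit(dat, sp, "trait")
  reps <- simulate(fit, nsim = 2L, seed = 7L)
  expect_length(reps, 2L)
  expect_equal(nrow(reps[[1L]]), fit$n_obs)
  expect_equal(sort(unique(reps[[1L]]$cohort)), sort(unique(dat$cohort)))
  expect_false(identical(reps[[1L]]$trait, reps[[2L]]$trait))
})
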