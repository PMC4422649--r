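test_that("genotype distribution follows Hardy-Weinberg x linkage equilibrium", {
  gd <- genotype_distribution(0.5, noia_spec("x1"))
  expect_equal(gd$prob, c(0.25, 0.5, 0.25))
  # fixation at both loci: a single genotype with probability 1
  gd2 <- genotype_distribution(c(1, 0), noia_spec(c("A", "B")))
  expect_equal(sum(gd2$prob > 0), 1L)
  expect_equal(gd2$support[gd2$prob == 1, ], c(A = 2L, B = 0L))
  # random frequencies: probabilities sum to 1, marginals recover p
  set.seed(3)
  sp <- noia_spec(c("A", "B", "C"))
  p <- runif(3)
  gd3 <- genotype_distribution(p, sp)
  expect_equal(sum(gd3$prob), 1, tolerance = 1e-12)
  marg <- colSums(gd3$prob * gd3$support) / 2
  expect_equal(unname(marg), p, tolerance = 1e-12)
})

test_that("genotypic values expand the effect estimates correctly", {
  sp <- two_locus_spec()
  eff <- noia_effects(c(mu = 10, a_x1 = 1.5), spec = sp)
  expect_equal(genotypic_value(eff, cbind(x1 = 0L, x2 = 0L)), 10)  # reference
  expect_equal(genotypic_value(eff, cbind(x1 = 2L, x2 = 0L)), 13)
  eff2 <- noia_effects(c(mu = 0, a_x1 = 1, a_x2 = 1, aa_x1.x2 = 0.5), spec = sp)
  expect_equal(genotypic_value(eff2, cbind(x1 = 2L, x2 = 2L)), 6)  # 2+2+4*0.5
})

test_that("single-locus additive variance matches the closed forms", {
  expect_equal(single_locus_va(1, 0, 0.5), 0.5)
  expect_equal(single_locus_va(0, 1, 0.5), 0)  # symmetric overdominance
  expect_equal(single_locus_va(1, 0, 0.5, c(0.1, 0, 0)), 0.45)
  # full correction formula with q != p
  a <- 0.7; d <- -0.3; p <- 0.3; q <- 1 - p
  s <- c(0.02, 0.005, 0.01)
  expect_equal(single_locus_va(a, d, p, s),
               2 * p * q * (a + d * (q - p))^2 -
                 2 * p * q * (s[1] + 2 * (q - p) * s[2] + (q - p)^2 * s[3]))
  # matrix form of s agrees with the vector form
  S <- matrix(c(s[1], s[2], s[2], s[3]), 2)
  expect_equal(single_locus_va(a, d, p, S), single_locus_va(a, d, p, s))
})

test_that("moment-factorized variances equal the enumeration backend", {
  set.seed(17)
  for (i in 1:20) {
    L <- sample(2:4, 1L)
    sp <- rand_spec(L)
    eff <- rand_effects(sp, with_S = TRUE)
    p <- runif(L)
    for (corr in c(FALSE, TRUE)) for (eq in c("covariance", "sd_product")) {
      v1 <- suppressWarnings(total_genetic_variance(
        eff, p, corrected = corr, eq_mean_sq = eq))
      v2 <- suppressWarnings(total_genetic_variance(
        eff, p, corrected = corr, method = "enumeration", eq_mean_sq = eq))
      expect_lt(abs(v1 - v2), 1e-10 * max(1, abs(v2)))
    }
  }
})

test_that("zero sampling covariance makes corrected equal uncorrected", {
  set.seed(23)
  sp <- rand_spec(3L, 2L)
  eff <- rand_effects(sp, with_S = FALSE)
  p <- runif(3)
  expect_equal(total_genetic_variance(eff, p, corrected = TRUE),
               total_genetic_variance(eff, p))
  expect_equal(additive_variance(eff, p, corrected = TRUE)$va,
               additive_variance(eff, p)$va)
})

test_that("average effects match closed forms and the regression oracle", {
  # no epistasis, d = 0: alpha = a at every p (horizontal trajectory)
  sp1 <- noia_spec("k")
  eff_add <- noia_effects(c(mu = 0, a_k = 1.3), spec = sp1)
  for (p in c(0.1, 0.35, 0.8)) {
    expect_equal(average_effect(eff_add, p, "k")$alpha, 1.3)
  }
  # no epistasis with dominance: alpha = a + d(q - p)
  eff_dom <- noia_effects(c(mu = 0, a_k = 1, d_k = 0.5), spec = sp1)
  ae <- average_effect(eff_dom, 0.25, "k")
  expect_equal(ae$alpha, 1 + 0.5 * (0.75 - 0.25))  # 1.25
  expect_equal(ae$alpha, ae$alpha1 - ae$alpha2)
  expect_equal(oracle_alpha_regression(eff_dom, 0.25, "k"), 1.25)
  # with additive-by-additive epistasis, alpha_1 moves with p_2 and tracks
  # the enumeration-regression oracle
  sp2 <- two_locus_spec()
  eff_epi <- noia_effects(c(mu = 0, a_x1 = 1, d_x1 = 0.2, a_x2 = 0.5,
                            aa_x1.x2 = 0.6), spec = sp2)
  alphas <- numeric(5)
  for (i in seq_along(p2 <- c(0.05, 0.25, 0.5, 0.75, 0.95))) {
    p <- c(0.4, p2[i])
    got <- average_effect(eff_epi, p, "x1")$alpha
    expect_equal(got, oracle_alpha_regression(eff_epi, p, "x1"),
                 tolerance = 1e-10)
    alphas[i] <- got
  }
  expect_gt(diff(range(alphas)), 0.1)  # background dependence is real
  # coefficient vector reproduces alpha as a linear form
  ae2 <- average_effect(eff_epi, c(0.4, 0.25), "x1")
  expect_equal(sum(ae2$coeff * eff_epi$b[names(ae2$coeff)]), ae2$alpha)
})

test_that("fixed loci give zero contribution and finite alpha", {
  sp <- two_locus_spec()
  eff <- noia_effects(c(mu = 0, a_x1 = 1, d_x1 = 0.3, a_x2 = 0.5,
                        aa_x1.x2 = 0.4), spec = sp)
  ae <- average_effect(eff, c(1, 0.5), "x1")
  expect_true(is.finite(ae$alpha))
  expect_equal(ae$contribution, 0)
  expect_equal(total_genetic_variance(eff, c(1, 0)), 0)
  expect_equal(additive_variance(eff, c(0, 1))$va, 0)
})

test_that("additive variance sums independent single-locus contributions", {
  sp <- noia_spec(c("A", "B", "C"))
  eff <- noia_effects(c(mu = 5, a_A = 1, d_A = 0.5, a_B = -0.7, d_B = 0.1,
                        a_C = 0.3, d_C = -0.2), spec = sp)
  p <- c(0.2, 0.5, 0.7)
  va <- additive_variance(eff, p)$va
  expected <- single_locus_va(1, 0.5, 0.2) + single_locus_va(-0.7, 0.1, 0.5) +
    single_locus_va(0.3, -0.2, 0.7)
  expect_equal(va, expected, tolerance = 1e-12)
  # without epistasis V_G decomposes into V_A + dominance remainder >= V_A
  vg <- total_genetic_variance(eff, p)
  expect_gte(vg, va - 1e-12)
})

test_that("V_A never exceeds V_G for exact effects (projection property)", {
  set.seed(37)
  for (i in 1:25) {
    L <- sample(2:4, 1L)
    sp <- rand_spec(L)
    eff <- rand_effects(sp)
    p <- runif(L)
    va <- additive_variance(eff, p)$va
    vg <- total_genetic_variance(eff, p)
    expect_lte(va, vg + 1e-10)
    # V_A equals the variance of the best allele-count linear predictor
    expect_equal(va, oracle_va_regression(eff, p), tolerance = 1e-8)
  }
})

test_that("variances are invariant to relabelling the loci", {
  set.seed(41)
  sp <- noia_spec(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  eff <- rand_effects(sp, with_S = TRUE)
  p <- c(0.3, 0.6, 0.8)
  # same model with loci declared in reverse order
  sp_r <- noia_spec(c("C", "B", "A"), rbind(c("B", "A"), c("C", "B")))
  # map effects: a/d keep locus names; pair labels follow declared order, and
  # ad/da swap when the within-pair order flips
  map <- c(mu = "mu", a_A = "a_A", a_B = "a_B", a_C = "a_C",
           d_A = "d_A", d_B = "d_B", d_C = "d_C",
           aa_A.B = "aa_B.A", ad_A.B = "da_B.A", da_A.B = "ad_B.A",
           dd_A.B = "dd_B.A",
           aa_B.C = "aa_C.B", ad_B.C = "da_C.B", da_B.C = "ad_C.B",
           dd_B.C = "dd_C.B")
  labs_r <- c("mu", noiavar:::design_labels(sp_r))
  b_r <- setNames(numeric(length(labs_r)), labs_r)
  b_r[map[eff$labels]] <- eff$b
  S_r <- matrix(0, length(labs_r), length(labs_r),
                dimnames = list(labs_r, labs_r))
  S_r[map[eff$labels], map[eff$labels]] <- eff$S
  eff_r <- noia_effects(b_r, S_r, sp_r)
  p_r <- c(0.8, 0.6, 0.3)
  for (corr in c(FALSE, TRUE)) {
    expect_equal(suppressWarnings(total_genetic_variance(eff, p, corrected = corr)),
                 suppressWarnings(total_genetic_variance(eff_r, p_r, corrected = corr)),
                 tolerance = 1e-10)
    expect_equal(suppressWarnings(additive_variance(eff, p, corrected = corr)$va),
                 suppressWarnings(additive_variance(eff_r, p_r, corrected = corr)$va),
                 tolerance = 1e-10)
  }
})

test_that("zero epistatic effects make the epistasis flag irrelevant", {
  set.seed(43)
  sp <- noia_spec(c("A", "B"), rbind(c("A", "B")))
  labs <- c("mu", noiavar:::design_labels(sp))
  b <- setNames(numeric(length(labs)), labs)
  b[c("mu", "a_A", "d_A", "a_B", "d_B")] <- c(3, 1, 0.4, -0.6, 0.2)
  # covariance only among the single-locus block
  S <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  sub <- c("mu", "a_A", "d_A", "a_B", "d_B")
  S[sub, sub] <- rand_psd(sub)
  eff <- noia_effects(b, S, sp)
  p <- c(0.35, 0.65)
  for (corr in c(FALSE, TRUE)) {
    expect_equal(total_genetic_variance(eff, p, corrected = corr, epistasis = TRUE),
                 total_genetic_variance(eff, p, corrected = corr, epistasis = FALSE),
                 tolerance = 1e-12)
  }
  expect_equal(average_effect(eff, p, "A", epistasis = TRUE)$alpha,
               average_effect(eff, p, "A", epistasis = FALSE)$alpha)
})

test_that("corrected estimators are unbiased in Monte Carlo, uncorrected biased up", {
  set.seed(47)
  sp <- noia_spec(c("A", "B"), rbind(c("A", "B")))
  truth <- rand_effects(sp)
  labs <- truth$labels
  S <- rand_psd(labs, scale = 0.3)
  p <- c(0.4, 0.7)
  true_vg <- total_genetic_variance(truth, p)
  true_va <- additive_variance(truth, p)$va
  n_draw <- 2000L
  B <- rmvn(n_draw, truth$b, S)
  vg_c <- vg_u <- va_c <- va_u <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    eff_i <- noia_effects(setNames(B[i, ], labs), S, sp)
    vg_u[i] <- total_genetic_variance(eff_i, p)
    vg_c[i] <- suppressWarnings(total_genetic_variance(eff_i, p, corrected = TRUE))
    va_u[i] <- additive_variance(eff_i, p)$va
    va_c[i] <- suppressWarnings(additive_variance(eff_i, p, corrected = TRUE)$va)
  }
  mc_se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(vg_c) - true_vg), 3 * mc_se(vg_c))
  expect_lt(abs(mean(va_c) - true_va), 3 * mc_se(va_c))
  expect_gt(mean(vg_u), true_vg + 3 * mc_se(vg_u))
  expect_gt(mean(va_u), true_va + 3 * mc_se(va_u))
  # the alternative mean-square form does not deliver unbiasedness here
  vg_sd <- vapply(seq_len(200L), function(i) {
    eff_i <- noia_effects(setNames(B[i, ], labs), S, sp)
    suppressWarnings(total_genetic_variance(eff_i, p, corrected = TRUE,
                                            eq_mean_sq = "sd_product"))
  }, numeric(1))
  expect_false(isTRUE(all.equal(mean(vg_sd), mean(vg_c[1:200]), tolerance = 1e-3)))
})

test_that("negative corrected variances are reported with a warning, not clipped", {
  sp <- noia_spec("k")
  labs <- c("mu", "a_k", "d_k")
  b <- setNames(c(0, 0.1, 0), labs)
  S <- diag(c(0, 1, 0)); dimnames(S) <- list(labs, labs)
  eff <- noia_effects(b, S, sp)
  expect_warning(v <- total_genetic_variance(eff, 0.5, corrected = TRUE),
                 "negative")
  expect_lt(v, 0)
})
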