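# Shared fixtures and independent oracles for the suite.

# random symmetric positive semidefinite matrix with given labels
rand_psd <- function(labels, scale = 0.1) {
  n <- length(labels)
  M <- matrix(rnorm(n * n), n)
  S <- crossprod(M) * scale / n
  dimnames(S) <- list(labels, labels)
  S
}

# multivariate normal draws via Cholesky (rows = draws)
rmvn <- function(n, mu, S) {
  R <- chol(S + diag(1e-12, nrow(S)))
  sweep(matrix(rnorm(n * length(mu)), n) %*% R, 2L, mu, "+")
}

# a random spec with L loci and a random subset of pairs
rand_spec <- function(L, n_pairs = NULL) {
  loci <- paste0("L", seq_len(L))
  if (L < 2L) return(noia_spec(loci, NULL))
  all_p <- t(utils::combn(loci, 2L))
  if (is.null(n_pairs)) n_pairs <- sample.int(nrow(all_p), 1L)
  noia_spec(loci, all_p[sample.int(nrow(all_p), n_pairs), , drop = FALSE])
}

# random effects object (optionally with a PSD sampling covariance)
rand_effects <- function(spec, with_S = FALSE, sd_single = 0.6, sd_epi = 0.4) {
  labs <- c("mu", noiavar:::design_labels(spec))
  b <- setNames(numeric(length(labs)), labs)
  b["mu"] <- rnorm(1, 10, 2)
  single <- grepl("^[ad]_", labs)
  b[single] <- rnorm(sum(single), 0, sd_single)
  epi <- !single & labs != "mu"
  b[epi] <- rnorm(sum(epi), 0, sd_epi)
  S <- if (with_S) rand_psd(labs) else NULL
  noia_effects(b, S, spec)
}

# Independent V_A oracle: weighted least-squares regression of the
# enumerated genotypic values on per-locus donor-allele counts under the
# HW x LE genotype distribution; V_A is the variance of the fitted values.
oracle_va_regression <- function(effects, p, epistasis = TRUE) {
  sp <- effects$spec
  gd <- genotype_distribution(p, sp)
  Z <- genotypic_value(effects, gd$support, epistasis = epistasis)
  w <- gd$prob
  X <- cbind(1, gd$support)
  keep <- c(TRUE, apply(gd$support, 2L, function(x) {
    stats::weighted.mean((x - stats::weighted.mean(x, w))^2, w) > 1e-14
  }))
  X <- X[, keep, drop = FALSE]
  beta <- solve(crossprod(X * w, X), crossprod(X * w, Z))
  fitted <- drop(X %*% beta)
  sum(w * (fitted - sum(w * fitted))^2)
}

# Independent average-effect oracle: the partial regression coefficient of
# the enumerated genotypic value on donor-allele count at one locus.
oracle_alpha_regression <- function(effects, p, locus, epistasis = TRUE) {
  sp <- effects$spec
  gd <- genotype_distribution(p, sp)
  Z <- genotypic_value(effects, gd$support, epistasis = epistasis)
  w <- gd$prob
  X <- cbind(1, gd$support)
  sdv <- apply(gd$support, 2L, function(x)
    stats::weighted.mean((x - stats::weighted.mean(x, w))^2, w))
  keep <- c(TRUE, sdv > 1e-14)
  beta <- solve(crossprod(X[, keep] * w, X[, keep]), crossprod(X[, keep] * w, Z))
  k <- which(colnames(X)[keep] == locus)
  drop(beta[k])
}

# small two-locus truth shared by fitting tests
two_locus_truth <- function() {
  c(mu = 10, a_x1 = 1, d_x1 = 0.5, a_x2 = -0.8, d_x2 = 0.2,
    aa_x1.x2 = 0.4, ad_x1.x2 = -0.3, da_x1.x2 = 0.1, dd_x1.x2 = 0.25)
}

two_locus_spec <- function() noia_spec(c("x1", "x2"), rbind(c("x1", "x2")))
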