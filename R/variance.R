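#' Multilocus genotype distribution under Hardy-Weinberg proportions
#'
#' Enumerates all 3^L multilocus genotypes and their population frequencies
#' as the product of per-locus Hardy-Weinberg genotype probabilities
#' (linkage equilibrium): at a locus with donor-allele frequency p, the
#' genotype probabilities are q^2, 2pq, p^2 for 0, 1, 2 donor alleles.
#'
#' @param freqs donor-allele frequency per locus (each in [0, 1]); a single
#'   value is recycled across loci.
#' @param spec a \code{\link{noia_spec}}.
#' @return List of class \code{"genotype_distribution"} with \code{support}
#'   (3^L x L donor-allele-count matrix) and \code{prob} (frequencies,
#'   summing to 1).
#' @examples
#' gd <- genotype_distribution(0.5, noia_spec("x1"))
#' gd$prob  # 0.25 0.50 0.25
#' @export
genotype_distribution <- function(freqs, spec) {
  p <- validate_freqs(freqs, spec)
  L <- length(spec$loci)
  if (L > 12L) stop("enumeration over 3^", L, " genotypes is not sensible")
  G <- all_genotypes(spec)
  prob <- rep(1, nrow(G))
  for (l in seq_len(L)) {
    pl <- unname(p[l])
    hw <- c((1 - pl)^2, 2 * pl * (1 - pl), pl^2)
    prob <- prob * hw[G[, l] + 1L]
  }
  structure(list(support = G, prob = prob, freqs = p),
            class = "genotype_distribution")
}

validate_freqs <- function(freqs, spec) {
  L <- length(spec$loci)
  p <- as.numeric(freqs)
  if (length(p) == 1L) p <- rep(p, L)
  if (length(p) != L)
    stop("expected ", L, " allele frequencies, got ", length(p))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("allele frequencies must lie in [0, 1]")
  names(p) <- spec$loci
  p
}

# Per-locus moments of the NOIA index variables under HW proportions,
# indexed by the column codes (0 = absent, 1 = additive, 2 = dominance).
# first_moment[c+1] = E[factor]; second_moment[c1+1, c2+1] = E[f1 f2].
locus_moments <- function(p) {
  q <- 1 - p
  m1 <- c(1, 2 * p, 2 * p * q)
  m2 <- matrix(c(1,          2 * p,             2 * p * q,
                 2 * p,      4 * p^2 + 2 * p * q, 2 * p * q,
                 2 * p * q,  2 * p * q,          2 * p * q),
               3L, 3L, byrow = TRUE)
  list(m1 = m1, m2 = m2)
}

# First- and second-moment vectors/matrices of all design columns
# (including the intercept row "mu") under HW x linkage equilibrium:
# E[X_i] and E[X_i X_k] factorize across loci because each column touches
# each locus through at most one index variable.
design_moments <- function(spec, p) {
  codes <- column_codes(spec)
  B <- nrow(codes)
  M1 <- rep(1, B)
  M2 <- matrix(1, B, B)
  for (l in seq_along(spec$loci)) {
    mom <- locus_moments(p[l])
    idx <- codes[, l] + 1L
    M1 <- M1 * mom$m1[idx]
    M2 <- M2 * mom$m2[idx, idx]
  }
  dimnames(M2) <- list(rownames(codes), rownames(codes))
  names(M1) <- rownames(codes)
  list(M1 = M1, M2 = M2)
}

# Align an effects object to the label set of `spec` (subsetting b and S);
# used to evaluate no-epistasis quantities from a full effect set.
align_effects <- function(effects, spec) {
  labels <- c("mu", design_labels(spec))
  missing <- setdiff(labels, effects$labels)
  if (length(missing))
    stop("effects lack label(s): ", paste(missing, collapse = ", "))
  list(b = effects$b[labels], S = effects$S[labels, labels, drop = FALSE],
       labels = labels)
}

#' Single-locus additive genetic variance, with optional bias correction
#'
#' For one biallelic locus with additive effect a, dominance deviation d and
#' donor-allele frequency p, the additive variance is
#' \eqn{V_A = 2pq[a + d(q - p)]^2}. When the sampling (co)variance of the
#' effect estimates is supplied, the estimation-error bias
#' \eqn{2pq(s_a^2 + 2(q-p)s_{ad} + (q-p)^2 s_d^2)} is subtracted, giving the
#' bias-corrected estimator; the corrected value may be negative and is
#' never truncated.
#'
#' @param a,d additive effect and dominance deviation (trait units).
#' @param p donor-allele frequency.
#' @param s optional 2x2 sampling (co)variance matrix of (a, d), or a
#'   length-3 vector \code{c(s_a2, s_ad, s_d2)}.
#' @return The (corrected, if \code{s} is given) additive variance.
#' @examples
#' single_locus_va(1, 0, 0.5)                 # 0.5
#' single_locus_va(1, 0, 0.5, c(0.1, 0, 0))   # 0.45
#' @export
single_locus_va <- function(a, d, p, s = NULL) {
  stopifnot(p >= 0, p <= 1)
  q <- 1 - p
  va <- 2 * p * q * (a + d * (q - p))^2
  if (!is.null(s)) {
    if (is.matrix(s)) s <- c(s[1L, 1L], s[1L, 2L], s[2L, 2L])
    va <- va - 2 * p * q * (s[1L] + 2 * (q - p) * s[2L] + (q - p)^2 * s[3L])
  }
  va
}

#' Total genetic variance from genetic effects and allele frequencies
#'
#' Computes \eqn{V_G = E[Z_G^2] - E[Z_G]^2} over the Hardy-Weinberg /
#' linkage-equilibrium distribution of multilocus genotypes, where
#' \eqn{Z_G} is the predicted genotypic value. With \code{corrected = TRUE}
#' the estimation-error bias is removed: every product of effect estimates
#' \eqn{\hat b_i \hat b_k} in the expansion of both \eqn{E[Z_G^2]} and
#' \eqn{E[Z_G]^2} is replaced by \eqn{\hat b_i \hat b_k - s_{\hat b_i \hat
#' b_k}}, using the full sampling (co)variance matrix of the estimates.
#' Corrected values may be negative; they are reported as computed (with a
#' warning), never truncated.
#'
#' The default backend factorizes the required moments per locus (valid
#' under linkage equilibrium) and costs O(B^2 L); \code{method =
#' "enumeration"} sums over all 3^L genotypes and is retained as an exact
#' cross-check.
#'
#' @param effects a \code{\link{noia_effects}} object.
#' @param freqs donor-allele frequency per locus.
#' @param corrected subtract the estimation-error bias?
#' @param epistasis include epistatic effects (default: as modelled)? When
#'   \code{FALSE}, only the mu/a/d entries of the effect vector (and their
#'   covariances) enter.
#' @param method \code{"moments"} (factorized) or \code{"enumeration"}.
#' @param eq_mean_sq how the \eqn{E[Z_G]^2} term is corrected:
#'   \code{"covariance"} subtracts the sampling covariance
#'   \eqn{s_{\hat b_i \hat b_k}} (the unbiased form, default);
#'   \code{"sd_product"} subtracts the product of standard errors
#'   \eqn{s_{\hat b_i} s_{\hat b_k}}, provided for comparison with the
#'   alternative published form.
#' @return The total genetic variance (trait units^2).
#' @export
total_genetic_variance <- function(effects, freqs, corrected = FALSE,
                                   epistasis = effects$spec$epistasis,
                                   method = c("moments", "enumeration"),
                                   eq_mean_sq = c("covariance", "sd_product")) {
  stopifnot(inherits(effects, "noia_effects"))
  method <- match.arg(method)
  eq_mean_sq <- match.arg(eq_mean_sq)
  sp <- effects$spec
  sp$epistasis <- isTRUE(epistasis)
  p <- validate_freqs(freqs, sp)
  eff <- align_effects(effects, sp)
  if (corrected && all(eff$S == 0) && !is.null(attr(effects, "exact")))
    warning("corrected variance requested but sampling covariance is all zero")

  if (method == "moments") {
    mom <- design_moments(sp, p)
    Cmat <- mom$M2 - tcrossprod(mom$M1)
    vg <- drop(crossprod(eff$b, Cmat %*% eff$b))
    if (corrected) {
      vg <- if (eq_mean_sq == "covariance") {
        vg - sum(Cmat * eff$S)
      } else {
        sdev <- sqrt(pmax(diag(eff$S), 0))
        vg - sum(mom$M2 * eff$S) + sum(mom$M1 * sdev)^2
      }
    }
  } else {
    gd <- genotype_distribution(p, sp)
    X <- cbind(mu = 1, build_design(gd$support, sp))
    Z <- drop(X %*% eff$b)
    EZ <- sum(gd$prob * Z)
    EZ2 <- sum(gd$prob * Z^2)
    vg <- EZ2 - EZ^2
    if (corrected) {
      EZ2c <- EZ2 - sum(gd$prob * rowSums((X %*% eff$S) * X))
      xbar <- colSums(gd$prob * X)
      EZsqc <- if (eq_mean_sq == "covariance") {
        EZ^2 - drop(crossprod(xbar, eff$S %*% xbar))
      } else {
        EZ^2 - sum(xbar * sqrt(pmax(diag(eff$S), 0)))^2
      }
      vg <- EZ2c - EZsqc
    }
  }
  if (corrected && vg < 0)
    warning("bias-corrected V_G is negative (", signif(vg, 4),
            "); reported as computed")
  unname(vg)
}

#' Average effect of allele substitution at a locus
#'
#' The average effect \eqn{\alpha_k = \alpha_{k,1} - \alpha_{k,2}} is the
#' frequency-weighted difference between the allelic average effects
#' \eqn{\alpha_{k,1} = p_k E[Z|W_kW_k] + q_k E[Z|W_kw_k]} and
#' \eqn{\alpha_{k,2} = p_k E[Z|W_kw_k] + q_k E[Z|w_kw_k]}, where the
#' conditional means average the predicted genotypic value over
#' Hardy-Weinberg / linkage-equilibrium genotypes at all other loci. The
#' average effect is a linear function of the genetic effects,
#' \eqn{\alpha_k = c_k^\top \hat b}; the coefficient vector is returned so
#' that the bias-corrected square \eqn{(c_k^\top \hat b)^2 - c_k^\top S
#' c_k} can be formed. With epistasis excluded,
#' \eqn{\alpha_k = a_k + d_k (q_k - p_k)}, independent of other loci.
#'
#' @inheritParams total_genetic_variance
#' @param locus locus identifier (or index) at which to compute the effect.
#' @return List of class \code{"average_effect"}: \code{locus}, \code{p},
#'   \code{alpha}, \code{alpha1}, \code{alpha2}, \code{coeff} (named vector
#'   c_k over all effect labels), \code{contribution}
#'   (\eqn{2 p_k q_k \alpha_k^2}, uncorrected).
#' @export
average_effect <- function(effects, freqs, locus,
                           epistasis = effects$spec$epistasis) {
  stopifnot(inherits(effects, "noia_effects"))
  sp <- effects$spec
  sp$epistasis <- isTRUE(epistasis)
  p <- validate_freqs(freqs, sp)
  eff <- align_effects(effects, sp)
  k <- if (is.character(locus)) match(locus, sp$loci) else as.integer(locus)
  if (is.na(k) || k < 1L || k > length(sp$loci))
    stop("unknown locus: ", locus)

  codes <- column_codes(sp)
  # base_i = E[prod of factors at loci other than k]
  base <- rep(1, nrow(codes))
  for (l in seq_along(sp$loci)) {
    if (l == k) next
    base <- base * locus_moments(p[l])$m1[codes[, l] + 1L]
  }
  pk <- p[k]; qk <- 1 - pk
  # Factor value at locus k per genotype state (columns ww, Ww, WW):
  # code 0 -> 1,1,1 ; code 1 (additive) -> 0,1,2 ; code 2 (dominance) -> 0,1,0
  fk <- rbind(`0` = c(1, 1, 1), `1` = c(0, 1, 2), `2` = c(0, 1, 0))
  fmat <- fk[codes[, k] + 1L, , drop = FALSE]  # rows: effects; cols: ww,Ww,WW
  cond_mean <- drop(crossprod(fmat * base, eff$b))
  names(cond_mean) <- c("ww", "Ww", "WW")
  alpha1 <- pk * cond_mean["WW"] + qk * cond_mean["Ww"]
  alpha2 <- pk * cond_mean["Ww"] + qk * cond_mean["ww"]
  coeff <- base * (pk * (fmat[, 3L] - fmat[, 2L]) + qk * (fmat[, 2L] - fmat[, 1L]))
  names(coeff) <- eff$labels
  alpha <- sum(coeff * eff$b)
  structure(list(locus = sp$loci[k], p = unname(pk), alpha = unname(alpha),
                 alpha1 = unname(alpha1), alpha2 = unname(alpha2),
                 coeff = coeff, cond_mean = cond_mean,
                 contribution = unname(2 * pk * qk * alpha^2)),
            class = "average_effect")
}

#' @export
print.average_effect <- function(x, ...) {
  cat("Average effect at locus ", x$locus, " (p = ", signif(x$p, 4), "): alpha = ",
      signif(x$alpha, 5), "  [2pq alpha^2 = ", signif(x$contribution, 5), "]\n",
      sep = "")
  invisible(x)
}

#' Additive genetic variance across loci, with optional bias correction
#'
#' \eqn{V_A = \sum_k 2 p_k q_k \alpha_k^2}, summing the locus-specific
#' contributions of the average effects (\code{\link{average_effect}}).
#' With \code{corrected = TRUE} each squared average effect is replaced by
#' the bias-corrected quadratic form \eqn{(c_k^\top \hat b)^2 - c_k^\top S
#' c_k}, which removes the upward bias that squaring an error-laden linear
#' estimator introduces. Corrected contributions (and hence \eqn{V_A}) may
#' be negative and are never truncated.
#'
#' @inheritParams total_genetic_variance
#' @return Object of class \code{"noia_va"}: list with \code{va}, and
#'   \code{per_locus} (data frame: locus, p, alpha, alpha1, alpha2,
#'   contribution), plus the flags used.
#' @export
additive_variance <- function(effects, freqs, corrected = FALSE,
                              epistasis = effects$spec$epistasis) {
  stopifnot(inherits(effects, "noia_effects"))
  sp <- effects$spec
  sp$epistasis <- isTRUE(epistasis)
  p <- validate_freqs(freqs, sp)
  eff <- align_effects(effects, sp)
  rows <- lapply(seq_along(sp$loci), function(k) {
    ae <- average_effect(effects, p, k, epistasis = epistasis)
    contrib <- ae$contribution
    if (corrected) {
      contrib <- 2 * ae$p * (1 - ae$p) *
        (ae$alpha^2 - drop(crossprod(ae$coeff, eff$S %*% ae$coeff)))
    }
    data.frame(locus = ae$locus, p = ae$p, alpha = ae$alpha,
               alpha1 = ae$alpha1, alpha2 = ae$alpha2,
               contribution = contrib, stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  va <- sum(per_locus$contribution)
  if (corrected && va < 0)
    warning("bias-corrected V_A is negative (", signif(va, 4),
            "); reported as computed")
  structure(list(va = va, per_locus = per_locus, corrected = corrected,
                 epistasis = isTRUE(epistasis)),
            class = "noia_va")
}

#' @export
print.noia_va <- function(x, ...) {
  cat("Additive genetic variance: V_A = ", signif(x$va, 5),
      if (x$corrected) " (bias-corrected)" else " (uncorrected)",
      if (x$epistasis) ", with epistasis" else ", no epistasis", "\n", sep = "")
  print(x$per_locus, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Joint variance-component prediction
#'
#' Convenience wrapper computing total genetic variance, additive variance
#' and per-locus average effects for one set of allele frequencies.
#'
#' @inheritParams total_genetic_variance
#' @return Object of class \code{"noia_variance"}: list with \code{vg},
#'   \code{va}, \code{per_locus}, \code{freqs} and the flags used.
#' @examples
#' sp <- noia_spec("x1")
#' eff <- noia_effects(c(mu = 0, a_x1 = 1), spec = sp)
#' genetic_variances(eff, 0.5)$vg  # 0.5
#' @export
genetic_variances <- function(effects, freqs, corrected = FALSE,
                              epistasis = effects$spec$epistasis,
                              eq_mean_sq = c("covariance", "sd_product")) {
  eq_mean_sq <- match.arg(eq_mean_sq)
  vg <- total_genetic_variance(effects, freqs, corrected = corrected,
                               epistasis = epistasis, eq_mean_sq = eq_mean_sq)
  va <- additive_variance(effects, freqs, corrected = corrected,
                          epistasis = epistasis)
  structure(list(vg = vg, va = va$va, per_locus = va$per_locus,
                 freqs = validate_freqs(freqs, effects$spec),
                 corrected = corrected, epistasis = isTRUE(epistasis),
                 trait = effects$trait),
            class = "noia_variance")
}

#' @export
print.noia_variance <- function(x, ...) {
  cat("Predicted variance components",
      if (!is.null(x$trait)) paste0(" [", x$trait, "]"), ":\n", sep = "")
  cat("  V_G = ", signif(x$vg, 5), ", V_A = ", signif(x$va, 5),
      "  (", if (x$corrected) "bias-corrected" else "uncorrected",
      ", ", if (x$epistasis) "with epistasis" else "no epistasis", ")\n", sep = "")
  invisible(x)
}
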