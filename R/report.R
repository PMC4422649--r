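#' Epistatic deviations between full and single-locus predictions
#'
#' For every modelled DNIL pair and every two-locus genotype class,
#' contrasts the genotypic value predicted with all effects (full fit to
#' the DNIL data) against the non-epistatic value predicted from the
#' single-locus a/d effects of the reduced fit to NIL data. The summary
#' focuses, by default, on the four classes unobserved in single-locus
#' data — both loci non-reference: WW.WW, Ww.WW, WW.Ww, Ww.Ww — and also
#' reports the synergism contrast: the relative difference between the
#' summed absolute non-epistatic and epistatic deviations from the
#' reference genotype (negative values indicate synergism, i.e. epistasis
#' amplifies deviations; positive values indicate diminishing returns).
#'
#' @param full a \code{\link{noia_fit}} (or \code{\link{noia_effects}})
#'   with epistatic terms.
#' @param reduced the single-locus fit (or effects) supplying the
#'   non-epistatic a/d estimates.
#' @param classes \code{"unobserved"} (the four double-non-reference
#'   classes) or \code{"all"} (all nine).
#' @param denominator for the synergism percent difference: normalize the
#'   sum difference by the summed absolute non-epistatic values
#'   (\code{"nonepi"}, default) or by the summed absolute epistatic values
#'   (\code{"epi"}).
#' @return Object of class \code{"epistasis_deviations"}: list with
#'   \code{per_genotype} (data frame: pair, class, value_epi, value_nonepi,
#'   deviation), \code{mean_dev}, \code{sd_dev}, \code{synergism_pct}, and
#'   the options used.
#' @export
epistatic_deviations <- function(full, reduced,
                                 classes = c("unobserved", "all"),
                                 denominator = c("nonepi", "epi")) {
  classes <- match.arg(classes)
  denominator <- match.arg(denominator)
  eff_full <- as_effects(full)
  eff_red <- as_effects(reduced)
  spec <- eff_full$spec
  if (!nrow(spec$pairs)) stop("full model has no modelled pairs")
  L <- length(spec$loci)
  cls <- as.matrix(expand.grid(g1 = 0:2, g2 = 0:2))
  rows <- list()
  for (r in seq_len(nrow(spec$pairs))) {
    i <- spec$pairs[r, 1L]; j <- spec$pairs[r, 2L]
    G <- matrix(0L, 9L, L, dimnames = list(NULL, spec$loci))
    G[, i] <- cls[, 1L]; G[, j] <- cls[, 2L]
    mu_f <- eff_full$b["mu"]; mu_r <- eff_red$b["mu"]
    # deviations from the reference genotype, so intercepts cancel
    z_epi <- genotypic_value(eff_full, G, epistasis = TRUE) - mu_f
    z_non <- genotypic_value(eff_red, G, epistasis = FALSE) - mu_r
    rows[[r]] <- data.frame(
      pair = paste0(spec$loci[i], ":", spec$loci[j]),
      class = paste0(decode_genotype(cls[, 1L]), ".", decode_genotype(cls[, 2L])),
      both_nonref = cls[, 1L] > 0L & cls[, 2L] > 0L,
      value_epi = unname(z_epi), value_nonepi = unname(z_non),
      deviation = unname(z_epi - z_non), stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  sel <- if (classes == "unobserved") per$both_nonref else rep(TRUE, nrow(per))
  dev <- per$deviation[sel]
  denom <- switch(denominator,
                  nonepi = sum(abs(per$value_nonepi[sel])),
                  epi = sum(abs(per$value_epi[sel])))
  syn <- (sum(abs(per$value_nonepi[sel])) - sum(abs(per$value_epi[sel]))) / denom
  structure(list(per_genotype = per, mean_dev = mean(dev), sd_dev = stats::sd(dev),
                 synergism_pct = syn, classes = classes,
                 denominator = denominator,
                 trait = eff_full$trait),
            class = "epistasis_deviations")
}

#' @export
print.epistasis_deviations <- function(x, ...) {
  cat("Epistatic deviations",
      if (!is.null(x$trait)) paste0(" [", x$trait, "]"),
      " over ", x$classes, " genotype classes:\n", sep = "")
  cat("  mean ", signif(x$mean_dev, 3), ", sd ", signif(x$sd_dev, 3),
      "; synergism contrast ", signif(x$synergism_pct, 3),
      " (negative = synergism)\n", sep = "")
  invisible(x)
}

as_effects <- function(x) {
  if (inherits(x, "noia_fit")) x$effects
  else if (inherits(x, "noia_effects")) x
  else stop("expected a noia_fit or noia_effects object")
}

#' Pleiotropy: correlations of genetic effects across traits
#'
#' Pearson correlations (with two-sided p-values) between the genetic
#' effect estimates of each pair of traits, over all genetic effects
#' (single-locus and epistatic; the reference mean is excluded). Labels
#' must align across traits.
#'
#' @param effect_list named list of \code{\link{noia_effects}} (or
#'   \code{noia_fit}) objects, one per trait.
#' @return List with \code{r} and \code{p_value} (trait x trait matrices)
#'   and \code{pairs} (data frame, one row per trait pair).
#' @export
pleiotropy_correlations <- function(effect_list) {
  effs <- lapply(effect_list, as_effects)
  if (length(effs) < 2L) stop("need at least two traits")
  labs0 <- setdiff(effs[[1L]]$labels, "mu")
  for (e in effs[-1L]) {
    if (!identical(setdiff(e$labels, "mu"), labs0))
      stop("effect labels do not align across traits")
  }
  traits <- names(effs)
  if (is.null(traits)) traits <- paste0("trait", seq_along(effs))
  M <- sapply(effs, function(e) e$b[labs0])
  k <- length(traits)
  r <- diag(1, k); pv <- diag(0, k)
  dimnames(r) <- dimnames(pv) <- list(traits, traits)
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ct <- stats::cor.test(M[, i], M[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      trait1 = traits[i], trait2 = traits[j],
      r = unname(ct$estimate), p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  list(r = r, p_value = pv, pairs = do.call(rbind, rows),
       n_effects = length(labs0))
}

#' Average-effect trajectory of a locus across an allele-frequency ensemble
#'
#' Evaluates the average effect of a locus (with epistasis) at each
#' frequency set of an ensemble, plotted against that locus's own
#' frequency; fits an ordinary least-squares line through the scatter; and
#' records the no-epistasis baseline \eqn{\alpha_k(p) = a_k + d_k(1-2p)}
#' (a line with intercept \eqn{a_k + d_k} and slope \eqn{-2 d_k}; exactly
#' horizontal for an additive locus, crossing zero when over- or
#' underdominance emerges).
#'
#' @param effects full-model \code{\link{noia_effects}} (or fit).
#' @param baseline_effects effects supplying the non-epistatic a/d terms
#'   (defaults to \code{effects}).
#' @param ensemble a \code{\link{sample_frequencies}} ensemble.
#' @param locus locus identifier.
#' @return Object of class \code{"alpha_trajectory"}: list with
#'   \code{points} (data frame p, alpha), \code{fit} (intercept, slope of
#'   the OLS line), \code{baseline} (intercept, slope), \code{locus}.
#' @export
alpha_trajectory <- function(effects, ensemble, locus,
                             baseline_effects = effects) {
  eff <- as_effects(effects)
  base <- as_effects(baseline_effects)
  stopifnot(inherits(ensemble, "frequency_ensemble"))
  sets <- ensemble$sets
  k <- if (is.character(locus)) match(locus, eff$spec$loci) else as.integer(locus)
  if (is.na(k)) stop("unknown locus: ", locus)
  alpha <- vapply(seq_len(nrow(sets)), function(s) {
    average_effect(eff, sets[s, ], k, epistasis = TRUE)$alpha
  }, numeric(1))
  p <- sets[, k]
  cf <- stats::coef(stats::lm(alpha ~ p))
  a_k <- base$b[paste0("a_", eff$spec$loci[k])]
  d_k <- base$b[paste0("d_", eff$spec$loci[k])]
  structure(list(points = data.frame(p = unname(p), alpha = unname(alpha)),
                 fit = c(intercept = unname(cf[1L]), slope = unname(cf[2L])),
                 baseline = c(intercept = unname(a_k + d_k),
                              slope = unname(-2 * d_k)),
                 locus = eff$spec$loci[k], trait = eff$trait),
            class = "alpha_trajectory")
}

#' @export
print.alpha_trajectory <- function(x, ...) {
  cat("Average-effect trajectory for locus ", x$locus,
      if (!is.null(x$trait)) paste0(" [", x$trait, "]"), ":\n", sep = "")
  cat("  OLS fit through ", nrow(x$points), " points: alpha = ",
      signif(x$fit["intercept"], 4), " + ", signif(x$fit["slope"], 4), " p\n",
      sep = "")
  cat("  no-epistasis baseline:            alpha = ",
      signif(x$baseline["intercept"], 4), " + ",
      signif(x$baseline["slope"], 4), " p\n", sep = "")
  invisible(x)
}

#' @export
plot.alpha_trajectory <- function(x, ...) {
  plot(x$points$p, x$points$alpha, xlab = "donor-allele frequency p",
       ylab = expression(alpha), main = paste("Locus", x$locus), ...)
  graphics::abline(x$fit["intercept"], x$fit["slope"], lty = 2)
  graphics::abline(x$baseline["intercept"], x$baseline["slope"], lty = 1)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Ensemble summaries of predicted variance components
#'
#' Evaluates V_G and V_A at every frequency set of an ensemble and reports
#' their means and standard deviations plus the ratio of mean V_A to mean
#' V_G (reported as NA when mean V_G is nonpositive).
#'
#' @param effects a \code{\link{noia_effects}} (or fit).
#' @param ensemble a \code{\link{sample_frequencies}} ensemble.
#' @param corrected,epistasis flags passed to the variance engine.
#' @return Object of class \code{"ensemble_summary"}: list with
#'   \code{mean_vg}, \code{sd_vg}, \code{mean_va}, \code{sd_va},
#'   \code{va_vg_ratio}, \code{values} (data frame of per-set vg, va) and
#'   the flags.
#' @export
ensemble_variance_summary <- function(effects, ensemble, corrected = FALSE,
                                      epistasis = NULL) {
  eff <- as_effects(effects)
  if (is.null(epistasis)) epistasis <- eff$spec$epistasis
  stopifnot(inherits(ensemble, "frequency_ensemble"))
  sets <- ensemble$sets
  vals <- t(vapply(seq_len(nrow(sets)), function(s) {
    suppressWarnings(c(
      vg = total_genetic_variance(eff, sets[s, ], corrected = corrected,
                                  epistasis = epistasis),
      va = additive_variance(eff, sets[s, ], corrected = corrected,
                             epistasis = epistasis)$va))
  }, c(vg = 0, va = 0)))
  mean_vg <- mean(vals[, "vg"])
  structure(list(mean_vg = mean_vg, sd_vg = stats::sd(vals[, "vg"]),
                 mean_va = mean(vals[, "va"]), sd_va = stats::sd(vals[, "va"]),
                 va_vg_ratio = if (mean_vg > 0) mean(vals[, "va"]) / mean_vg
                               else NA_real_,
                 values = as.data.frame(vals),
                 distribution = ensemble$distribution,
                 corrected = corrected, epistasis = isTRUE(epistasis),
                 trait = eff$trait),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Variance components over ", nrow(x$values), " frequency sets (",
      x$distribution, " distribution; ",
      if (x$corrected) "bias-corrected" else "uncorrected", ", ",
      if (x$epistasis) "with epistasis" else "no epistasis", ")",
      if (!is.null(x$trait)) paste0(" [", x$trait, "]"), ":\n", sep = "")
  cat("  V_A ", signif(x$mean_va, 3), " (", signif(x$sd_va, 3), ")",
      ";  V_G ", signif(x$mean_vg, 3), " (", signif(x$sd_vg, 3), ")",
      ";  V_A/V_G ", if (is.na(x$va_vg_ratio)) "NA" else signif(x$va_vg_ratio, 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.ensemble_summary <- function(x, which = c("va", "vg"), ...) {
  which <- match.arg(which)
  v <- x$values[[which]]
  plot(stats::density(v), main = paste("Density of",
                                       if (which == "va") "V_A" else "V_G"),
       xlab = "variance (trait units^2)", ...)
  invisible(x)
}
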