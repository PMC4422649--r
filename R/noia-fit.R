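#' Fit the NOIA mixed linear model
#'
#' Fits, for one trait, the linear model whose fixed effects are the NOIA
#' functional genetic effects (additive and dominance terms per locus, plus
#' the four pairwise interaction terms per modelled DNIL pair) and whose
#' random effects are intercepts for greenhouse cohort and for seed family
#' nested within genotype. Estimation is by REML via \pkg{lme4}; an ML refit
#' is stored for likelihood-ratio comparison of nested fixed-effect
#' structures.
#'
#' With \code{scope = "single_locus"} the fit is restricted to plants that
#' are non-reference at no more than one locus (the NIL subset), which is
#' how the non-epistatic ("reduced-data") effect estimates are obtained; in
#' that case the design drops the epistatic columns regardless of
#' \code{spec$epistasis}.
#'
#' @param data a phenotype table: data frame with columns \code{cohort},
#'   \code{family}, one genotype column per locus of \code{spec} (donor
#'   allele counts 0/1/2 or ww/Ww/WW strings), and the trait column.
#' @param spec a \code{\link{noia_spec}}.
#' @param trait name of the trait column to fit. Rows with a missing value
#'   for this trait are dropped (per-trait, not per-plant).
#' @param scope \code{"full"} (all records, design per \code{spec}) or
#'   \code{"single_locus"} (NIL subset, no epistatic columns).
#' @param engine \code{"auto"} fits by REML (\code{lme4::lmer}) and falls
#'   back to ordinary least squares if the mixed fit is degenerate (e.g.
#'   noiseless data or a single cohort and family); \code{"reml"} and
#'   \code{"ols"} force the choice.
#' @param check_rank error (naming a column) if the fixed-effect design is
#'   rank deficient rather than silently dropping columns.
#'
#' @return An object of class \code{"noia_fit"}: list with elements
#'   \code{effects} (a \code{\link{noia_effects}}: estimates + sampling
#'   covariance), \code{spec} (the design actually fitted), \code{trait},
#'   \code{scope}, \code{loglik_reml}, \code{loglik_ml}, \code{aic} (from
#'   the ML fit), \code{varcomp} (named vector: cohort, family, residual
#'   variances), \code{n_obs}, \code{engine}, and \code{model} (the
#'   underlying \code{merMod} or \code{lm} object).
#'
#' @examples
#' sp <- noia_spec(c("x1", "x2"), rbind(c("x1", "x2")))
#' dat <- simulate_phenotypes(simulation_config(sp,
#'   true_effects = c(mu = 10, a_x1 = 1, d_x1 = 0.5, a_x2 = -1),
#'   var_cohort = 0.1, var_family = 0.05, var_residual = 0.5,
#'   n_per_cell = 4, n_cohorts = 2, seed = 1))
#' fit <- noia_fit(dat, sp, trait = "trait")
#' coef(fit)[1:5]
#' @export
noia_fit <- function(data, spec, trait,
                     scope = c("full", "single_locus"),
                     engine = c("auto", "reml", "ols"),
                     check_rank = TRUE) {
  stopifnot(inherits(spec, "noia_spec"))
  scope <- match.arg(scope)
  engine <- match.arg(engine)
  for (col in c("cohort", "family", trait)) {
    if (!col %in% names(data)) stop("data lacks required column '", col, "'")
  }
  G <- genotype_matrix(data[, spec$loci, drop = FALSE], spec)

  keep <- !is.na(data[[trait]])
  fit_spec <- spec
  if (scope == "single_locus") {
    keep <- keep & rowSums(G != 0L) <= 1L
    fit_spec$epistasis <- FALSE
  }
  if (!any(keep)) stop("no usable observations for trait '", trait, "'")
  G <- G[keep, , drop = FALSE]
  y <- as.numeric(data[[trait]][keep])
  # Composite family key enforces nesting of seed family within genotype.
  genostring <- apply(G, 1L, paste, collapse = "")
  fam <- factor(paste(genostring, data$family[keep], sep = "/"))
  coh <- factor(data$cohort[keep])

  X <- build_design(G, fit_spec)
  if (check_rank) {
    qrX <- qr(cbind(`(Intercept)` = 1, X))
    if (qrX$rank < ncol(X) + 1L) {
      dropped <- colnames(qrX$qr)[qrX$pivot[-seq_len(qrX$rank)]]
      stop("design is rank deficient; no informative contrast for: ",
           paste(dropped, collapse = ", "))
    }
  }

  df <- data.frame(y = y, X, check.names = FALSE)
  df$.cohort <- coh
  df$.family <- fam
  fixed <- paste0("y ~ ", paste0("`", colnames(X), "`", collapse = " + "))

  use_ols <- engine == "ols" ||
    (engine == "auto" && (nlevels(coh) < 2L || nlevels(fam) < 2L))
  model <- NULL
  if (!use_ols) {
    form <- stats::as.formula(paste0(fixed, " + (1 | .cohort) + (1 | .family)"))
    model <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(form, data = df, REML = TRUE,
                   control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                               check.nobs.vs.nRE = "ignore",
                                               calc.derivs = FALSE)))),
      error = function(e) {
        if (engine == "reml") stop("REML fit failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(model) && engine == "auto") use_ols <- TRUE
  }

  if (use_ols) {
    if (is.null(model) && engine == "auto" && nlevels(coh) >= 2L && nlevels(fam) >= 2L)
      warning("mixed-model fit failed; falling back to ordinary least squares")
    model <- stats::lm(stats::as.formula(fixed), data = df)
    b <- stats::coef(model)
    if (anyNA(b)) stop("design is rank deficient; no informative contrast for: ",
                       paste(names(b)[is.na(b)], collapse = ", "))
    S <- stats::vcov(model)
    ll_ml <- as.numeric(stats::logLik(model))
    varcomp <- c(cohort = 0, family = 0,
                 residual = sum(stats::residuals(model)^2) / stats::df.residual(model))
    out <- list(loglik_reml = ll_ml, loglik_ml = ll_ml,
                aic = stats::AIC(model), engine = "ols")
  } else {
    b <- lme4::fixef(model)
    S <- as.matrix(stats::vcov(model))
    vc <- as.data.frame(lme4::VarCorr(model))
    getv <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v[1L] else 0 }
    varcomp <- c(cohort = getv(".cohort"), family = getv(".family"),
                 residual = getv("Residual"))
    mlfit <- suppressWarnings(suppressMessages(lme4::refitML(model)))
    out <- list(loglik_reml = as.numeric(stats::logLik(model)),
                loglik_ml = as.numeric(stats::logLik(mlfit)),
                aic = stats::AIC(mlfit), engine = "reml")
  }
  names(b) <- sub("^`|`$", "", gsub("`", "", names(b)))
  dimnames(S) <- list(names(b), names(b))

  structure(c(list(effects = noia_effects(b, S, fit_spec, trait = trait),
                   spec = fit_spec, trait = trait, scope = scope,
                   varcomp = varcomp, n_obs = length(y), model = model),
              out),
            class = "noia_fit")
}

#' @export
print.noia_fit <- function(x, digits = 4, ...) {
  cat("NOIA mixed-model fit: trait '", x$trait, "', ", x$n_obs,
      " observations (", x$scope, " scope, ", x$engine, ")\n", sep = "")
  cat("  fixed effects: ", length(x$effects$b), " (incl. reference mean)\n", sep = "")
  cat("  variance components: cohort ", signif(x$varcomp["cohort"], digits),
      ", family ", signif(x$varcomp["family"], digits),
      ", residual ", signif(x$varcomp["residual"], digits), "\n", sep = "")
  cat("  logLik (REML) ", signif(x$loglik_reml, 7),
      "; logLik (ML) ", signif(x$loglik_ml, 7),
      "; AIC ", signif(x$aic, 7), "\n", sep = "")
  invisible(x)
}

#' @export
summary.noia_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$effects$S), 0))
  z <- object$effects$b / ifelse(se > 0, se, NA)
  tab <- data.frame(estimate = object$effects$b, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab), class = "summary.noia_fit")
}

#' @export
print.summary.noia_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nEffect estimates (Wald z):\n")
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
coef.noia_fit <- function(object, ...) object$effects$b

#' @export
vcov.noia_fit <- function(object, ...) object$effects$S

#' @export
logLik.noia_fit <- function(object, REML = TRUE, ...) {
  ll <- if (REML) object$loglik_reml else object$loglik_ml
  structure(ll, df = length(object$effects$b) + 3L, class = "logLik")
}

#' Predicted genotypic values from a fitted model
#'
#' @param object a \code{\link{noia_fit}}.
#' @param newdata genotype states (matrix/data frame, one column per locus);
#'   defaults to all 3^L multilocus genotypes when the locus count is small.
#' @param epistasis include epistatic terms (default: as fitted).
#' @param ... unused.
#' @return Named vector of predicted genotypic values.
#' @export
predict.noia_fit <- function(object, newdata = NULL,
                             epistasis = object$spec$epistasis, ...) {
  if (is.null(newdata)) {
    L <- length(object$spec$loci)
    if (L > 8L) stop("supply 'newdata'; enumerating 3^", L, " genotypes is not sensible")
    newdata <- all_genotypes(object$spec)
  }
  z <- genotypic_value(object$effects, newdata, epistasis = epistasis)
  G <- genotype_matrix(newdata, object$spec)
  names(z) <- apply(matrix(decode_genotype(G), nrow(G)), 1L, paste, collapse = ":")
  z
}

#' @export
residuals.noia_fit <- function(object, ...) stats::residuals(object$model)

# All 3^L multilocus genotypes as a donor-allele-count matrix (enumeration
# order: first locus varies fastest).
all_genotypes <- function(spec) {
  L <- length(spec$loci)
  G <- as.matrix(expand.grid(rep(list(0:2), L)))
  colnames(G) <- spec$loci
  G
}

#' Likelihood-ratio test for epistasis
#'
#' Compares a full model (with epistatic terms) to a nested reduced model
#' (without), both fitted to the same observations, using maximum-likelihood
#' log-likelihoods: \eqn{X^2 = 2(\ell_{full} - \ell_{red})} referred to a
#' chi-squared distribution with degrees of freedom equal to the difference
#' in parameter counts (REML likelihoods are not comparable across
#' fixed-effect structures, so the ML refits stored by
#' \code{\link{noia_fit}} are used).
#'
#' @param full,reduced \code{\link{noia_fit}} objects for nested
#'   fixed-effect structures fitted to the same data.
#' @return Object of class \code{"noia_lrt"}: list with \code{chi2},
#'   \code{df}, \code{p_value}, and the two ML log-likelihoods.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "noia_fit"), inherits(reduced, "noia_fit"))
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted to different numbers of observations (",
         full$n_obs, " vs ", reduced$n_obs, ")")
  if (!all(reduced$effects$labels %in% full$effects$labels))
    stop("models are not nested: reduced model has effects absent from the full model")
  df <- length(full$effects$labels) - length(reduced$effects$labels)
  chi2 <- max(0, 2 * (full$loglik_ml - reduced$loglik_ml))
  p <- if (df > 0L) stats::pchisq(chi2, df, lower.tail = FALSE) else 1
  structure(list(chi2 = chi2, df = df, p_value = p,
                 loglik_full = full$loglik_ml, loglik_reduced = reduced$loglik_ml),
            class = "noia_lrt")
}

#' @export
print.noia_lrt <- function(x, ...) {
  cat("Likelihood-ratio test for epistasis\n")
  cat("  X^2 = ", signif(x$chi2, 5), ", df = ", x$df,
      ", p = ", format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
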