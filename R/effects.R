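#' Construct a set of genetic-effect estimates
#'
#' Bundles functional effect estimates with their full sampling
#' (co)variance matrix. This is the bridge between model fitting and the
#' variance-component predictions: every downstream quantity (genotypic
#' values, V_G, V_A, average effects) is a function of these estimates, and
#' the bias corrections consume the (co)variance matrix \code{S}.
#'
#' Effects are labelled \code{mu} (the reference-genotype mean),
#' \code{a_<locus>}, \code{d_<locus>}, and \code{aa_/ad_/da_/dd_<i>.<j>} for
#' modelled pairs. Labels absent from \code{b} are treated as exactly zero
#' with zero sampling variance (the convention for DNIL pairs without
#' measurements).
#'
#' @param b named numeric vector of effect estimates (trait units). A
#'   \code{"(Intercept)"} name is normalized to \code{"mu"}; a missing
#'   intercept is taken as 0.
#' @param S sampling (co)variance matrix of the estimates (trait units^2),
#'   with dimnames matching \code{names(b)}; \code{NULL} for exact effects
#'   (all sampling variances zero).
#' @param spec the \code{\link{noia_spec}} the labels refer to.
#' @param trait optional trait name carried along for reporting.
#' @return An object of class \code{"noia_effects"}: list with elements
#'   \code{labels} (full label set \code{c("mu", design labels)}), \code{b}
#'   and \code{S} (aligned to \code{labels}, zero-filled), \code{spec},
#'   \code{trait}.
#' @export
noia_effects <- function(b, S = NULL, spec, trait = NULL) {
  stopifnot(inherits(spec, "noia_spec"))
  nm <- names(b)
  if (is.null(nm)) stop("'b' must be a named vector of effects")
  nm[nm == "(Intercept)"] <- "mu"
  names(b) <- nm
  labels <- c("mu", design_labels(spec))
  unknown <- setdiff(nm, labels)
  if (length(unknown)) stop("unknown effect label(s): ",
                            paste(unknown, collapse = ", "))
  bb <- stats::setNames(numeric(length(labels)), labels)
  bb[nm] <- b
  SS <- matrix(0, length(labels), length(labels),
               dimnames = list(labels, labels))
  if (!is.null(S)) {
    S <- as.matrix(S)
    rn <- rownames(S)
    if (is.null(rn)) {
      if (!identical(dim(S), c(length(nm), length(nm))))
        stop("'S' dimension does not match 'b'")
      rn <- nm
      dimnames(S) <- list(nm, nm)
    }
    rn[rn == "(Intercept)"] <- "mu"
    dimnames(S) <- list(rn, rn)
    if (length(setdiff(rn, labels)))
      stop("'S' carries unknown labels")
    if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S))))
      stop("'S' must be symmetric")
    SS[rn, rn] <- (S + t(S)) / 2
    if (any(diag(SS) < -1e-12)) stop("'S' has negative diagonal entries")
  }
  structure(list(labels = labels, b = bb, S = SS, spec = spec, trait = trait),
            class = "noia_effects")
}

#' @export
print.noia_effects <- function(x, ...) {
  cat("NOIA genetic-effect estimates",
      if (!is.null(x$trait)) paste0(" [", x$trait, "]"), "\n", sep = "")
  se <- sqrt(pmax(diag(x$S), 0))
  df <- data.frame(estimate = x$b, se = se)
  print(utils::head(df, 12L), digits = 4)
  if (nrow(df) > 12L) cat("  ... (", nrow(df) - 12L, " more effects)\n", sep = "")
  invisible(x)
}

#' @export
coef.noia_effects <- function(object, ...) object$b

#' @export
vcov.noia_effects <- function(object, ...) object$S

#' Predict genotypic values from genetic effects
#'
#' The predicted genotypic value of a multilocus genotype is the
#' reference-genotype mean plus the sum of effect estimates weighted by the
#' NOIA index variables: \eqn{\hat Z_{G,u} = \mu + \sum_i \hat b_i X_{i,u}}.
#' With \code{epistasis = FALSE} only the single-locus a/d terms enter (the
#' "non-epistatic" genotypic value).
#'
#' @param effects a \code{\link{noia_effects}} object.
#' @param genotypes genotype states as in \code{\link{build_design}}.
#' @param epistasis include the epistatic terms? Defaults to whether the
#'   effects' spec models them.
#' @return Numeric vector of genotypic values, one per genotype row.
#' @export
genotypic_value <- function(effects, genotypes, epistasis = effects$spec$epistasis) {
  stopifnot(inherits(effects, "noia_effects"))
  sp <- effects$spec
  sp$epistasis <- isTRUE(epistasis)
  X <- build_design(genotypes, sp)
  drop(effects$b["mu"] + X %*% effects$b[colnames(X)])
}

#' Read/write effect estimates and their covariance matrix
#'
#' `write_effects` stores the estimates as a CSV of (label, estimate, se)
#' plus a square CSV for the sampling (co)variance matrix; `read_effects`
#' reloads them against a spec.
#'
#' @param effects a \code{\link{noia_effects}} object.
#' @param file path for the estimate CSV; the covariance matrix goes to
#'   \code{cov_file} (default: same path with \code{"_cov"} inserted).
#' @param cov_file path for the covariance CSV.
#' @param spec the \code{\link{noia_spec}} used to validate labels on read.
#' @param trait optional trait name attached on read.
#' @return \code{read_effects} returns a \code{\link{noia_effects}};
#'   \code{write_effects} returns \code{file} invisibly.
#' @export
write_effects <- function(effects, file,
                          cov_file = sub("(\\.[^.]+)$", "_cov\\1", file)) {
  stopifnot(inherits(effects, "noia_effects"))
  utils::write.csv(data.frame(label = effects$labels,
                              estimate = unname(effects$b),
                              se = sqrt(pmax(diag(effects$S), 0))),
                   file, row.names = FALSE)
  utils::write.csv(data.frame(label = effects$labels, effects$S,
                              check.names = FALSE),
                   cov_file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_effects
#' @export
read_effects <- function(file, spec, trait = NULL,
                         cov_file = sub("(\\.[^.]+)$", "_cov\\1", file)) {
  est <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("label", "estimate") %in% names(est)))
    stop("effect CSV needs columns 'label' and 'estimate'")
  b <- stats::setNames(est$estimate, est$label)
  S <- NULL
  if (file.exists(cov_file)) {
    cv <- utils::read.csv(cov_file, check.names = FALSE, stringsAsFactors = FALSE)
    S <- as.matrix(cv[, -1L, drop = FALSE])
    dimnames(S) <- list(cv$label, colnames(S))
  }
  noia_effects(b, S, spec, trait = trait)
}
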