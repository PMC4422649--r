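#' Define a NOIA model specification
#'
#' A model specification names the biallelic QTL under study and the set of
#' locus pairs for which epistatic (interaction) effects are modelled. In a
#' double-NIL (DNIL) experiment each modelled pair corresponds to one DNIL
#' line set: two donor QTL segregating in an otherwise isogenic background.
#' Pairs not listed contribute no epistatic terms; their interaction effects
#' are treated as exactly zero with zero sampling variance throughout the
#' variance calculations.
#'
#' @param loci character vector of locus identifiers (e.g. \code{"x1"}).
#' @param pairs the modelled QTL pairs: a two-column matrix or data frame of
#'   locus identifiers, a list of length-2 character vectors, or \code{NULL}
#'   for no pairs. Order within a pair is irrelevant; pairs are stored with
#'   loci in declared order and sorted lexicographically so that design
#'   columns (and hence covariance matrices) align across fits.
#' @param epistasis logical; if \code{FALSE} the design carries only the
#'   single-locus additive and dominance columns (the reduced model).
#'
#' @return An object of class \code{"noia_spec"}: a list with elements
#'   \code{loci}, \code{pairs} (integer matrix, one row per pair, columns
#'   \code{i < j} indexing \code{loci}) and \code{epistasis}.
#' @examples
#' sp <- noia_spec(paste0("x", 1:7), pairs = utils::combn(paste0("x", 1:7), 2)[, 1:11])
#' count_parameters(sp)
#' @export
noia_spec <- function(loci, pairs = NULL, epistasis = TRUE) {
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("duplicate locus identifiers")
  if (length(loci) < 1L) stop("at least one locus is required")
  P <- normalize_pairs(pairs, loci)
  structure(list(loci = loci, pairs = P, epistasis = isTRUE(epistasis)),
            class = "noia_spec")
}

normalize_pairs <- function(pairs, loci) {
  if (is.null(pairs) || (is.matrix(pairs) && ncol(pairs) == 0L)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) matrix(p, nrow = 1L)))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L && nrow(pairs) == 2L) {
    pairs <- t(pairs)  # accept the 2 x n layout combn() produces
  } else if (ncol(pairs) == 2L && nrow(pairs) == 2L &&
             (pairs[1L, 1L] == pairs[1L, 2L] || pairs[2L, 1L] == pairs[2L, 2L])) {
    pairs <- t(pairs)  # 2x2 from combn: rows would pair a locus with itself
  }
  if (ncol(pairs) != 2L) stop("'pairs' must have two loci per pair")
  idx <- matrix(match(as.character(pairs), loci), ncol = 2L)
  if (anyNA(idx)) {
    bad <- as.character(pairs)[is.na(match(as.character(pairs), loci))][1L]
    stop("pair references unknown locus: ", bad)
  }
  swap <- idx[, 1L] > idx[, 2L]
  idx[swap, ] <- idx[swap, 2:1]
  if (any(idx[, 1L] == idx[, 2L])) stop("a pair must involve two distinct loci")
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  if (anyDuplicated(idx)) stop("duplicate pairs")
  dimnames(idx) <- list(NULL, c("i", "j"))
  idx
}

#' @export
print.noia_spec <- function(x, ...) {
  cat("NOIA model specification\n")
  cat("  loci  (", length(x$loci), "): ", paste(x$loci, collapse = " "), "\n", sep = "")
  cat("  pairs (", nrow(x$pairs), ")",
      if (nrow(x$pairs)) paste0(": ", paste(pair_labels(x), collapse = " ")), "\n", sep = "")
  cat("  epistatic terms: ", if (x$epistasis) "included" else "excluded", "\n", sep = "")
  invisible(x)
}

pair_labels <- function(spec) {
  if (!nrow(spec$pairs)) return(character(0))
  paste0(spec$loci[spec$pairs[, 1L]], ":", spec$loci[spec$pairs[, 2L]])
}

#' Encode a single-locus genotype as NOIA index variables
#'
#' The functional NOIA coding counts donor (W) alleles for the additive
#' index and flags heterozygosity for the dominance index, so the fully
#' homozygous reference genotype maps to (0, 0) and the inbred reference
#' line is the model's zero point.
#'
#' @param state genotype state(s): donor-allele counts \code{0/1/2} or the
#'   strings \code{"ww"}, \code{"Ww"}, \code{"WW"} (also accepted: "wW").
#' @return A two-column integer matrix with columns \code{xa} (0, 1 or 2
#'   donor alleles) and \code{xd} (1 iff heterozygous), one row per input.
#' @examples
#' encode_locus(c("ww", "Ww", "WW"))
#' @export
encode_locus <- function(state) {
  xa <- genotype_codes(state)
  cbind(xa = xa, xd = as.integer(xa == 1L))
}

# Normalize genotype states to donor-allele counts; errors name the offender.
genotype_codes <- function(state) {
  if (is.numeric(state)) {
    xa <- as.integer(state)
    bad <- which(is.na(xa) | xa < 0L | xa > 2L | xa != state)
  } else {
    map <- c(ww = 0L, wW = 1L, Ww = 1L, WW = 2L, "0" = 0L, "1" = 1L, "2" = 2L)
    xa <- unname(map[as.character(state)])
    bad <- which(is.na(xa))
  }
  if (length(bad)) {
    stop("unknown genotype state '", as.character(state)[bad[1L]],
         "' at position ", bad[1L],
         " (expected 0/1/2 donor-allele counts or ww/Ww/WW)")
  }
  xa
}

# Decode donor-allele counts back to the canonical string states.
decode_genotype <- function(xa) c("ww", "Ww", "WW")[xa + 1L]

#' Build the NOIA design matrix
#'
#' Assembles the functional NOIA design for a set of multilocus genotypes:
#' one additive (\code{a_}) and one dominance (\code{d_}) column per locus,
#' followed, when epistasis is modelled, by the four pairwise-product columns
#' \code{aa_}, \code{ad_}, \code{da_}, \code{dd_} for each modelled pair
#' (\code{ad_i.j} is the product of the additive index at the first-declared
#' locus of the pair and the dominance index at the second).
#'
#' @param genotypes a matrix or data frame of genotype states, one column per
#'   locus of \code{spec} (columns matched by name when named, by position
#'   otherwise), states as in \code{\link{encode_locus}}.
#' @param spec a \code{\link{noia_spec}}.
#' @return Numeric matrix with one row per genotype and labelled columns in
#'   the fixed order described above.
#' @examples
#' sp <- noia_spec(c("x1", "x2"), pairs = rbind(c("x1", "x2")))
#' build_design(rbind(c(2, 2)), sp)
#' @export
build_design <- function(genotypes, spec) {
  G <- genotype_matrix(genotypes, spec)
  L <- length(spec$loci)
  XA <- G
  XD <- matrix(as.integer(G == 1L), nrow(G), L)
  cols <- vector("list", 2L * L + 4L * nrow(spec$pairs) * spec$epistasis)
  labs <- character(length(cols))
  for (l in seq_len(L)) {
    cols[[l]] <- XA[, l]
    labs[l] <- paste0("a_", spec$loci[l])
    cols[[L + l]] <- XD[, l]
    labs[L + l] <- paste0("d_", spec$loci[l])
  }
  if (spec$epistasis && nrow(spec$pairs)) {
    k <- 2L * L
    for (r in seq_len(nrow(spec$pairs))) {
      i <- spec$pairs[r, 1L]; j <- spec$pairs[r, 2L]
      tag <- paste0(spec$loci[i], ".", spec$loci[j])
      cols[[k + 1L]] <- XA[, i] * XA[, j]; labs[k + 1L] <- paste0("aa_", tag)
      cols[[k + 2L]] <- XA[, i] * XD[, j]; labs[k + 2L] <- paste0("ad_", tag)
      cols[[k + 3L]] <- XD[, i] * XA[, j]; labs[k + 3L] <- paste0("da_", tag)
      cols[[k + 4L]] <- XD[, i] * XD[, j]; labs[k + 4L] <- paste0("dd_", tag)
      k <- k + 4L
    }
  }
  X <- do.call(cbind, cols)
  dimnames(X) <- list(rownames(G), labs)
  X
}

# Coerce genotype input to an n x L integer matrix of donor-allele counts,
# columns aligned to spec$loci.
genotype_matrix <- function(genotypes, spec) {
  L <- length(spec$loci)
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes)
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1L)
  if (!is.null(colnames(genotypes))) {
    missing <- setdiff(spec$loci, colnames(genotypes))
    if (length(missing)) stop("genotypes lack locus column(s): ",
                              paste(missing, collapse = ", "))
    genotypes <- genotypes[, spec$loci, drop = FALSE]
  } else if (ncol(genotypes) != L) {
    stop("genotypes have ", ncol(genotypes), " columns; spec has ", L, " loci")
  }
  G <- matrix(genotype_codes(genotypes), nrow(genotypes), L,
              dimnames = list(rownames(genotypes), spec$loci))
  G
}

#' Parameter and degrees-of-freedom accounting for the epistasis test
#'
#' Counts model parameters by the convention used for the overall
#' likelihood-ratio test of epistasis: the genetic-effect columns plus one
#' cohort term and one family term; the intercept is not counted. For the
#' 7-QTL, 11-DNIL study design this gives 60 parameters in the full model,
#' 16 in the reduced (no-epistasis) model, and 44 degrees of freedom for
#' the test.
#'
#' @param spec a \code{\link{noia_spec}}.
#' @return Named integer vector \code{c(n_full, n_reduced, df_lrt)}.
#' @examples
#' sp <- noia_spec(paste0("x", 1:7), utils::combn(paste0("x", 1:7), 2)[, 1:11])
#' count_parameters(sp)  # 60 16 44
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "noia_spec"))
  L <- length(spec$loci)
  n_full <- 2L * L + 4L * nrow(spec$pairs) + 2L
  n_reduced <- 2L * L + 2L
  c(n_full = n_full, n_reduced = n_reduced, df_lrt = n_full - n_reduced)
}

# Per-column locus/factor codes used by the moment-factorized variance
# engine: entry (column, locus) is 0 if the locus does not enter the column,
# 1 if it enters through the additive index, 2 through the dominance index.
# Row 1 is the intercept (all zeros). Each design column touches any locus
# through at most one index, so this table is a complete description.
column_codes <- function(spec) {
  L <- length(spec$loci)
  nP <- if (spec$epistasis) nrow(spec$pairs) else 0L
  B <- 1L + 2L * L + 4L * nP
  codes <- matrix(0L, B, L, dimnames = list(c("mu", design_labels(spec)), spec$loci))
  for (l in seq_len(L)) {
    codes[1L + l, l] <- 1L
    codes[1L + L + l, l] <- 2L
  }
  if (nP) {
    k <- 1L + 2L * L
    for (r in seq_len(nP)) {
      i <- spec$pairs[r, 1L]; j <- spec$pairs[r, 2L]
      codes[k + 1L, c(i, j)] <- c(1L, 1L)
      codes[k + 2L, c(i, j)] <- c(1L, 2L)
      codes[k + 3L, c(i, j)] <- c(2L, 1L)
      codes[k + 4L, c(i, j)] <- c(2L, 2L)
      k <- k + 4L
    }
  }
  codes
}

design_labels <- function(spec) {
  L <- length(spec$loci)
  labs <- c(paste0("a_", spec$loci), paste0("d_", spec$loci))
  if (spec$epistasis && nrow(spec$pairs)) {
    for (r in seq_len(nrow(spec$pairs))) {
      tag <- paste0(spec$loci[spec$pairs[r, 1L]], ".", spec$loci[spec$pairs[r, 2L]])
      labs <- c(labs, paste0(c("aa_", "ad_", "da_", "dd_"), tag))
    }
  }
  labs
}

# Drop epistatic terms from a spec (the reduced model's design).
reduce_spec <- function(spec) {
  out <- spec
  out$epistasis <- FALSE
  out
}
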