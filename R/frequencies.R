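#' Sample ensembles of allele frequencies
#'
#' Draws sets of donor-allele frequencies, one frequency per locus,
#' independently across loci and sets, under either a uniform distribution
#' on [0, 1] or a U-shaped distribution with density proportional to
#' \eqn{1/(p(1-p))} truncated to \eqn{[\epsilon, 1-\epsilon]} — the
#' neutral-theory stationary form that concentrates mass near fixation.
#' The U-shaped draw uses the inverse-CDF method: the CDF is proportional
#' to \eqn{\log(p/(1-p))}, so a uniform deviate is mapped through the
#' logistic function between the truncation logits.
#'
#' @param n_sets number of frequency sets (the study design uses 200).
#' @param spec a \code{\link{noia_spec}} (or an integer locus count).
#' @param distribution \code{"uniform"} or \code{"u_shaped"}.
#' @param eps truncation bound for the U-shaped density (0 < eps < 0.5).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return Object of class \code{"frequency_ensemble"}: list with
#'   \code{sets} (n_sets x L matrix, columns named by locus),
#'   \code{distribution}, \code{eps}, \code{seed}.
#' @examples
#' ens <- sample_frequencies(5, noia_spec(c("x1", "x2")), "uniform", seed = 1)
#' dim(ens$sets)
#' @export
sample_frequencies <- function(n_sets, spec,
                               distribution = c("uniform", "u_shaped"),
                               eps = 0.01, seed = NULL) {
  distribution <- match.arg(distribution)
  if (is.numeric(spec) && length(spec) == 1L)
    spec <- noia_spec(paste0("L", seq_len(spec)))
  stopifnot(inherits(spec, "noia_spec"), n_sets >= 1L)
  L <- length(spec$loci)
  if (distribution == "u_shaped" && (eps <= 0 || eps >= 0.5))
    stop("'eps' must lie in (0, 0.5)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  u <- matrix(stats::runif(n_sets * L), n_sets, L)
  sets <- if (distribution == "uniform") u else u_shaped_quantile(u, eps)
  colnames(sets) <- spec$loci
  structure(list(sets = sets, distribution = distribution,
                 eps = if (distribution == "u_shaped") eps else NA_real_,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "frequency_ensemble")
}

# Inverse CDF of the truncated density f(p) proportional to 1/(p(1-p)) on
# [eps, 1-eps]: CDF is linear in logit(p), so invert through plogis.
u_shaped_quantile <- function(u, eps) {
  lo <- stats::qlogis(eps)
  hi <- stats::qlogis(1 - eps)
  stats::plogis(lo + u * (hi - lo))
}

# Analytic CDF of the truncated U-shaped density (used in tests).
u_shaped_cdf <- function(p, eps) {
  lo <- stats::qlogis(eps)
  hi <- stats::qlogis(1 - eps)
  pmin(1, pmax(0, (stats::qlogis(p) - lo) / (hi - lo)))
}

#' @export
print.frequency_ensemble <- function(x, ...) {
  cat("Allele-frequency ensemble: ", nrow(x$sets), " sets x ", ncol(x$sets),
      " loci, ", x$distribution, " distribution",
      if (!is.na(x$eps)) paste0(" (eps = ", x$eps, ")"),
      if (!is.na(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  invisible(x)
}

#' Serialize / load a frequency ensemble
#'
#' The ensemble is written as a CSV (header of locus ids, one row per set)
#' with a JSON sidecar recording the distribution, truncation and seed, so
#' a run can be reproduced or an externally supplied set file substituted.
#'
#' @param ensemble a \code{\link{sample_frequencies}} result.
#' @param file CSV path; the sidecar goes to \code{paste0(file, ".json")}.
#' @return \code{read_frequencies} returns a \code{frequency_ensemble};
#'   \code{write_frequencies} returns \code{file} invisibly.
#' @export
write_frequencies <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "frequency_ensemble"))
  utils::write.csv(as.data.frame(ensemble$sets), file, row.names = FALSE)
  meta <- list(distribution = ensemble$distribution,
               eps = ensemble$eps, seed = ensemble$seed,
               n_sets = nrow(ensemble$sets))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(file)
}

#' @rdname write_frequencies
#' @export
read_frequencies <- function(file) {
  sets <- as.matrix(utils::read.csv(file, check.names = FALSE))
  if (anyNA(sets) || any(sets < 0 | sets > 1))
    stop("frequency file contains values outside [0, 1]")
  meta <- list(distribution = "external", eps = NA_real_, seed = NA_integer_)
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar)) {
    m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta$distribution <- m$distribution %||% "external"
    meta$eps <- if (is.null(m$eps) || is.na(m$eps)) NA_real_ else as.numeric(m$eps)
    meta$seed <- if (is.null(m$seed) || is.na(m$seed)) NA_integer_ else as.integer(m$seed)
  }
  structure(list(sets = sets, distribution = meta$distribution,
                 eps = meta$eps, seed = meta$seed),
            class = "frequency_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
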