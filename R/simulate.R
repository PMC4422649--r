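#' Configure a phenotype simulation
#'
#' Describes a generative model for NIL/DNIL phenotype data: trait value =
#' genotypic value (from the true effects via the NOIA design) + a cohort
#' random intercept + a seed-family random intercept + residual, all
#' Gaussian. Two design modes are supported: \code{"balanced"} lays out
#' \code{n_per_cell} plants for each of the 9 two-locus genotype classes of
#' every modelled pair, replicated across \code{n_cohorts} cohorts with
#' \code{n_families} seed families per genotype-within-cohort cell;
#' \code{"mirror"} replicates the exact row structure (cohort, family,
#' genotype) of a template phenotype table, as a parametric bootstrap
#' requires.
#'
#' @param spec a \code{\link{noia_spec}}.
#' @param true_effects named vector of generating effects (labels as in
#'   \code{\link{noia_effects}}; any sampling covariance is ignored), or a
#'   \code{noia_effects} object.
#' @param var_cohort,var_family,var_residual variance components
#'   (trait units^2, each >= 0).
#' @param design \code{"balanced"} or \code{"mirror"}.
#' @param template phenotype table whose structure \code{"mirror"} copies.
#' @param n_per_cell,n_cohorts,n_families balanced-design dimensions.
#' @param trait name of the simulated trait column.
#' @param seed integer seed.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(spec, true_effects,
                              var_cohort = 0, var_family = 0, var_residual = 1,
                              design = c("balanced", "mirror"), template = NULL,
                              n_per_cell = 5L, n_cohorts = 2L, n_families = 2L,
                              trait = "trait", seed = NULL) {
  stopifnot(inherits(spec, "noia_spec"))
  design <- match.arg(design)
  if (inherits(true_effects, "noia_effects")) {
    eff <- true_effects
    eff$S[] <- 0
  } else {
    eff <- noia_effects(true_effects, S = NULL, spec = spec)
  }
  if (any(c(var_cohort, var_family, var_residual) < 0))
    stop("variance components must be nonnegative")
  if (design == "mirror" && is.null(template))
    stop("mirror design requires a 'template' phenotype table")
  structure(list(spec = spec, effects = eff, var_cohort = var_cohort,
                 var_family = var_family, var_residual = var_residual,
                 design = design, template = template,
                 n_per_cell = as.integer(n_per_cell),
                 n_cohorts = as.integer(n_cohorts),
                 n_families = as.integer(n_families),
                 trait = trait, seed = seed),
            class = "simulation_config")
}

# Genotype layout of a balanced DNIL design: the 9 two-locus classes per
# modelled pair (reference at all other loci); if the spec has no pairs,
# the 3 classes per locus.
balanced_layout <- function(spec) {
  L <- length(spec$loci)
  rows <- list()
  if (nrow(spec$pairs)) {
    for (r in seq_len(nrow(spec$pairs))) {
      g <- matrix(0L, 9L, L, dimnames = list(NULL, spec$loci))
      cls <- expand.grid(0:2, 0:2)
      g[, spec$pairs[r, 1L]] <- cls[, 1L]
      g[, spec$pairs[r, 2L]] <- cls[, 2L]
      rows[[r]] <- cbind(g, pair = r)
    }
  } else {
    for (l in seq_len(L)) {
      g <- matrix(0L, 3L, L, dimnames = list(NULL, spec$loci))
      g[, l] <- 0:2
      rows[[l]] <- cbind(g, pair = l)
    }
  }
  out <- do.call(rbind, rows)
  # distinct genotype rows may recur across pairs (e.g. the reference class);
  # keep them: each DNIL line set contributes its own plants
  out
}

#' Simulate a phenotype dataset
#'
#' Draws one dataset from a \code{\link{simulation_config}}: genotypic
#' values from the true effects, plus Gaussian cohort, family and residual
#' draws (cohort and family draws shared within their groups). Reproducible
#' given the config seed.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param seed overrides the config seed when given.
#' @return A phenotype table: data frame with \code{plant_id},
#'   \code{cohort}, \code{family}, one genotype column per locus
#'   (donor-allele counts), and the trait column.
#' @export
simulate_phenotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  sp <- cfg$spec
  if (cfg$design == "mirror") {
    tpl <- cfg$template
    G <- genotype_matrix(tpl[, sp$loci, drop = FALSE], sp)
    cohort <- as.character(tpl$cohort)
    family <- as.character(tpl$family)
  } else {
    lay <- balanced_layout(sp)
    Gcell <- lay[, sp$loci, drop = FALSE]
    pair <- lay[, "pair"]
    reps <- expand.grid(rep = seq_len(cfg$n_per_cell),
                        fam = seq_len(cfg$n_families),
                        cohort = seq_len(cfg$n_cohorts),
                        cell = seq_len(nrow(Gcell)))
    G <- Gcell[reps$cell, , drop = FALSE]
    cohort <- paste0("C", reps$cohort)
    family <- paste0("P", pair[reps$cell], ".G",
                     apply(G, 1L, paste, collapse = ""), ".C", reps$cohort,
                     ".F", reps$fam)
  }
  n <- nrow(G)
  z <- genotypic_value(cfg$effects, G)
  coh_lev <- unique(cohort)
  fam_lev <- unique(family)
  coh_eff <- stats::setNames(stats::rnorm(length(coh_lev), 0, sqrt(cfg$var_cohort)), coh_lev)
  fam_eff <- stats::setNames(stats::rnorm(length(fam_lev), 0, sqrt(cfg$var_family)), fam_lev)
  y <- z + coh_eff[cohort] + fam_eff[family] +
    stats::rnorm(n, 0, sqrt(cfg$var_residual))
  out <- data.frame(plant_id = sprintf("p%05d", seq_len(n)),
                    cohort = cohort, family = family,
                    as.data.frame(G), stringsAsFactors = FALSE)
  out[[cfg$trait]] <- unname(y)
  out
}

#' Simulate a study-like NIL/DNIL phenotype dataset
#'
#' Generates a fixture dataset with the dimensions of the floral-trait QTL
#' study: 7 biallelic QTL, 11 of the 21 possible QTL pairs observed as
#' DNILs with all 9 two-locus genotype classes each, 12 greenhouse cohorts
#' (each DNIL wholly inside a cohort, pairs spread over cohorts), seed
#' families of unbalanced (truncated-geometric) size nested within
#' genotype, and roughly 10,500 plant records. Generating effects are drawn
#' once from Gaussian priors at realistic millimetre-scale magnitudes;
#' cohort, family and residual variances default to 0.2, 0.1 and 1.0.
#'
#' @param seed integer seed controlling the random-effect and residual
#'   draws; different seeds give different phenotypes on an identical
#'   design skeleton.
#' @param design_seed integer seed for the fixture itself (generating
#'   effects, cohort assignment, family-size unbalance), fixed by default
#'   so the skeleton is one reproducible object.
#' @param n_target approximate total record count.
#' @param effect_sd,epi_sd prior standard deviations for single-locus and
#'   epistatic effects.
#' @param var_cohort,var_family,var_residual variance components.
#' @return List with \code{data} (phenotype table with trait column
#'   \code{"trait"}), \code{spec}, \code{effects} (the generating
#'   \code{\link{noia_effects}}, zero covariance) and the variance
#'   components.
#' @export
simulate_study_like <- function(seed = 1L, design_seed = 767L,
                                n_target = 10497L,
                                effect_sd = 0.5, epi_sd = 0.35,
                                var_cohort = 0.2, var_family = 0.1,
                                var_residual = 1.0) {
  loci <- paste0("x", 1:7)
  all_pairs <- utils::combn(loci, 2L)
  spec <- noia_spec(loci, pairs = all_pairs[, 1:11])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(design_seed))

  labs <- design_labels(spec)
  b <- stats::setNames(numeric(length(labs) + 1L), c("mu", labs))
  b["mu"] <- 10
  single <- grepl("^[ad]_", labs)
  b[labs[single]] <- stats::rnorm(sum(single), 0, effect_sd)
  b[labs[!single]] <- stats::rnorm(sum(!single), 0, epi_sd)
  eff <- noia_effects(b, spec = spec, trait = "trait")

  # Cohort layout: 12 cohorts; each DNIL appears complete in 2-3 cohorts,
  # redrawn until every cohort hosts at least one DNIL.
  n_cohorts <- 12L
  repeat {
    pair_cohorts <- lapply(seq_len(11L), function(r) {
      k <- sample(2:3, 1L)
      sample.int(n_cohorts, k)
    })
    if (length(unique(unlist(pair_cohorts))) == n_cohorts) break
  }
  cells_per_pair <- vapply(pair_cohorts, length, 1L) * 9L
  per_cell <- n_target / sum(cells_per_pair)

  rows <- list()
  cls <- as.matrix(expand.grid(0:2, 0:2))
  fam_counter <- 0L
  for (r in seq_len(11L)) {
    for (co in pair_cohorts[[r]]) {
      for (cl in seq_len(9L)) {
        g <- stats::setNames(integer(7L), loci)
        g[spec$pairs[r, ]] <- cls[cl, ]
        # unbalanced families: truncated-geometric sizes until the cell quota
        n_cell <- max(1L, stats::rpois(1L, per_cell))
        sizes <- integer(0)
        while (sum(sizes) < n_cell) {
          sizes <- c(sizes, min(1L + stats::rgeom(1L, 1 / 6), 25L))
        }
        excess <- sum(sizes) - n_cell
        sizes[length(sizes)] <- sizes[length(sizes)] - excess
        sizes <- sizes[sizes > 0L]
        for (s in sizes) {
          fam_counter <- fam_counter + 1L
          rows[[length(rows) + 1L]] <-
            data.frame(cohort = paste0("C", co),
                       family = paste0("F", fam_counter),
                       as.data.frame(matrix(rep(g, s), ncol = 7L, byrow = TRUE,
                                            dimnames = list(NULL, loci))),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  dat <- do.call(rbind, rows)
  dat <- data.frame(plant_id = sprintf("p%05d", seq_len(nrow(dat))), dat,
                    stringsAsFactors = FALSE)
  G <- as.matrix(dat[, loci])
  set.seed(as.integer(seed))  # noise only: skeleton is seed-invariant
  coh_lev <- unique(dat$cohort); fam_lev <- unique(dat$family)
  coh_eff <- stats::setNames(stats::rnorm(length(coh_lev), 0, sqrt(var_cohort)), coh_lev)
  fam_eff <- stats::setNames(stats::rnorm(length(fam_lev), 0, sqrt(var_family)), fam_lev)
  dat$trait <- genotypic_value(eff, G) + coh_eff[dat$cohort] +
    fam_eff[dat$family] + stats::rnorm(nrow(dat), 0, sqrt(var_residual))
  rownames(dat) <- NULL
  list(data = dat, spec = spec, effects = eff,
       varcomp = c(cohort = var_cohort, family = var_family,
                   residual = var_residual))
}

#' Parametric-bootstrap replicates from a fitted model
#'
#' \code{simulate} on a \code{\link{noia_fit}} draws replicate datasets
#' with the same size and grouping structure as the fitted data, using the
#' estimated fixed effects and variance components — the generator that the
#' parametric-bootstrap validation of the bias correction relies on.
#'
#' @param object a \code{\link{noia_fit}}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of \code{nsim} phenotype tables.
#' @export
simulate.noia_fit <- function(object, nsim = 1, seed = NULL, ...) {
  dat <- fit_template(object)
  cfg <- simulation_config(object$spec, object$effects,
                           var_cohort = object$varcomp["cohort"],
                           var_family = object$varcomp["family"],
                           var_residual = object$varcomp["residual"],
                           design = "mirror", template = dat,
                           trait = object$trait)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(nsim), function(i) simulate_phenotypes(cfg, seed = NULL))
}

# Reconstruct a (cohort, family, genotype) template from a fitted model's
# frame: additive columns a_<locus> carry the donor-allele counts.
fit_template <- function(fit) {
  fr <- if (isS4(fit$model)) fit$model@frame else fit$model$model
  L <- length(fit$spec$loci)
  G <- sapply(paste0("a_", fit$spec$loci), function(cn) fr[[cn]])
  colnames(G) <- fit$spec$loci
  data.frame(cohort = if (".cohort" %in% names(fr)) as.character(fr$.cohort) else "C1",
             family = if (".family" %in% names(fr)) as.character(fr$.family)
                      else paste0("F", apply(G, 1L, paste, collapse = "")),
             as.data.frame(G), stringsAsFactors = FALSE)
}
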