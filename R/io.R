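#' Read and write phenotype tables
#'
#' The canonical phenotype dialect is a CSV with one row per plant and
#' columns \code{plant_id} (optional), \code{cohort}, \code{family}, one
#' genotype column per locus (donor-allele counts 0/1/2, or ww/Ww/WW
#' strings), and one numeric column per trait (missing values allowed;
#' records are dropped per trait at fit time, not at read time).
#'
#' @param path CSV file path.
#' @param spec a \code{\link{noia_spec}} naming the expected locus columns.
#' @param traits character vector of trait column names to validate; by
#'   default every column that is not an id/grouping/locus column.
#' @return A validated data frame (phenotype table).
#' @export
read_phenotypes <- function(path, spec, traits = NULL) {
  stopifnot(inherits(spec, "noia_spec"))
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("cohort", "family")) {
    if (!col %in% names(dat))
      stop("phenotype file lacks required column '", col, "'")
  }
  missing <- setdiff(spec$loci, names(dat))
  if (length(missing))
    stop("phenotype file lacks genotype column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(traits)) {
    traits <- setdiff(names(dat), c("plant_id", "cohort", "family", spec$loci))
  } else {
    mt <- setdiff(traits, names(dat))
    if (length(mt)) stop("phenotype file lacks trait column(s): ",
                         paste(mt, collapse = ", "))
  }
  for (tr in traits) {
    v <- dat[[tr]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad))
        stop("non-numeric value for trait '", tr, "' at row ", bad[1L],
             ": '", v[bad[1L]], "'")
      dat[[tr]] <- vn
    }
  }
  # validate genotype codes (errors name the offending record)
  for (l in spec$loci) {
    codes <- genotype_codes(dat[[l]])
    dat[[l]] <- codes
  }
  if (!"plant_id" %in% names(dat))
    dat <- data.frame(plant_id = sprintf("p%05d", seq_len(nrow(dat))), dat,
                      stringsAsFactors = FALSE)
  dat
}

#' @rdname read_phenotypes
#' @param data a phenotype table to write.
#' @export
write_phenotypes <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, as JSON, the inputs, seed and settings that produced a set of
#' output files, so any result can be regenerated.
#'
#' @param path output JSON path.
#' @param ... named settings to record (seeds, input paths, flags).
#' @export
write_manifest <- function(path, ...) {
  entries <- list(...)
  entries$package <- "noiavar"
  entries$version <- as.character(utils::packageVersion("noiavar"))
  entries$r_version <- R.version.string
  entries$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
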