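## Facial recognition intensity (FRI).
##
## FRI = Nf x Pmax: the number of independent facial phenotypes of a disease
## times the maximum penetrance among its facial phenotypes. Correlated
## phenotypes (e.g. small jaw and crowded teeth) share a correlation-group
## id and are counted once; penetrance is a fraction in (0, 1], with 1
## assigned to phenotypes reported as present in essentially all patients.

#' Construct a phenotype profile
#'
#' @param disease disease name.
#' @param phenotypes data.frame (or list coercible to one) with columns
#'   `name`, `penetrance` (fraction in (0, 1]) and `group_id` (non-empty;
#'   phenotypes sharing a `group_id` are treated as correlated and counted
#'   once). If `group_id` is absent each phenotype forms its own group.
#' @return A list of class `phenotype_profile`.
#' @export
phenotype_profile <- function(disease, phenotypes) {
  phenotypes <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  if (nrow(phenotypes) == 0) {
    abort2(sprintf("disease '%s': phenotype list is empty", disease),
           "frimeta_error_validation")
  }
  if (!all(c("name", "penetrance") %in% names(phenotypes))) {
    abort2("phenotypes need columns 'name' and 'penetrance'",
           "frimeta_error_schema")
  }
  if (!"group_id" %in% names(phenotypes)) {
    phenotypes$group_id <- phenotypes$name
  }
  p <- phenotypes$penetrance
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort2(sprintf("disease '%s': penetrance must be a fraction in (0, 1]",
                   disease),
           "frimeta_error_validation")
  }
  if (any(is.na(phenotypes$group_id) | phenotypes$group_id == "")) {
    abort2(sprintf("disease '%s': group_id must be non-empty", disease),
           "frimeta_error_validation")
  }
  if (anyDuplicated(phenotypes$name)) {
    abort2(sprintf("disease '%s': duplicate phenotype name", disease),
           "frimeta_error_validation")
  }
  structure(list(disease = disease,
                 phenotypes = phenotypes[, c("name", "penetrance", "group_id")]),
            class = "phenotype_profile")
}

#' Compute the facial recognition intensity of a disease
#'
#' `FRI = Nf x Pmax`, where `Nf` is the number of independent phenotypes
#' (distinct correlation groups) and `Pmax` the maximum penetrance over all
#' listed phenotypes.
#'
#' @param profile a [phenotype_profile()].
#' @return A list of class `fri_result` with fields `disease`, `nf`, `pmax`,
#'   `fri`.
#' @export
compute_fri <- function(profile) {
  stopifnot(inherits(profile, "phenotype_profile"))
  ph <- profile$phenotypes
  nf <- length(unique(ph$group_id))
  pmax_ <- max(ph$penetrance)
  structure(list(disease = profile$disease, nf = nf, pmax = pmax_,
                 fri = nf * pmax_),
            class = "fri_result")
}

#' @export
print.fri_result <- function(x, ...) {
  cat(sprintf("FRI(%s) = %d x %.3f = %.4g\n", x$disease, x$nf, x$pmax, x$fri))
  invisible(x)
}

#' Load a phenotype/penetrance table
#'
#' Reads a CSV with columns `disease, phenotype, penetrance_pct, group_id`
#' (penetrance in percent, converted to a fraction internally) and groups
#' rows into one [phenotype_profile()] per disease.
#'
#' @param path CSV path.
#' @return A named list of `phenotype_profile` objects, one per disease.
#' @export
load_phenotype_table <- function(path) {
  if (!file.exists(path)) {
    abort2(sprintf("phenotype file not found: %s", path), "frimeta_error_io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("disease", "phenotype", "penetrance_pct", "group_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort2(sprintf("phenotype table is missing column(s): %s",
                   paste(missing, collapse = ", ")),
           "frimeta_error_schema")
  }
  if (any(!is.finite(df$penetrance_pct) | df$penetrance_pct <= 0 |
            df$penetrance_pct > 100)) {
    abort2("penetrance_pct must lie in (0, 100]", "frimeta_error_validation")
  }
  if (anyDuplicated(df[, c("disease", "phenotype")])) {
    abort2("duplicate (disease, phenotype) row in phenotype table",
           "frimeta_error_validation")
  }
  profiles <- lapply(split(df, df$disease), function(d) {
    phenotype_profile(d$disease[1],
                      data.frame(name = d$phenotype,
                                 penetrance = d$penetrance_pct / 100,
                                 group_id = d$group_id,
                                 stringsAsFactors = FALSE))
  })
  profiles[unique(df$disease)]
}

#' Reference phenotype profiles for the seven benchmark diseases
#'
#' Loads the packaged phenotype/penetrance fixture covering the seven
#' diseases used to calibrate the FRI scale (Down syndrome, acromegaly,
#' Cornelia de Lange syndrome, Angelman syndrome, Cushing's syndrome, fetal
#' alcohol spectrum disorders, Turner syndrome). Only the per-disease
#' maximum penetrance is published for these diseases, so the fixture fills
#' every phenotype of a disease with that maximum; `nf` and `pmax` (hence
#' FRI) are unaffected by the fill.
#'
#' For Angelman syndrome the published sources disagree: the tabulated index
#' (6 phenotypes, maximum penetrance 100%, FRI = 6) conflicts with the
#' accompanying narrative value of 8. The fixture follows the tabulated
#' value and a warning surfaces the discrepancy.
#'
#' @return A named list of `phenotype_profile` objects.
#' @export
fri_reference_profiles <- function() {
  path <- system.file("extdata", "phenotypes_table1.csv", package = "frimeta",
                      mustWork = TRUE)
  profiles <- load_phenotype_table(path)
  if ("Angelman syndrome" %in% names(profiles)) {
    warning(paste("Angelman syndrome: published FRI values conflict",
                  "(tabulated 6 x 100% = 6 vs narrative 8);",
                  "the fixture follows the tabulated value, FRI = 6"),
            call. = FALSE)
  }
  profiles
}

#' FRI table for a set of profiles
#'
#' @param profiles a list of `phenotype_profile` objects.
#' @return A data.frame with columns `disease, nf, pmax, fri`.
#' @export
fri_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    r <- compute_fri(p)
    data.frame(disease = r$disease, nf = r$nf, pmax = r$pmax, fri = r$fri,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
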