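## Study-level input/output and per-study accuracy summaries.
##
## A "study set" is a data.frame with one row per diagnostic-accuracy study:
## the four cells of its 2x2 table (tp, fp, fn, tn) plus covariates used by
## pooling, meta-regression, subgroup and sensitivity analyses.

# Columns every studies file must carry, in the documented schema.
.mandatory_cols <- c("study_id", "disease", "tp", "fp", "fn", "tn")

# Optional covariate columns recognised by downstream stages.
.covariate_cols <- c("fri", "training_n", "resolution_px", "model_class",
                     "control_type", "n_diseases", "validation", "excl_flags")

.model_class_levels <- c("deep_learning", "non_deep_learning", "unreported")
.control_type_levels <- c("healthy", "other_diseases", "mixed")
.validation_levels <- c("internal", "external")
.excl_flag_levels <- c("unclear_model", "unclear_reference",
                       "external_validation", "unclear_sampling")

#' Read a study-level 2x2 CSV
#'
#' Reads and validates a CSV of study-level diagnostic 2x2 tables. The file
#' must carry columns `study_id, disease, tp, fp, fn, tn`; the covariate
#' columns `fri, training_n, resolution_px, model_class, control_type,
#' n_diseases, validation, excl_flags` are optional and any further columns
#' are preserved untouched. `excl_flags` holds semicolon-separated tokens
#' from `unclear_model`, `unclear_reference`, `external_validation`,
#' `unclear_sampling`. Counts must be non-negative integers and every study
#' must have both a diseased arm (`tp + fn >= 1`) and a control arm
#' (`fp + tn >= 1`).
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param schema_version schema identifier; currently only `"1"` exists.
#' @return A `data.frame` of class `study_set`, one row per study, row order
#'   preserved.
#' @export
read_studies <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    abort2(sprintf("unknown studies schema version '%s'", schema_version),
           "frimeta_error_schema")
  }
  if (!file.exists(path)) {
    abort2(sprintf("studies file not found: %s", path), "frimeta_error_io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0) {
    abort2("studies file contains a header but no rows", "frimeta_error_empty")
  }
  missing <- setdiff(.mandatory_cols, names(df))
  if (length(missing)) {
    abort2(sprintf("missing mandatory column(s): %s",
                   paste(missing, collapse = ", ")),
           "frimeta_error_schema")
  }
  as_study_set(df)
}

#' Validate a data.frame of studies
#'
#' Applies the `study_set` invariants (integer non-negative counts, both
#' arms non-empty, known enum levels) and returns the validated object.
#'
#' @param df data.frame with at least `study_id, disease, tp, fp, fn, tn`.
#' @return `df` with class `study_set` prepended.
#' @export
as_study_set <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.mandatory_cols, names(df))
  if (length(missing)) {
    abort2(sprintf("missing mandatory column(s): %s",
                   paste(missing, collapse = ", ")),
           "frimeta_error_schema")
  }
  for (cc in c("tp", "fp", "fn", "tn")) {
    v <- df[[cc]]
    if (!is.numeric(v) || anyNA(v)) {
      abort2(sprintf("column '%s' must be numeric and complete", cc),
             "frimeta_error_validation")
    }
    bad <- which(v < 0 | v != floor(v))
    if (length(bad)) {
      abort2(sprintf("row %s (study_id '%s'): column '%s' must be a non-negative integer, got %s",
                     bad[1], df$study_id[bad[1]], cc, v[bad[1]]),
             "frimeta_error_validation")
    }
  }
  bad_dis <- which(df$tp + df$fn < 1)
  if (length(bad_dis)) {
    abort2(sprintf("row %s (study_id '%s'): diseased arm is empty (tp + fn = 0)",
                   bad_dis[1], df$study_id[bad_dis[1]]),
           "frimeta_error_validation")
  }
  bad_con <- which(df$fp + df$tn < 1)
  if (length(bad_con)) {
    abort2(sprintf("row %s (study_id '%s'): control arm is empty (fp + tn = 0)",
                   bad_con[1], df$study_id[bad_con[1]]),
           "frimeta_error_validation")
  }
  check_enum <- function(col, levels) {
    if (!col %in% names(df)) return()
    v <- df[[col]]
    bad <- which(!is.na(v) & v != "" & !(v %in% levels))
    if (length(bad)) {
      abort2(sprintf("row %s: '%s' value '%s' not one of {%s}",
                     bad[1], col, v[bad[1]], paste(levels, collapse = ", ")),
             "frimeta_error_validation")
    }
  }
  check_enum("model_class", .model_class_levels)
  check_enum("control_type", .control_type_levels)
  check_enum("validation", .validation_levels)
  if ("excl_flags" %in% names(df)) {
    toks <- unlist(strsplit(df$excl_flags[!is.na(df$excl_flags)], ";",
                            fixed = TRUE))
    toks <- trimws(toks[toks != ""])
    bad <- setdiff(toks, .excl_flag_levels)
    if (length(bad)) {
      abort2(sprintf("unknown excl_flags token(s): %s",
                     paste(unique(bad), collapse = ", ")),
             "frimeta_error_validation")
    }
  }
  class(df) <- unique(c("study_set", class(df)))
  df
}

## split an excl_flags string into a character vector of tokens
parse_flags <- function(x) {
  if (is.na(x) || x == "") return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Per-study accuracy summary
#'
#' Computes sensitivity, specificity, exact (Clopper-Pearson) confidence
#' intervals, the log diagnostic odds ratio and its Woolf variance for a
#' single study's 2x2 table. When any cell of the table is zero the
#' continuity correction `cc` is added to all four cells for the log-OR and
#' its variance only; the observed proportions are never corrected.
#'
#' @param s one study: a one-row `study_set`, or any list/row with fields
#'   `tp, fp, fn, tn`.
#' @param cc continuity correction added to every cell when any cell is zero
#'   (default 0.5).
#' @param ci_level confidence level for the per-study intervals.
#' @return A list of class `study_accuracy` with fields `se_hat`, `sp_hat`,
#'   `se_ci`, `sp_ci`, `ln_or`, `var_ln_or`, `corrected`.
#' @export
summarize_study <- function(s, cc = 0.5, ci_level = 0.95) {
  stopifnot(cc >= 0, ci_level > 0, ci_level < 1)
  if (is.data.frame(s)) {
    stopifnot(nrow(s) == 1)
    s <- as.list(s)
  }
  tp <- s$tp; fp <- s$fp; fn <- s$fn; tn <- s$tn
  n_dis <- tp + fn
  n_con <- fp + tn
  if (n_dis == 0 || n_con == 0) {
    abort2("degenerate study: an arm of the 2x2 table is empty",
           "frimeta_error_degenerate_arm")
  }
  se_hat <- tp / n_dis
  sp_hat <- tn / n_con
  corrected <- any(c(tp, fp, fn, tn) == 0) && cc > 0
  cells <- c(tp, fp, fn, tn) + if (corrected) cc else 0
  ln_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  var_ln_or <- sum(1 / cells)
  structure(
    list(se_hat = se_hat, sp_hat = sp_hat,
         se_ci = clopper_pearson(tp, n_dis, ci_level),
         sp_ci = clopper_pearson(tn, n_con, ci_level),
         ln_or = ln_or, var_ln_or = var_ln_or, corrected = corrected),
    class = "study_accuracy")
}

#' Forest table of per-study accuracy
#'
#' Applies [summarize_study()] to every row of a study set, producing the
#' table behind a paired sensitivity/specificity forest plot.
#'
#' @inheritParams summarize_study
#' @param studies a `study_set`.
#' @return A data.frame with one row per study: `study_id, disease, se, se_lo,
#'   se_hi, sp, sp_lo, sp_hi, ln_or, var_ln_or, corrected`.
#' @export
forest_table <- function(studies, cc = 0.5, ci_level = 0.95) {
  studies <- as_study_set(as.data.frame(studies))
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    a <- summarize_study(studies[i, , drop = FALSE], cc = cc,
                         ci_level = ci_level)
    data.frame(study_id = studies$study_id[i], disease = studies$disease[i],
               se = a$se_hat, se_lo = a$se_ci[1], se_hi = a$se_ci[2],
               sp = a$sp_hat, sp_lo = a$sp_ci[1], sp_hi = a$sp_ci[2],
               ln_or = a$ln_or, var_ln_or = a$var_ln_or,
               corrected = a$corrected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write and read result tables
#'
#' Persists a result table (or any list structure, for JSON) so that a
#' read-back reproduces every numeric field at full double precision.
#'
#' @param results a data.frame (csv or json) or list (json only).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   the parsed object.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  ok <- tryCatch(suppressWarnings({
    if (format == "json") {
      # 17 significant digits: doubles survive the round trip bit-exactly
      jsonlite::write_json(results, path, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null")
    } else {
      stopifnot(is.data.frame(results))
      out <- results
      for (j in seq_along(out)) {
        if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
      }
      utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
    }
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) {
    abort2(sprintf("cannot write report to '%s': %s", path,
                   conditionMessage(ok)),
           "frimeta_error_io")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort2(sprintf("report file not found: %s", path), "frimeta_error_io")
  }
  if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
}
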