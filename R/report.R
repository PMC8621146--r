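## Full-analysis orchestration: pooling -> SROC -> meta-regression ->
## required-FRI thresholds -> subgroups -> stratified summaries ->
## sensitivity refits, with provenance and structured logging.

default_config <- function() {
  list(
    level = 0.95,
    quad_points = 15,
    restarts = 5,
    seed = 1L,
    cc = 0.5,
    metareg_method = "reml",
    ## target operating points for the required-FRI table
    thresholds = list(c(0.85, 0.85), c(0.90, 0.85), c(0.90, 0.90),
                      c(0.95, 0.90), c(0.95, 0.95)),
    ## "reference" uses the published link coefficients; "fitted" the
    ## meta-regression estimated on the supplied studies
    threshold_link = "reference",
    fri_bands = c(6, 8),
    size_bands = c(100, 1000),
    ## exclusion-flag sets for the sensitivity refits
    sensitivity_flags = list("external_validation", "unclear_model",
                             "unclear_reference")
  )
}

#' Read an analysis configuration file
#'
#' YAML mirror of the `config` argument of [run_full_analysis()]; keys in
#' the file override the defaults and keys passed programmatically override
#' the file.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort2(sprintf("config file not found: %s", path), "frimeta_error_io")
  }
  yaml::read_yaml(path)
}

merge_config <- function(base, override) {
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

## interval labels: "<c1", "c1~c2" (right-open; last middle band closed), ">cn"
band_labels <- function(cuts) {
  c(sprintf("<%g", cuts[1]),
    if (length(cuts) > 1) sprintf("%g~%g", cuts[-length(cuts)], cuts[-1]),
    sprintf(">%g", cuts[length(cuts)]))
}

band_assign <- function(x, cuts) {
  labs <- band_labels(cuts)
  idx <- findInterval(x, cuts, left.open = FALSE) + 1L
  ## the upper cutpoint belongs to the last middle band, not the ">" band
  idx[!is.na(x) & x == cuts[length(cuts)]] <- length(labs) - 1L
  factor(labs[idx], levels = labs)
}

#' Stratified per-study accuracy summaries
#'
#' Tabulates the median and (minimum, maximum) of the observed per-study
#' sensitivity and specificity across strata of FRI and training-set size
#' (and optionally AI model class). Bands are right-open except the last:
#' cutpoints `c(100, 1000)` give strata `<100`, `100~1000` (closed at both
#' ends) and `>1000`. Empty strata are reported with zero studies, not
#' dropped.
#'
#' @param studies a `study_set` with `fri` and `training_n` columns.
#' @param fri_bands,size_bands strictly increasing cutpoints.
#' @param by_model also stratify FRI bands by `model_class` (additional rows
#'   with `size_band = "(all)"`).
#' @return A data.frame: `fri_band, size_band, model_class, n_studies,
#'   se_median, se_min, se_max, sp_median, sp_min, sp_max`.
#' @export
stratified_accuracy <- function(studies, fri_bands = c(6, 8),
                                size_bands = c(100, 1000), by_model = FALSE) {
  for (cuts in list(fri_bands, size_bands)) {
    if (length(cuts) < 1 || is.unsorted(cuts, strictly = TRUE)) {
      abort2("band cutpoints must be strictly increasing",
             "frimeta_error_validation")
    }
  }
  studies <- as_study_set(as.data.frame(studies))
  ft <- forest_table(studies)
  fri_band <- band_assign(studies$fri %||% rep(NA_real_, nrow(studies)),
                          fri_bands)
  size_band <- band_assign(studies$training_n %||% rep(NA_real_, nrow(studies)),
                           size_bands)

  stat_row <- function(idx) {
    if (!any(idx)) {
      return(data.frame(n_studies = 0L, se_median = NA_real_,
                        se_min = NA_real_, se_max = NA_real_,
                        sp_median = NA_real_, sp_min = NA_real_,
                        sp_max = NA_real_))
    }
    data.frame(n_studies = sum(idx),
               se_median = stats::median(ft$se[idx]),
               se_min = min(ft$se[idx]), se_max = max(ft$se[idx]),
               sp_median = stats::median(ft$sp[idx]),
               sp_min = min(ft$sp[idx]), sp_max = max(ft$sp[idx]))
  }

  rows <- list()
  for (fb in levels(fri_band)) {
    for (sb in levels(size_band)) {
      idx <- !is.na(fri_band) & !is.na(size_band) &
        fri_band == fb & size_band == sb
      rows[[length(rows) + 1]] <-
        cbind(data.frame(fri_band = fb, size_band = sb,
                         model_class = "(all)"), stat_row(idx))
    }
  }
  if (by_model && "model_class" %in% names(studies)) {
    mc <- studies$model_class
    for (fb in levels(fri_band)) {
      for (m in c("deep_learning", "non_deep_learning")) {
        idx <- !is.na(fri_band) & fri_band == fb & !is.na(mc) & mc == m
        rows[[length(rows) + 1]] <-
          cbind(data.frame(fri_band = fb, size_band = "(all)",
                           model_class = m), stat_row(idx))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach FRI values to studies by disease lookup
#'
#' Joins the FRI of each study's disease from a set of phenotype profiles.
#' Studies targeting more than one disease (`n_diseases > 1`) are left
#' unmapped unless they already carry an `fri` value, since a multi-disease
#' study has no single phenotype profile.
#'
#' @param studies a `study_set`.
#' @param profiles named list of `phenotype_profile` objects (e.g. from
#'   [fri_reference_profiles()]).
#' @return The studies with an `fri` column filled where a lookup applied.
#' @export
attach_fri <- function(studies, profiles) {
  studies <- as_study_set(as.data.frame(studies))
  tab <- fri_table(profiles)
  if (!"fri" %in% names(studies)) studies$fri <- NA_real_
  single <- if ("n_diseases" %in% names(studies)) {
    is.na(studies$n_diseases) | studies$n_diseases == 1
  } else {
    rep(TRUE, nrow(studies))
  }
  hit <- match(studies$disease, tab$disease)
  fill <- single & is.na(studies$fri) & !is.na(hit)
  studies$fri[fill] <- tab$fri[hit[fill]]
  studies
}

with_stage <- function(stage, log, expr) {
  log(stage, "start")
  r <- tryCatch(expr, error = function(e) e)
  if (inherits(r, "error")) {
    log(stage, "error", message = conditionMessage(r))
    abort2(sprintf("analysis aborted at stage '%s': %s", stage,
                   conditionMessage(r)),
           "frimeta_error_stage")
  }
  log(stage, "done")
  r
}

#' Run the full meta-analytic pipeline
#'
#' Executes every stage of the analysis in order: per-study summaries,
#' bivariate pooling, SROC, FRI meta-regression, required-FRI thresholds,
#' subgroup analyses, stratified accuracy, and sensitivity refits. FRI is
#' attached to single-disease studies from the phenotype table (default:
#' the packaged reference profiles). Deterministic given identical inputs,
#' config and seed.
#'
#' @param studies_path path to the studies CSV (see [read_studies()]).
#' @param phenotypes_path optional phenotype CSV; `NULL` uses the packaged
#'   reference table.
#' @param config named list overriding the defaults (level, quad_points,
#'   restarts, seed, cc, metareg_method, thresholds, threshold_link,
#'   fri_bands, size_bands, sensitivity_flags), or a path readable by
#'   [read_config()] passed as a list via `config = read_config(path)`.
#' @param out_dir optional directory: writes `report.json`, `forest.csv`,
#'   `sroc.csv`, `thresholds.csv`, `subgroups.csv`, `strata.csv` and
#'   `log.jsonl`. Partial artifacts are preserved when a stage fails.
#' @return A list of class `analysis_report` with sections `pooled`, `sroc`,
#'   `metareg`, `thresholds`, `subgroups`, `strata`, `sensitivity` and
#'   `provenance`.
#' @export
run_full_analysis <- function(studies_path, phenotypes_path = NULL,
                              config = list(), out_dir = NULL) {
  cfg <- merge_config(default_config(), config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_path <- if (!is.null(out_dir)) file.path(out_dir, "log.jsonl") else NULL
  cfg_hash <- rlang::hash(cfg)
  log <- function(stage, status, ...) {
    rec <- c(list(stage = stage, status = status, seed = cfg$seed,
                  config_hash = cfg_hash,
                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             list(...))
    if (!is.null(log_path)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
          file = log_path, append = TRUE)
    }
    invisible(rec)
  }

  studies <- with_stage("read_studies", log, read_studies(studies_path))
  profiles <- with_stage("phenotypes", log, {
    if (is.null(phenotypes_path)) {
      suppressWarnings(fri_reference_profiles())
    } else {
      load_phenotype_table(phenotypes_path)
    }
  })
  studies <- with_stage("attach_fri", log, attach_fri(studies, profiles))

  forest <- with_stage("forest", log,
                       forest_table(studies, cc = cfg$cc,
                                    ci_level = cfg$level))
  emit <- function(name, df) {
    if (!is.null(out_dir)) {
      write_report(df, file.path(out_dir, paste0(name, ".csv")), "csv")
    }
  }
  emit("forest", forest)

  fit <- with_stage("pool", log,
                    fit_bivariate(studies, quad_points = cfg$quad_points,
                                  restarts = cfg$restarts, seed = cfg$seed))
  pooled <- with_stage("pooled_summary", log,
                       pooled_summary(fit, level = cfg$level))

  sroc_res <- with_stage("sroc", log, sroc(fit, level = cfg$level))
  if (!is.null(out_dir)) {
    sc <- rbind(
      data.frame(component = "curve", sroc_res$curve),
      data.frame(component = "conf", sroc_res$conf_region$polygon),
      data.frame(component = "pred", sroc_res$pred_region$polygon))
    write_report(sc, file.path(out_dir, "sroc.csv"), "csv")
  }

  mr_studies <- studies[!is.na(studies$fri), , drop = FALSE]
  metareg <- with_stage("metareg", log, {
    if (nrow(mr_studies) >= 3) {
      fit_metareg(mr_studies, covariates = "fri",
                  method = cfg$metareg_method, cc = cfg$cc,
                  level = cfg$level)
    } else {
      NULL
    }
  })

  thresholds <- with_stage("thresholds", log, {
    if (identical(cfg$threshold_link, "fitted") && !is.null(metareg)) {
      required_fri_table(cfg$thresholds, fit = metareg)
    } else {
      required_fri_table(cfg$thresholds)
    }
  })
  emit("thresholds", thresholds)

  subgroups <- with_stage("subgroups", log, {
    specs <- list(
      list(variable = "fri",
           splitter = function(d) ifelse(d$fri <= 6, "<=6", ">6")),
      list(variable = "training_n", splitter = 1000),
      list(variable = "resolution_px", splitter = 30000),
      list(variable = "model_class",
           splitter = function(d) ifelse(d$model_class == "unreported",
                                         NA, d$model_class)),
      list(variable = "n_diseases",
           splitter = function(d) ifelse(d$n_diseases > 1, ">1", "1")),
      list(variable = "control_type",
           splitter = function(d) ifelse(d$control_type == "mixed",
                                         NA, d$control_type)))
    out <- list()
    for (sp in specs) {
      if (!sp$variable %in% names(studies)) next
      r <- tryCatch(
        subgroup_analysis(studies, sp$variable, sp$splitter,
                          level = cfg$level, method = cfg$metareg_method,
                          quad_points = cfg$quad_points,
                          restarts = cfg$restarts, seed = cfg$seed),
        error = function(e) NULL)
      if (!is.null(r)) out[[sp$variable]] <- r
    }
    out
  })
  if (!is.null(out_dir) && length(subgroups)) {
    sg <- do.call(rbind, lapply(subgroups, function(s) {
      do.call(rbind, lapply(s$groups, function(g) {
        data.frame(variable = s$variable, group = g$label,
                   n_studies = g$n_studies, se = g$se$est,
                   se_lo = g$se$ci[1], se_hi = g$se$ci[2], sp = g$sp$est,
                   sp_lo = g$sp$ci[1], sp_hi = g$sp$ci[2],
                   degenerate = g$degenerate,
                   p_interaction = s$p_interaction)
      }))
    }))
    write_report(sg, file.path(out_dir, "subgroups.csv"), "csv")
  }

  strata <- with_stage("strata", log,
                       stratified_accuracy(studies, fri_bands = cfg$fri_bands,
                                           size_bands = cfg$size_bands,
                                           by_model = TRUE))
  emit("strata", strata)

  sensitivity <- with_stage("sensitivity", log, {
    lapply(cfg$sensitivity_flags, function(fl) {
      fl <- as.character(fl)
      r <- tryCatch(
        refit_excluding(studies, flags = fl, level = cfg$level,
                        quad_points = cfg$quad_points,
                        restarts = cfg$restarts, seed = cfg$seed),
        error = function(e) NULL)
      if (is.null(r)) {
        list(flags = fl, feasible = FALSE)
      } else {
        list(flags = fl, feasible = TRUE, dropped = r$dropped,
             summary = r$summary)
      }
    })
  })

  report <- structure(
    list(pooled = pooled, sroc = sroc_res, metareg = metareg,
         thresholds = thresholds, subgroups = subgroups, strata = strata,
         sensitivity = sensitivity,
         study_ids = list(
           pooled = fit$study_id,
           metareg = if (!is.null(metareg)) metareg$study_id else character()),
         provenance = list(seed = cfg$seed,
                           version = as.character(utils::packageVersion("frimeta")),
                           config_hash = cfg_hash,
                           timestamp = format(Sys.time(),
                                              "%Y-%m-%dT%H:%M:%S%z"))),
    class = "analysis_report")

  if (!is.null(out_dir)) {
    write_report(report_to_list(report),
                 file.path(out_dir, "report.json"), "json")
  }
  report
}

#' Serialisable form of an analysis report
#'
#' Strips non-serialisable components (model objects, ellipse matrices) so
#' that the report round-trips through JSON. The numeric content is
#' identical between repeated runs with the same inputs, config and seed;
#' only the provenance timestamp differs.
#'
#' @param report an `analysis_report`.
#' @return A plain nested list.
#' @export
report_to_list <- function(report) {
  ps_list <- function(ps) {
    if (is.null(ps)) return(NULL)
    lapply(ps[c("se", "sp", "plr", "nlr", "dor")],
           function(s) list(est = s$est, ci = s$ci))
  }
  mr <- report$metareg
  list(
    pooled = c(ps_list(report$pooled), list(level = report$pooled$level)),
    sroc = list(summary_point = as.list(report$sroc$summary_point),
                curve = report$sroc$curve,
                conf_polygon = report$sroc$conf_region$polygon,
                pred_polygon = report$sroc$pred_region$polygon,
                level = report$sroc$level),
    metareg = if (!is.null(mr)) {
      list(intercept = mr$intercept, coef = mr$coef, tau2 = mr$tau2,
           n_studies = mr$n_studies, method = mr$method)
    },
    thresholds = report$thresholds,
    subgroups = lapply(report$subgroups, function(s) {
      list(variable = s$variable, p_interaction = s$p_interaction,
           groups = lapply(s$groups, function(g) {
             list(label = g$label, n_studies = g$n_studies,
                  se = g$se, sp = g$sp, degenerate = g$degenerate)
           }))
    }),
    strata = report$strata,
    sensitivity = lapply(report$sensitivity, function(s) {
      out <- list(flags = s$flags, feasible = s$feasible)
      if (isTRUE(s$feasible)) {
        out$dropped <- s$dropped
        out$summary <- ps_list(s$summary)
      }
      out
    }),
    study_ids = report$study_ids,
    provenance = report$provenance)
}
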