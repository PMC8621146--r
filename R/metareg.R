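## Random-effects meta-regression of study ln(OR) on FRI (and other
## covariates), and inversion of the fitted linear link into required-FRI
## thresholds for target sensitivity and specificity.
##
## Model: y_k = x_k' beta + u_k + e_k with e_k ~ N(0, v_k) (v_k the known
## Woolf variance of the study log diagnostic odds ratio) and
## u_k ~ N(0, tau2). tau2 is estimated by REML (default) or
## DerSimonian-Laird; inference on beta is Wald z. The fitting engine is
## metafor::rma.uni.

#' Published coefficient sets of the FRI / ln(OR) link
#'
#' Two variants of the fitted linear relation between facial recognition
#' intensity and the log diagnostic odds ratio,
#' `ln(OR) = slope * FRI + intercept`, circulate in the source analysis:
#' the primary single-covariate fit (slope 0.4960, intercept 1.459) and a
#' table-caption variant (slope 0.4951, intercept 1.46). The primary set is
#' the package default wherever a link is needed.
#'
#' @format A list with elements `primary` and `table`, each a named numeric
#'   vector `c(slope, intercept)`.
#' @export
fri_link_coefs <- list(
  primary = c(slope = 0.4960, intercept = 1.459),
  table = c(slope = 0.4951, intercept = 1.46)
)

## assemble y, v and the design matrix for the requested covariates
metareg_data <- function(studies, covariates, cc = 0.5) {
  studies <- as_study_set(as.data.frame(studies))
  ft <- forest_table(studies, cc = cc)
  if (length(covariates)) {
    missing_cols <- setdiff(covariates, names(studies))
    if (length(missing_cols)) {
      abort2(sprintf("covariate column(s) not present: %s",
                     paste(missing_cols, collapse = ", ")),
             "frimeta_error_schema")
    }
    X <- studies[, covariates, drop = FALSE]
    bad <- !stats::complete.cases(X)
    if (any(bad)) {
      abort2(sprintf("missing covariate values for study_id(s): %s",
                     paste(studies$study_id[bad], collapse = ", ")),
             "frimeta_error_validation")
    }
  } else {
    X <- NULL
  }
  list(y = ft$ln_or, v = ft$var_ln_or, X = X, study_id = studies$study_id)
}

#' Random-effects meta-regression of ln(OR)
#'
#' Regresses each study's log diagnostic odds ratio (computed by
#' [summarize_study()], with its Woolf sampling variance treated as known)
#' on the requested covariates, with an additive between-study variance
#' `tau2` estimated by REML or DerSimonian-Laird. An empty covariate list
#' gives the intercept-only random-effects pooling of ln(OR).
#'
#' @param studies a `study_set`; covariates are taken from its columns.
#' @param covariates character vector of covariate column names (e.g.
#'   `"fri"`, `"training_n"`); may be empty.
#' @param method `"reml"` (default), `"dl"` (DerSimonian-Laird), or `"fe"`
#'   (common-effect: `tau2` fixed at zero).
#' @param cc continuity correction passed to [summarize_study()].
#' @param level confidence level of the coefficient intervals.
#' @return An object of class `metareg_fit`: `coef` (named list per
#'   covariate with `beta`, `se`, `ci`, `p`), `intercept` (same structure),
#'   `tau2`, `n_studies`, `method`, `level`, and the underlying
#'   `metafor::rma` object as `$rma`.
#' @export
fit_metareg <- function(studies, covariates = "fri",
                        method = c("reml", "dl", "fe"), cc = 0.5,
                        level = 0.95) {
  method <- match.arg(method)
  md <- metareg_data(studies, covariates, cc = cc)
  p <- length(covariates) + 1
  if (length(md$y) < p) {
    abort2(sprintf("%d studies cannot support %d coefficients", length(md$y), p),
           "frimeta_error_insufficient_data")
  }
  if (!is.null(md$X)) {
    Xm <- cbind(1, as.matrix(data.frame(lapply(md$X, as.numeric))))
    if (qr(Xm)$rank < ncol(Xm)) {
      abort2(sprintf("collinear design: covariates {%s} with the intercept are rank-deficient",
                     paste(covariates, collapse = ", ")),
             "frimeta_error_rank_deficient")
    }
    mods <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
    dat <- cbind(data.frame(yi = md$y, vi = md$v), md$X)
  } else {
    mods <- NULL
    dat <- data.frame(yi = md$y, vi = md$v)
  }
  ## saturated designs leave no residual degrees of freedom for tau2,
  ## which is then identically zero
  meth <- if (method == "fe" || length(md$y) == p) "FE" else toupper(method)
  args <- list(yi = md$y, vi = md$v, data = dat, method = meth, test = "z",
               level = 100 * level,
               control = list(threshold = 1e-10, maxiter = 1000))
  if (!is.null(mods)) args$mods <- mods
  fit <- do.call(metafor::rma.uni, args)
  b <- as.numeric(fit$beta)
  term <- function(i) list(beta = b[i], se = unname(fit$se[i]),
                           ci = unname(c(fit$ci.lb[i], fit$ci.ub[i])),
                           p = unname(fit$pval[i]))
  coefs <- lapply(seq_along(covariates) + 1, term)
  names(coefs) <- covariates
  structure(
    list(coef = coefs, intercept = term(1), tau2 = fit$tau2,
         n_studies = fit$k, method = method, level = level,
         study_id = md$study_id, rma = fit),
    class = "metareg_fit")
}

#' @export
print.metareg_fit <- function(x, ...) {
  cat(sprintf("Random-effects meta-regression of ln(OR) (%s), %d studies, tau2 = %.4f\n",
              toupper(x$method), x$n_studies, x$tau2))
  lv <- round(100 * x$level)
  row <- function(nm, tm) {
    cat(sprintf("  %-12s %8.4f  [%d%% CI %.4f, %.4f]  p = %.4g\n",
                nm, tm$beta, lv, tm$ci[1], tm$ci[2], tm$p))
  }
  row("(intercept)", x$intercept)
  for (nm in names(x$coef)) row(nm, x$coef[[nm]])
  invisible(x)
}

#' Predicted ln(OR) at a given FRI
#'
#' @param fit a `metareg_fit` containing an `fri` coefficient.
#' @param fri FRI value(s).
#' @return `intercept + slope * fri`.
#' @export
predict_lnor <- function(fit, fri) {
  stopifnot(inherits(fit, "metareg_fit"))
  if (!"fri" %in% names(fit$coef)) {
    abort2("fit has no 'fri' coefficient", "frimeta_error_validation")
  }
  fit$intercept$beta + fit$coef$fri$beta * fri
}

#' Required FRI for a target operating point
#'
#' Inverts the linear FRI / ln(OR) link: for target sensitivity and
#' specificity, the implied diagnostic odds ratio is
#' `OR = se * sp / ((1 - se) (1 - sp))` and the FRI a disease must reach is
#' `(ln(OR) - intercept) / slope`. All values are returned at full
#' precision; see [format_fri_thresholds()] for the conventional 2-decimal
#' presentation.
#'
#' @param se,sp target sensitivity and specificity, strictly inside (0, 1).
#' @param slope,intercept link coefficients (defaults: the primary set of
#'   [fri_link_coefs]).
#' @return A list of class `fri_threshold`: `se_target`, `sp_target`,
#'   `or_implied`, `ln_or`, `fri_required`.
#' @export
required_fri <- function(se, sp, slope = fri_link_coefs$primary[["slope"]],
                         intercept = fri_link_coefs$primary[["intercept"]]) {
  if (!(se > 0 && se < 1 && sp > 0 && sp < 1)) {
    abort2("target se and sp must lie strictly inside (0, 1)",
           "frimeta_error_domain")
  }
  if (slope == 0) {
    abort2("link slope is zero; the relation cannot be inverted",
           "frimeta_error_inversion")
  }
  or <- (se * sp) / ((1 - se) * (1 - sp))
  lnor <- log(or)
  structure(list(se_target = se, sp_target = sp, or_implied = or,
                 ln_or = lnor, fri_required = (lnor - intercept) / slope),
            class = "fri_threshold")
}

#' Required-FRI table for a list of operating points
#'
#' @param targets list (or 2-column matrix/data.frame) of `(se, sp)` pairs.
#' @param slope,intercept link coefficients, or supply `fit` instead.
#' @param fit optional `metareg_fit` whose `fri` slope and intercept are
#'   used.
#' @return A data.frame with columns `se, sp, or, ln_or, fri` at full
#'   precision (zero rows for an empty target list).
#' @export
required_fri_table <- function(targets,
                               slope = fri_link_coefs$primary[["slope"]],
                               intercept = fri_link_coefs$primary[["intercept"]],
                               fit = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "metareg_fit"))
    slope <- fit$coef$fri$beta
    intercept <- fit$intercept$beta
  }
  if (is.matrix(targets) || is.data.frame(targets)) {
    targets <- lapply(seq_len(nrow(targets)),
                      function(i) as.numeric(targets[i, 1:2]))
  }
  if (!length(targets)) {
    return(data.frame(se = numeric(), sp = numeric(), or = numeric(),
                      ln_or = numeric(), fri = numeric()))
  }
  rows <- lapply(targets, function(t2) {
    r <- required_fri(t2[1], t2[2], slope, intercept)
    data.frame(se = r$se_target, sp = r$sp_target, or = r$or_implied,
               ln_or = r$ln_or, fri = r$fri_required)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Presentation rounding of a required-FRI table
#'
#' Rounds `or`, `ln_or` and `fri` half-up to two decimals, the conventional
#' presentation; the unrounded table from [required_fri_table()] keeps full
#' precision.
#'
#' @param tab output of [required_fri_table()].
#' @return The table with rounded `or`, `ln_or`, `fri` columns.
#' @export
format_fri_thresholds <- function(tab) {
  tab$or <- round_half_up(tab$or, 2)
  tab$ln_or <- round_half_up(tab$ln_or, 2)
  tab$fri <- round_half_up(tab$fri, 2)
  tab
}

#' Subgroup analysis with an interaction test
#'
#' Splits the studies into subgroups, pools each subgroup with the
#' bivariate model, and tests whether diagnostic accuracy differs between
#' subgroups via a Wald test on the group term(s) in a random-effects
#' meta-regression of ln(OR) (a z-test for a binary split; the chi-square
#' moderator test for multi-level splits). Groups too small for a bivariate
#' fit (< 2 studies) are reported with raw pooled proportions, flagged
#' `degenerate`, and excluded from the interaction test.
#'
#' @param studies a `study_set`.
#' @param variable covariate column the split is based on (label only).
#' @param splitter either a cut value (numeric `variable`: groups
#'   `"<cut"` / `">=cut"`) or a function mapping the studies data.frame to a
#'   vector of group labels.
#' @param level confidence level for per-group summaries.
#' @param method tau2 estimator for the interaction meta-regression.
#' @param ... passed to [fit_bivariate()] for the per-group fits.
#' @return A list of class `subgroup_result`: `variable`, `groups` (list of
#'   `label`, `n_studies`, `se`, `sp` with CIs, `degenerate`),
#'   `p_interaction`.
#' @export
subgroup_analysis <- function(studies, variable, splitter, level = 0.95,
                              method = c("reml", "dl"), ...) {
  method <- match.arg(method)
  studies <- as_study_set(as.data.frame(studies))
  if (is.function(splitter)) {
    grp <- splitter(studies)
  } else {
    if (!variable %in% names(studies)) {
      abort2(sprintf("covariate column not present: %s", variable),
             "frimeta_error_schema")
    }
    v <- studies[[variable]]
    if (!is.numeric(v)) {
      abort2("a cut-value splitter needs a numeric covariate",
             "frimeta_error_validation")
    }
    grp <- ifelse(v < splitter, sprintf("<%g", splitter),
                  sprintf(">=%g", splitter))
  }
  keep <- !is.na(grp)
  studies <- studies[keep, , drop = FALSE]
  grp <- as.character(grp[keep])
  if (length(unique(grp)) < 2) {
    abort2("splitter produced fewer than 2 subgroups",
           "frimeta_error_validation")
  }

  groups <- lapply(sort(unique(grp)), function(g) {
    sub <- studies[grp == g, , drop = FALSE]
    if (nrow(sub) >= 2) {
      fit <- fit_bivariate(sub, ...)
      ps <- pooled_summary(fit, level = level)
      list(label = g, n_studies = nrow(sub),
           se = ps$se, sp = ps$sp, degenerate = FALSE)
    } else {
      a <- summarize_study(sub[1, , drop = FALSE], ci_level = level)
      list(label = g, n_studies = nrow(sub),
           se = list(est = a$se_hat, ci = a$se_ci),
           sp = list(est = a$sp_hat, ci = a$sp_ci), degenerate = TRUE)
    }
  })

  ## interaction test on groups large enough for pooling
  sizes <- table(grp)
  ok_groups <- names(sizes)[sizes >= 2]
  p_int <- NA_real_
  if (length(ok_groups) >= 2) {
    in_test <- grp %in% ok_groups
    md <- metareg_data(studies[in_test, , drop = FALSE], character())
    dat <- data.frame(yi = md$y, vi = md$v, grp = factor(grp[in_test]))
    fit <- metafor::rma.uni(yi = yi, vi = vi, mods = ~ grp, data = dat,
                            method = toupper(method), test = "z",
                            control = list(threshold = 1e-10, maxiter = 1000))
    p_int <- fit$QMp
  }
  structure(list(variable = variable, groups = groups, p_interaction = p_int),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("Subgroup analysis by %s (p interaction = %.4g)\n",
              x$variable, x$p_interaction))
  for (g in x$groups) {
    cat(sprintf("  %-10s n=%2d  Se %.2f [%.2f, %.2f]  Sp %.2f [%.2f, %.2f]%s\n",
                g$label, g$n_studies, g$se$est, g$se$ci[1], g$se$ci[2],
                g$sp$est, g$sp$ci[1], g$sp$ci[2],
                if (g$degenerate) "  (raw proportions)" else ""))
  }
  invisible(x)
}
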