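test_that("quadrature log-likelihood is stable in the number of nodes", {
  st <- toy_studies()
  mu <- c(0.5, 1.2)
  sig <- matrix(c(0.6, -0.2, -0.2, 0.8), 2)
  ll15 <- bivariate_loglik(st, mu, sig, quad_points = 15)
  ll25 <- bivariate_loglik(st, mu, sig, quad_points = 25)
  ll35 <- bivariate_loglik(st, mu, sig, quad_points = 35)
  expect_lt(abs(ll25 - ll15), 1e-7)
  expect_lt(abs(ll35 - ll25), 1e-9)
})

test_that("with sigma fixed at zero a single balanced study gives mu = (0, 0)", {
  st <- as_study_set(data.frame(study_id = "s", disease = "d",
                                tp = 50, fp = 50, fn = 50, tn = 50))
  fit <- fit_bivariate(st, sigma_fixed = matrix(0, 2, 2), restarts = 1)
  expect_equal(fit$mu, c(0, 0), tolerance = 1e-5)
  expect_error(fit_bivariate(st), class = "frimeta_error_insufficient_data")
})

test_that("the fit is exchangeable in study order and equivariant under arm swapping", {
  st <- random_studies(8, seed = 3)
  fit <- fit_bivariate(st, quad_points = 9, restarts = 2)
  perm <- st[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  fit_p <- fit_bivariate(perm, quad_points = 9, restarts = 2)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit_p$mu, fit$mu, tolerance = 1e-4)

  swapped <- st
  swapped$tp <- st$tn; swapped$tn <- st$tp
  swapped$fp <- st$fn; swapped$fn <- st$fp
  fit_s <- fit_bivariate(as_study_set(swapped), quad_points = 9, restarts = 2)
  expect_equal(fit_s$mu, fit$mu[2:1], tolerance = 1e-3)
  expect_equal(fit_s$sigma[1, 1], fit$sigma[2, 2], tolerance = 1e-2)
  expect_equal(fit_s$sigma[2, 2], fit$sigma[1, 1], tolerance = 1e-2)
  expect_equal(fit_s$sigma[1, 2], fit$sigma[1, 2], tolerance = 1e-2)
  expect_equal(fit_s$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("estimated means recover a known truth within Monte-Carlo uncertainty", {
  cfg <- synthetic_config(n_studies = 40, mu = logit(c(0.89, 0.92)),
                          sigma = diag(0.5, 2), arm_size_range = c(100, 100),
                          seed = 2024)
  sim <- simulate_studies(cfg)
  fit <- fit_bivariate(sim$studies, quad_points = 9, restarts = 2)
  expect_true(fit$converged)
  se_mu <- sqrt(diag(fit$vcov_mu))
  expect_lt(abs(fit$mu[1] - logit(0.89)), 3 * se_mu[1])
  expect_lt(abs(fit$mu[2] - logit(0.92)), 3 * se_mu[2])
})

# a hand-built fit object isolates the summary transformations from the optimiser
fake_fit <- function(mu, vcov_mu = diag(0.04, 2), sigma = diag(0.5, 2)) {
  structure(list(mu = mu, sigma = sigma, vcov_mu = vcov_mu, loglik = 0,
                 n_studies = 10, converged = TRUE, quad_points = 15,
                 free_sigma = TRUE, study_id = paste0("s", 1:10),
                 data = data.frame(se = plogis(rnorm(10, mu[1], 0.5)),
                                   sp = plogis(rnorm(10, mu[2], 0.5)))),
            class = "bivariate_fit")
}

test_that("pooled_summary matches the closed-form transformations of the means", {
  fit <- fake_fit(logit(c(0.89, 0.92)))
  ps <- pooled_summary(fit)
  expect_equal(ps$se$est, 0.89)
  expect_equal(ps$sp$est, 0.92)
  expect_equal(ps$dor$est, (0.89 * 0.92) / (0.11 * 0.08))
  expect_equal(ps$dor$est, 93.045, tolerance = 1e-4)
  expect_equal(ps$plr$est, 0.89 / 0.08)
  expect_equal(ps$nlr$est, 0.11 / 0.92)
  # dor = plr/nlr to machine precision
  expect_equal(ps$dor$est, ps$plr$est / ps$nlr$est, tolerance = 1e-15)

  null <- pooled_summary(fake_fit(c(0, 0)))
  expect_equal(null$se$est, 0.5)
  expect_equal(null$sp$est, 0.5)
  expect_equal(null$plr$est, 1)
  expect_equal(null$nlr$est, 1)
  expect_equal(null$dor$est, 1)

  degenerate <- pooled_summary(fake_fit(logit(c(0.8, 0.9)),
                                        vcov_mu = matrix(0, 2, 2)))
  expect_equal(degenerate$se$ci, rep(0.8, 2))
  expect_equal(degenerate$dor$ci, rep(degenerate$dor$est, 2))

  bad <- fake_fit(c(1, 1), vcov_mu = matrix(c(1, 2, 2, 1), 2))
  expect_error(pooled_summary(bad), class = "frimeta_error_numerical")
})

test_that("SROC geometry: slope, symmetry, region containment and collapse", {
  # sigma12 = 0 gives a horizontal curve at the pooled sensitivity
  flat <- fake_fit(logit(c(0.9, 0.85)), sigma = diag(c(0.4, 0.7)))
  s <- sroc(flat)
  expect_true(all(abs(s$curve$se - 0.9) < 1e-12))
  expect_equal(unname(s$summary_point["se"]), 0.9)

  # exchangeable parameters: the summary point sits on the se = sp diagonal
  # and exchangeable-covariance regions are symmetric about it (the
  # regression-line curve itself is direction-specific by construction)
  symf <- fake_fit(c(1.5, 1.5), sigma = matrix(c(0.5, 0.2, 0.2, 0.5), 2),
                   vcov_mu = matrix(c(0.04, 0.01, 0.01, 0.04), 2))
  ss <- sroc(symf, n_points = 41)
  expect_equal(unname(ss$summary_point["se"]),
               unname(1 - ss$summary_point["fpr"]))
  # every reflected confidence-polygon point still lies on the ellipse
  Minv <- solve(symf$vcov_mu)
  refl <- ss$conf_region$polygon_logit[, 2:1]
  d <- sweep(refl, 2, symf$mu)
  expect_equal(rowSums((d %*% Minv) * d), rep(qchisq(0.95, 2), nrow(d)),
               tolerance = 1e-8)

  # summary point lies on the curve
  f <- fake_fit(logit(c(0.88, 0.91)), sigma = matrix(c(0.5, -0.15, -0.15, 0.4), 2))
  sf <- sroc(f)
  i <- which.min(abs(sf$curve$fpr - sf$summary_point["fpr"]))
  expect_equal(sf$curve$se[i], unname(sf$summary_point["se"]), tolerance = 1e-6)

  # prediction region contains the confidence region at equal level
  Vinv <- solve(f$vcov_mu + f$sigma)
  q <- qchisq(0.95, 2)
  d <- sweep(sf$conf_region$polygon_logit, 2, f$mu)
  expect_true(all(rowSums((d %*% Vinv) * d) <= q + 1e-8))

  # level -> 0 collapses both regions onto the summary point
  s0 <- sroc(f, level = 1e-12)
  expect_equal(max(abs(sweep(s0$conf_region$polygon_logit, 2, f$mu))), 0,
               tolerance = 1e-4)
  expect_equal(max(abs(sweep(s0$pred_region$polygon_logit, 2, f$mu))), 0,
               tolerance = 1e-4)

  # degenerate between-study variance of logit sp has no curve
  deg <- fake_fit(c(1, 1), sigma = diag(c(0.5, 0)))
  expect_error(sroc(deg), class = "frimeta_error_degenerate_curve")
})

test_that("refit_excluding drops exactly the flagged studies", {
  st <- read_studies(fixture_path("synthetic_studies_20.csv"))
  full <- fit_bivariate(st, quad_points = 7, restarts = 1)
  noop <- refit_excluding(st, flags = character(), quad_points = 7,
                          restarts = 1)
  expect_equal(noop$fit$loglik, full$loglik)
  expect_equal(noop$fit$mu, full$mu)
  expect_length(noop$dropped, 0)

  r <- refit_excluding(st, flags = "unclear_model", quad_points = 7,
                       restarts = 1)
  expect_equal(r$fit$n_studies, 15)
  expect_length(r$dropped, 5)

  # excluding everything (or all but one) is an error
  st2 <- st
  st2$excl_flags <- "unclear_model"
  st2$excl_flags[1] <- ""
  expect_error(refit_excluding(as_study_set(st2), flags = "unclear_model"),
               class = "frimeta_error_insufficient_data")
})
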