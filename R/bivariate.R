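## Bivariate random-effects pooling of sensitivity and specificity.
##
## Model: for study k with n1_k diseased and n2_k control subjects,
##   tp_k ~ Binomial(n1_k, invlogit(theta_k1)),
##   tn_k ~ Binomial(n2_k, invlogit(theta_k2)),
##   (theta_k1, theta_k2) ~ N(mu, Sigma).
## The exact marginal likelihood integrates the binomial kernels over the
## bivariate normal; each study's 2-D integral is evaluated by adaptive
## Gauss-Hermite product quadrature centred at the conditional mode and
## scaled by the conditional curvature. This is the binomial-normal GLMM
## used by DTA meta-analysis (the generalisation of the approximate-normal
## bivariate model that stays well-defined at observed Se or Sp of 1).

.gh_env <- new.env(parent = emptyenv())

gh_rule <- function(q) {
  key <- sprintf("q%d", q)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(q)
  .gh_env[[key]]
}

## counts from a study_set
study_counts <- function(studies) {
  studies <- as_study_set(as.data.frame(studies))
  list(tp = as.numeric(studies$tp), n1 = as.numeric(studies$tp + studies$fn),
       tn = as.numeric(studies$tn), n2 = as.numeric(studies$fp + studies$tn),
       study_id = studies$study_id)
}

## Marginal log-likelihood with adaptive GHQ. Returns list(ll, modes).
## modes0: K x 2 warm-start matrix for the per-study conditional modes.
.biv_ll <- function(cnt, mu, sigma, quad_points, modes0 = NULL) {
  K <- length(cnt$tp)
  tp <- cnt$tp; n1 <- cnt$n1; tn <- cnt$tn; n2 <- cnt$n2
  lch <- lchoose(n1, tp) + lchoose(n2, tn)

  if (max(abs(sigma)) < 1e-12) {
    ll <- sum(tp * mu[1] - n1 * log1pexp(mu[1]) +
                tn * mu[2] - n2 * log1pexp(mu[2]) + lch)
    return(list(ll = ll, modes = matrix(mu, K, 2, byrow = TRUE)))
  }

  detS <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  if (detS <= 0) return(list(ll = -Inf, modes = modes0))
  P11 <- sigma[2, 2] / detS
  P22 <- sigma[1, 1] / detS
  P12 <- -sigma[1, 2] / detS
  ldS <- log(detS)

  ## conditional modes by damped Newton on the (strictly concave) integrand
  th <- modes0
  if (is.null(th)) th <- matrix(mu, K, 2, byrow = TRUE)
  for (it in 1:60) {
    p1 <- stats::plogis(th[, 1]); p2 <- stats::plogis(th[, 2])
    e1 <- th[, 1] - mu[1]; e2 <- th[, 2] - mu[2]
    g1 <- tp - n1 * p1 - (P11 * e1 + P12 * e2)
    g2 <- tn - n2 * p2 - (P12 * e1 + P22 * e2)
    a <- n1 * p1 * (1 - p1) + P11
    d <- n2 * p2 * (1 - p2) + P22
    det <- a * d - P12^2
    s1 <- (d * g1 - P12 * g2) / det
    s2 <- (a * g2 - P12 * g1) / det
    damp <- pmax(1, pmax(abs(s1), abs(s2)) / 3)  # trust region of 3 logits
    th[, 1] <- th[, 1] + s1 / damp
    th[, 2] <- th[, 2] + s2 / damp
    if (max(abs(s1 / damp), abs(s2 / damp)) < 1e-11) break
  }

  ## curvature at the mode -> per-study scaling of the GH grid
  p1 <- stats::plogis(th[, 1]); p2 <- stats::plogis(th[, 2])
  a <- n1 * p1 * (1 - p1) + P11
  d <- n2 * p2 * (1 - p2) + P22
  detA <- a * d - P12^2
  ## lower Cholesky of A^{-1}, A = [[a, b], [b, d]], b = P12 for all studies:
  ## A^{-1} = (1/detA) [[d, -b], [-b, a]]; chol lower of [[x11,x12],[.,x22]]
  x11 <- d / detA; x12 <- -P12 / detA; x22 <- a / detA
  C11 <- sqrt(x11)
  C21 <- x12 / C11
  C22 <- sqrt(pmax(x22 - C21^2, 1e-300))
  logdetC <- log(C11) + log(C22)

  gh <- gh_rule(quad_points)
  zx <- rep(gh$x, times = quad_points)
  zy <- rep(gh$x, each = quad_points)
  lwz <- rep(log(gh$w), times = quad_points) +
    rep(log(gh$w), each = quad_points) + zx^2 + zy^2

  s2r <- sqrt(2)
  T1 <- th[, 1] + s2r * outer(C11, zx)                      # K x Q^2
  T2 <- th[, 2] + s2r * (outer(C21, zx) + outer(C22, zy))
  D1 <- T1 - mu[1]; D2 <- T2 - mu[2]
  H <- tp * T1 - n1 * log1pexp(T1) + tn * T2 - n2 * log1pexp(T2) -
    0.5 * (P11 * D1^2 + 2 * P12 * D1 * D2 + P22 * D2^2) -
    log(2 * pi) - 0.5 * ldS
  M <- sweep(H, 2, lwz, "+")
  rmax <- M[cbind(seq_len(K), max.col(M, ties.method = "first"))]
  ll_k <- log(2) + logdetC + rmax + log(rowSums(exp(M - rmax))) + lch
  list(ll = sum(ll_k), modes = th)
}

#' Marginal log-likelihood of the bivariate binomial-normal model
#'
#' Evaluates, at fixed parameters, the exact marginal log-likelihood in
#' which each study's true (logit Se, logit Sp) pair is bivariate normal
#' `N(mu, sigma)` and the observed cell counts are binomial. Each study's
#' two-dimensional integral is computed by adaptive Gauss-Hermite product
#' quadrature with `quad_points` nodes per dimension.
#'
#' @param studies a `study_set` (see [read_studies()]).
#' @param mu numeric(2): mean logit-sensitivity, mean logit-specificity.
#' @param sigma 2x2 positive-semidefinite between-study covariance.
#' @param quad_points Gauss-Hermite nodes per dimension (default 15).
#' @return The log-likelihood (a single number).
#' @export
bivariate_loglik <- function(studies, mu, sigma, quad_points = 15) {
  sigma <- as.matrix(sigma)
  stopifnot(length(mu) == 2, all(dim(sigma) == c(2, 2)),
            isTRUE(all.equal(sigma[1, 2], sigma[2, 1])))
  .biv_ll(study_counts(studies), mu, sigma, quad_points)$ll
}

## (mu1, mu2, log sd1, log sd2, atanh rho) -> Sigma
par_to_sigma <- function(par) {
  sd1 <- exp(par[3]); sd2 <- exp(par[4]); rho <- tanh(par[5])
  matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2, 2)
}

#' Fit the bivariate random-effects model
#'
#' Maximises the exact marginal likelihood of the binomial-normal bivariate
#' model (see [bivariate_loglik()]) over the mean logits and the
#' between-study covariance, parameterised as log standard deviations plus
#' the inverse hyperbolic tangent of the correlation so the optimisation is
#' unconstrained. Several restarts from jittered empirical starting values
#' guard against local maxima; the best run is returned and a run that did
#' not meet the optimiser's convergence test is reported via
#' `converged = FALSE`, never dropped.
#'
#' @inheritParams bivariate_loglik
#' @param max_iter maximum optimiser iterations per start.
#' @param tol relative convergence tolerance of the optimiser.
#' @param restarts number of optimisation starts (first is unjittered).
#' @param seed integer seed controlling the jitter of restarts.
#' @param sigma_fixed optional 2x2 matrix; when supplied the between-study
#'   covariance is held fixed at this value (a zero matrix reduces the fit
#'   to independent binomial logit means) and only `mu` is estimated.
#' @return An object of class `bivariate_fit`: list with `mu`, `sigma`,
#'   `vcov_mu`, `loglik`, `n_studies`, `converged`, `quad_points`, and the
#'   per-study forest table under `$data`.
#' @export
fit_bivariate <- function(studies, quad_points = 15, max_iter = 500,
                          tol = 1e-8, restarts = 5, seed = 1L,
                          sigma_fixed = NULL) {
  studies <- as_study_set(as.data.frame(studies))
  cnt <- study_counts(studies)
  K <- length(cnt$tp)
  free_sigma <- is.null(sigma_fixed)
  if (free_sigma && K < 2) {
    abort2("at least 2 studies are required to estimate the between-study covariance",
           "frimeta_error_insufficient_data")
  }

  ## empirical starting values from corrected logits
  l1 <- stats::qlogis((cnt$tp + 0.5) / (cnt$n1 + 1))
  l2 <- stats::qlogis((cnt$tn + 0.5) / (cnt$n2 + 1))
  mu0 <- c(mean(l1), mean(l2))
  if (free_sigma) {
    sd0 <- pmax(c(stats::sd(l1), stats::sd(l2)), 0.25)
    rho0 <- if (K >= 3) stats::cor(l1, l2) else 0
    if (!is.finite(rho0)) rho0 <- 0
    rho0 <- max(min(rho0, 0.9), -0.9)
    par0 <- c(mu0, log(sd0), atanh(rho0))
  } else {
    sigma_fixed <- as.matrix(sigma_fixed)
    par0 <- mu0
  }

  env <- new.env()
  env$modes <- NULL
  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par[1:2]) > 20)) return(1e10)
    if (free_sigma && (any(par[3:4] < -6) || any(par[3:4] > 3) ||
                         abs(par[5]) > 8)) {
      return(1e10)
    }
    sig <- if (free_sigma) par_to_sigma(par) else sigma_fixed
    r <- .biv_ll(cnt, par[1:2], sig, quad_points, env$modes)
    if (!is.finite(r$ll)) return(1e10)
    env$modes <- r$modes
    -r$ll
  }

  set.seed(seed)
  jitters <- lapply(seq_len(max(restarts, 1)), function(r) {
    if (r == 1) rep(0, length(par0)) else stats::rnorm(length(par0), 0, 0.4)
  })

  best <- NULL
  any_finite <- FALSE
  for (jt in jitters) {
    start <- par0 + jt
    env$modes <- NULL
    o <- tryCatch({
      o1 <- stats::optim(start, negll, method = "Nelder-Mead",
                         control = list(maxit = max_iter, reltol = tol))
      stats::optim(o1$par, negll, method = "BFGS",
                   control = list(maxit = 100, reltol = tol))
    }, error = function(e) NULL)
    if (is.null(o) || o$value >= 1e10) next
    any_finite <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!any_finite) {
    abort2(paste("bivariate fit failed: non-finite likelihood at every start",
                 sprintf("(n_studies = %d, quad_points = %d)", K, quad_points)),
           "frimeta_error_optimization")
  }

  par <- best$par
  mu <- par[1:2]
  sigma <- if (free_sigma) par_to_sigma(par) else sigma_fixed
  env$modes <- NULL
  hess <- tryCatch(stats::optimHess(par, negll), error = function(e) NULL)
  vcov_all <- NULL
  if (!is.null(hess)) {
    vcov_all <- tryCatch(solve(hess), error = function(e) NULL)
  }
  if (is.null(vcov_all) || any(!is.finite(vcov_all))) {
    warning("observed information is singular; using a pseudo-inverse for vcov",
            call. = FALSE)
    vcov_all <- pracma::pinv(hess)
  }
  vcov_mu <- vcov_all[1:2, 1:2, drop = FALSE]
  vcov_mu <- (vcov_mu + t(vcov_mu)) / 2

  structure(
    list(mu = mu, sigma = sigma, vcov_mu = vcov_mu,
         loglik = -best$value, n_studies = K,
         converged = best$convergence == 0, quad_points = quad_points,
         par = par, free_sigma = free_sigma,
         study_id = cnt$study_id, data = forest_table(studies)),
    class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("Bivariate binomial-normal fit (adaptive Gauss-Hermite,",
      x$quad_points, "nodes/dim)\n")
  cat(sprintf("  studies: %d   logLik: %.4f   converged: %s\n",
              x$n_studies, x$loglik, x$converged))
  cat(sprintf("  pooled Se: %.3f   pooled Sp: %.3f\n",
              invlogit(x$mu[1]), invlogit(x$mu[2])))
  cat(sprintf("  between-study SDs: %.3f / %.3f   correlation: %.3f\n",
              sqrt(x$sigma[1, 1]), sqrt(x$sigma[2, 2]),
              stats::cov2cor(x$sigma)[1, 2]))
  invisible(x)
}

#' Pooled summary estimates with confidence intervals
#'
#' Transforms a [fit_bivariate()] fit into the usual summary operating
#' characteristics: pooled sensitivity and specificity (Wald intervals on
#' the logit scale, back-transformed) and positive/negative likelihood
#' ratios and the diagnostic odds ratio (delta-method intervals on the log
#' scale, exponentiated).
#'
#' @param fit a `bivariate_fit`.
#' @param level confidence level (default 0.95).
#' @return A list of class `pooled_summary` with elements `se`, `sp`, `plr`,
#'   `nlr`, `dor` (each `list(est, ci)`) and `level`.
#' @export
pooled_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "bivariate_fit"), level > 0, level < 1)
  if (!fit$converged) {
    warning("summarising a fit flagged as not converged", call. = FALSE)
  }
  V <- fit$vcov_mu
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    abort2("vcov of the pooled means is not positive semi-definite",
           "frimeta_error_numerical")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  mu <- fit$mu
  se <- invlogit(mu[1]); sp <- invlogit(mu[2])
  se_ci <- invlogit(mu[1] + c(-1, 1) * z * sqrt(max(V[1, 1], 0)))
  sp_ci <- invlogit(mu[2] + c(-1, 1) * z * sqrt(max(V[2, 2], 0)))

  delta_ci <- function(log_est, grad) {
    v <- max(drop(t(grad) %*% V %*% grad), 0)
    exp(log_est + c(-1, 1) * z * sqrt(v))
  }
  plr <- se / (1 - sp)
  nlr <- (1 - se) / sp
  dor <- plr / nlr
  structure(
    list(se = list(est = se, ci = se_ci),
         sp = list(est = sp, ci = sp_ci),
         plr = list(est = plr, ci = delta_ci(log(plr), c(1 - se, sp))),
         nlr = list(est = nlr, ci = delta_ci(log(nlr), c(-se, -(1 - sp)))),
         dor = list(est = dor, ci = delta_ci(log(dor), c(1, 1))),
         level = level),
    class = "pooled_summary")
}

#' @export
print.pooled_summary <- function(x, ...) {
  lv <- round(100 * x$level)
  f <- function(nm, s, pct = FALSE) {
    if (pct) {
      cat(sprintf("  %-4s %5.1f%%  (%d%% CI %.1f%% to %.1f%%)\n", nm,
                  100 * s$est, lv, 100 * s$ci[1], 100 * s$ci[2]))
    } else {
      cat(sprintf("  %-4s %6.2f  (%d%% CI %.2f to %.2f)\n", nm,
                  s$est, lv, s$ci[1], s$ci[2]))
    }
  }
  cat("Pooled diagnostic accuracy\n")
  f("Se", x$se, TRUE); f("Sp", x$sp, TRUE)
  f("PLR", x$plr); f("NLR", x$nlr); f("DOR", x$dor)
  invisible(x)
}

#' @export
as.data.frame.pooled_summary <- function(x, ...) {
  m <- c("se", "sp", "plr", "nlr", "dor")
  data.frame(measure = m,
             est = vapply(x[m], function(s) s$est, 0),
             lo = vapply(x[m], function(s) s$ci[1], 0),
             hi = vapply(x[m], function(s) s$ci[2], 0),
             level = x$level, row.names = NULL)
}

## ellipse in logit space: center (2), covariance M, chi-square(2) quantile q
logit_ellipse <- function(center, M, q, n = 121) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  tt <- seq(0, 2 * pi, length.out = n)
  L <- e$vectors %*% diag(sqrt(vals), 2)
  pts <- t(center + sqrt(q) * L %*% rbind(cos(tt), sin(tt)))
  list(center = center, axes = sqrt(q * vals),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       polygon_logit = pts,
       polygon = data.frame(fpr = 1 - invlogit(pts[, 2]),
                            se = invlogit(pts[, 1])))
}

#' Summary ROC curve with confidence and prediction regions
#'
#' Traces the summary ROC (SROC) curve implied by the fitted bivariate
#' model: in logit space the curve is the regression of logit(Se) on
#' logit(Sp) through the between-study covariance,
#' `logit(se) = mu1 + (sigma12 / sigma22) (logit(sp) - mu2)`, evaluated over
#' a grid covering the observed false-positive-rate range and mapped to ROC
#' coordinates. The confidence region is the Wald ellipse of the summary
#' point (using `vcov_mu`) and the prediction region the ellipse for a new
#' study's true logit pair (using `vcov_mu + sigma`), both at the
#' chi-square(2) quantile of `level` and mapped pointwise to ROC space.
#'
#' @param fit a `bivariate_fit`.
#' @param level confidence level of the regions.
#' @param n_points number of grid points for the curve.
#' @return A list of class `sroc_result`: `curve` (data.frame `fpr`, `se`,
#'   ordered by `fpr`), `summary_point`, `conf_region`, `pred_region`,
#'   `level`.
#' @export
sroc <- function(fit, level = 0.95, n_points = 201) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (fit$sigma[2, 2] <= 1e-12) {
    abort2(paste("between-study variance of logit specificity is zero;",
                 "the SROC curve is degenerate - use the pooled summary point"),
           "frimeta_error_degenerate_curve")
  }
  dat <- fit$data
  lsp_obs <- stats::qlogis(pmin(pmax(dat$sp, 1e-4), 1 - 1e-4))
  lsp_rng <- range(c(lsp_obs, fit$mu[2]))
  lsp <- seq(lsp_rng[1], lsp_rng[2], length.out = n_points)
  lsp <- sort(unique(c(lsp, fit$mu[2])))
  slope <- fit$sigma[1, 2] / fit$sigma[2, 2]
  lse <- fit$mu[1] + slope * (lsp - fit$mu[2])
  curve <- data.frame(fpr = 1 - invlogit(lsp), se = invlogit(lse))
  curve <- curve[order(curve$fpr), ]
  rownames(curve) <- NULL

  q <- stats::qchisq(level, df = 2)
  structure(
    list(curve = curve,
         summary_point = c(fpr = 1 - invlogit(fit$mu[2]),
                           se = invlogit(fit$mu[1])),
         conf_region = logit_ellipse(fit$mu, fit$vcov_mu, q),
         pred_region = logit_ellipse(fit$mu, fit$vcov_mu + fit$sigma, q),
         level = level),
    class = "sroc_result")
}

#' Sensitivity refit after excluding flagged studies
#'
#' Refits the bivariate model on the subset of studies carrying none of the
#' given exclusion flags (tokens of the `excl_flags` column), recording
#' which studies were dropped.
#'
#' @param studies a `study_set` with an `excl_flags` column (absent column
#'   means no study is flagged).
#' @param flags character vector of exclusion flags; studies carrying any of
#'   them are dropped. An empty set reproduces the full fit.
#' @param ... passed to [fit_bivariate()].
#' @param level confidence level for the pooled summary.
#' @return A list with `fit` (`bivariate_fit`), `summary`
#'   (`pooled_summary`), `dropped` (study ids removed) and `flags`.
#' @export
refit_excluding <- function(studies, flags = character(), level = 0.95, ...) {
  studies <- as_study_set(as.data.frame(studies))
  if (length(flags) && "excl_flags" %in% names(studies)) {
    has_flag <- vapply(studies$excl_flags,
                       function(x) length(intersect(parse_flags(x), flags)) > 0,
                       logical(1))
  } else {
    has_flag <- rep(FALSE, nrow(studies))
  }
  keep <- studies[!has_flag, , drop = FALSE]
  if (nrow(keep) < 2) {
    abort2(sprintf("exclusion by {%s} leaves %d study(ies); at least 2 required",
                   paste(flags, collapse = ", "), nrow(keep)),
           "frimeta_error_insufficient_data")
  }
  fit <- fit_bivariate(keep, ...)
  list(fit = fit, summary = pooled_summary(fit, level = level),
       dropped = studies$study_id[has_flag], flags = flags)
}
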