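## Seeded synthetic-study generator.
##
## Emulates the data-generating process the pooling model assumes: each
## study's true (logit Se, logit Sp) is bivariate normal around the
## study-set means, and the observed 2x2 cells are binomial draws at
## realistic test-set arm sizes. Defaults reflect the benchmark study set:
## pooled Se 0.89 / Sp 0.92, between-study variances 0.5, and test arms of
## 17 to 242 subjects.

#' Configuration for the synthetic-study generator
#'
#' @param n_studies number of studies to generate.
#' @param mu numeric(2), mean logit-sensitivity and logit-specificity.
#'   Default `logit(c(0.89, 0.92))`, the benchmark pooled operating point.
#' @param sigma 2x2 PSD between-study covariance of the logits (default
#'   `diag(0.5, 0.5)`).
#' @param arm_size_range integer pair: test-set size per arm is drawn
#'   uniformly from this range (default `c(17, 242)`).
#' @param fri_link optional list activating the FRI-linked generator used by
#'   [simulate_fri_cohort()]: `slope`, `intercept`, and either `fri_values`
#'   (values sampled with replacement) or `fri_range` (continuous uniform);
#'   optional `sp_anchor` (default 0.92), `tau` (SD of ln(DOR) noise,
#'   default 0.3), `max_resample` (default 100).
#' @param seed integer seed; all randomness flows through it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_studies = 20,
                             mu = logit(c(0.89, 0.92)),
                             sigma = diag(0.5, 2),
                             arm_size_range = c(17L, 242L),
                             fri_link = NULL,
                             seed = 1L) {
  sigma <- as.matrix(sigma)
  stopifnot(n_studies >= 1, length(mu) == 2, all(dim(sigma) == c(2, 2)))
  if (any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    abort2("sigma must be positive semi-definite", "frimeta_error_validation")
  }
  if (length(arm_size_range) != 2 || arm_size_range[1] < 1 ||
        arm_size_range[2] < arm_size_range[1]) {
    abort2("arm_size_range must be an increasing pair of sizes >= 1",
           "frimeta_error_validation")
  }
  if (!is.null(fri_link)) {
    if (is.null(fri_link$slope) || is.null(fri_link$intercept) ||
          (is.null(fri_link$fri_values) && is.null(fri_link$fri_range))) {
      abort2("fri_link needs slope, intercept and fri_values or fri_range",
             "frimeta_error_validation")
    }
    fri_link$sp_anchor <- fri_link$sp_anchor %||% 0.92
    fri_link$tau <- fri_link$tau %||% 0.3
    fri_link$max_resample <- fri_link$max_resample %||% 100
  }
  structure(list(n_studies = n_studies, mu = mu, sigma = sigma,
                 arm_size_range = as.integer(round(arm_size_range)),
                 fri_link = fri_link, seed = as.integer(seed)),
            class = "synthetic_config")
}

## square root of a 2x2 PSD matrix (eigen-based, handles singular sigma)
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

## counts + covariate frame from latent logits
.draw_counts <- function(theta, arm_range, disease, fri = NULL) {
  K <- nrow(theta)
  span <- arm_range[2] - arm_range[1] + 1L
  n1 <- arm_range[1] - 1L + sample.int(span, K, replace = TRUE)
  n2 <- arm_range[1] - 1L + sample.int(span, K, replace = TRUE)
  tp <- stats::rbinom(K, n1, invlogit(theta[, 1]))
  tn <- stats::rbinom(K, n2, invlogit(theta[, 2]))
  df <- data.frame(study_id = sprintf("sim%03d", seq_len(K)),
                   disease = disease, tp = tp, fp = n2 - tn, fn = n1 - tp,
                   tn = tn, stringsAsFactors = FALSE)
  if (!is.null(fri)) df$fri <- fri
  ## a study whose sampled arm produced an empty margin cannot happen:
  ## n1, n2 >= 1 by construction, so tp+fn = n1 >= 1 and fp+tn = n2 >= 1
  as_study_set(df)
}

#' Simulate a set of diagnostic-accuracy studies
#'
#' Draws each study's true `(logit Se, logit Sp)` from `N(mu, sigma)`, arm
#' sizes uniformly from `arm_size_range`, and the 2x2 cells binomially.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return A list: `studies` (a `study_set`) and `truth` (list with the
#'   per-study latent logits `theta` and the generating `config`).
#' @export
simulate_studies <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  K <- cfg$n_studies
  Z <- matrix(stats::rnorm(2 * K), K, 2)
  theta <- sweep(Z %*% psd_sqrt(cfg$sigma), 2, cfg$mu, "+")
  studies <- .draw_counts(theta, cfg$arm_size_range, "synthetic")
  list(studies = studies,
       truth = list(theta = theta, config = cfg))
}

#' Simulate a cohort with a true FRI / ln(DOR) link
#'
#' Generates studies whose true log diagnostic odds ratio follows the
#' linear link `ln(DOR) = slope * FRI + intercept + N(0, tau^2)`. The DOR
#' is decomposed into an operating point by anchoring the true specificity
#' at `sp_anchor` and assigning the remainder to sensitivity
#' (`logit(se) = ln(DOR) - logit(sp_anchor)`, since
#' `ln(DOR) = logit(se) + logit(sp)`); cell counts are then drawn
#' binomially as in [simulate_studies()]. Draws whose implied logit
#' sensitivity falls outside ±12 are resampled (up to
#' `fri_link$max_resample` times, then an error is raised).
#'
#' @param cfg a [synthetic_config()] whose `fri_link` is set.
#' @return A list: `studies` (a `study_set` with an `fri` column) and
#'   `truth` (per-study latent logits `theta`, drawn `fri`, true `ln_dor`,
#'   and the generating `config`).
#' @export
simulate_fri_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  fl <- cfg$fri_link
  if (is.null(fl)) {
    abort2("cfg$fri_link must be set for simulate_fri_cohort",
           "frimeta_error_validation")
  }
  set.seed(cfg$seed)
  K <- cfg$n_studies
  lsp <- logit(fl$sp_anchor)

  draw_one <- function() {
    fri <- if (!is.null(fl$fri_range)) {
      stats::runif(1, fl$fri_range[1], fl$fri_range[2])
    } else {
      fl$fri_values[sample.int(length(fl$fri_values), 1)]
    }
    lndor <- fl$slope * fri + fl$intercept + stats::rnorm(1, 0, fl$tau)
    c(fri = fri, lndor = lndor, lse = lndor - lsp)
  }
  fri <- numeric(K); lndor <- numeric(K); lse <- numeric(K)
  for (k in seq_len(K)) {
    d <- draw_one()
    tries <- 0
    while (abs(d[["lse"]]) > 12) {
      tries <- tries + 1
      if (tries > fl$max_resample) {
        abort2(sprintf("implied logit(se) out of range after %d resamples (fri link too steep for sp_anchor %.2f)",
                       fl$max_resample, fl$sp_anchor),
               "frimeta_error_validation")
      }
      d <- draw_one()
    }
    fri[k] <- d[["fri"]]; lndor[k] <- d[["lndor"]]; lse[k] <- d[["lse"]]
  }
  theta <- cbind(lse, rep(lsp, K))
  studies <- .draw_counts(theta, cfg$arm_size_range, "synthetic", fri = fri)
  list(studies = studies,
       truth = list(theta = theta, fri = fri, ln_dor = lndor, config = cfg))
}
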