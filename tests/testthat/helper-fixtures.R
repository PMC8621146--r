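# shared fixtures built in code

toy_studies <- function() {
  as_study_set(data.frame(
    study_id = c("a", "b", "c"), disease = "toy",
    tp = c(18, 40, 9), fp = c(3, 6, 1), fn = c(4, 10, 5),
    tn = c(30, 80, 20), stringsAsFactors = FALSE))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "frimeta", mustWork = TRUE)
}

# random valid study records for property tests
random_studies <- function(k, seed) {
  set.seed(seed)
  n1 <- sample(5:200, k, TRUE)
  n2 <- sample(5:200, k, TRUE)
  tp <- rbinom(k, n1, runif(k, 0.5, 0.99))
  tn <- rbinom(k, n2, runif(k, 0.5, 0.99))
  as_study_set(data.frame(
    study_id = sprintf("r%03d", seq_len(k)), disease = "random",
    tp = tp, fp = n2 - tn, fn = n1 - tp, tn = tn,
    fri = round(runif(k, 3, 9), 3), training_n = sample(30:3465, k, TRUE),
    stringsAsFactors = FALSE))
}

# brute-force 2-D trapezoid integration of the bivariate binomial-normal
# marginal log-likelihood; independent of the quadrature implementation
brute_force_loglik <- function(studies, mu, sigma, lim = 8, n_grid = 801) {
  g1 <- seq(mu[1] - lim, mu[1] + lim, length.out = n_grid)
  g2 <- seq(mu[2] - lim, mu[2] + lim, length.out = n_grid)
  h1 <- g1[2] - g1[1]; h2 <- g2[2] - g2[1]
  w1 <- rep(1, n_grid); w1[c(1, n_grid)] <- 0.5
  w2 <- w1
  Si <- solve(sigma)
  ldet <- determinant(sigma, logarithm = TRUE)$modulus
  d1 <- g1 - mu[1]; d2 <- g2 - mu[2]
  # log bivariate normal density over the grid
  lphi <- -log(2 * pi) - 0.5 * as.numeric(ldet) -
    0.5 * (outer(Si[1, 1] * d1^2, Si[2, 2] * d2^2, "+") +
             2 * Si[1, 2] * outer(d1, d2))
  ll <- 0
  for (i in seq_len(nrow(studies))) {
    n1 <- studies$tp[i] + studies$fn[i]
    n2 <- studies$fp[i] + studies$tn[i]
    lb1 <- dbinom(studies$tp[i], n1, plogis(g1), log = TRUE)
    lb2 <- dbinom(studies$tn[i], n2, plogis(g2), log = TRUE)
    M <- exp(outer(lb1, lb2, "+") + lphi)
    ll <- ll + log(h1 * h2 * sum((w1 %o% w2) * M))
  }
  ll
}
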