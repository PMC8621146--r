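#' Logit and inverse logit
#'
#' Convenience transforms used throughout the package. `logit()` maps a
#' probability in (0, 1) to the real line; `invlogit()` is its inverse.
#'
#' @param p probability in (0, 1).
#' @param x real number.
#' @return A numeric vector.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
invlogit <- function(x) stats::plogis(x)

## log(1 + exp(x)) without overflow for large |x|
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 0
  out[big] <- x[big] + log1p(exp(-x[big]))
  out[!big] <- log1p(exp(x[!big]))
  out
}

## Clopper-Pearson exact binomial CI
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

## round-half-up at `digits` decimals (base round() is half-to-even)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

abort2 <- function(msg, class) {
  rlang::abort(msg, class = c(class, "frimeta_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
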