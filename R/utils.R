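# Internal numerical and seed helpers.

#' Derive a child seed from a master seed and a label
#'
#' Deterministically splits one integer master seed into independent child
#' seeds, one per named consumer, so that a whole fixture suite reproduces
#' from a single integer.
#'
#' @param seed integer master seed.
#' @param label character tag naming the consumer (e.g. "reef_grid").
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expm1(z)/z with the removable singularity at z = 0 filled in; vectorised.
.expm1_over <- function(z) {
  out <- rep(1, length(z))
  nz <- z != 0
  out[nz] <- expm1(z[nz]) / z[nz]
  out
}

# E(x, h) = integral_0^h exp(-x t) dt = (1 - exp(-x h))/x, stable at x = 0.
.eint <- function(x, h) h * .expm1_over(-x * h)

# Truncated series sum_{k=0}^{7} (-z)^k / (k! (k + m)), evaluated by Horner.
.texp_series <- function(z, m) {
  s <- 0
  for (k in 7:0) s <- s * (-z) / (k + 1) + 1 / (k + m)
  s
}

# I1(a, h) = integral_0^h t exp(-a t) dt, series-stabilised for small a*h.
.i1int <- function(a, h) {
  n <- max(length(a), length(h))
  a <- rep_len(a, n); h <- rep_len(h, n)
  z <- a * h
  out <- numeric(n)
  small <- abs(z) < 1e-4
  out[small] <- h[small]^2 * .texp_series(z[small], 2)
  big <- !small
  out[big] <- (1 - (1 + z[big]) * exp(-z[big])) / a[big]^2
  out
}

# I2(a, h) = integral_0^h t^2 exp(-a t) dt, same stabilisation.
.i2int <- function(a, h) {
  n <- max(length(a), length(h))
  a <- rep_len(a, n); h <- rep_len(h, n)
  z <- a * h
  out <- numeric(n)
  small <- abs(z) < 1e-4
  out[small] <- h[small]^3 * .texp_series(z[small], 3)
  big <- !small
  out[big] <- (2 - (2 + 2 * z[big] + z[big]^2) * exp(-z[big])) / a[big]^3
  out
}

# x log2 x with 0 log 0 = 0.
.plog2p <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}
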