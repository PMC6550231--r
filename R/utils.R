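# Internal helpers shared across modules.

# Wrap angles into (-pi, pi].
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# log I0(x), numerically stable for large x (besselI overflows near x ~ 700).
log_bessel_I0 <- function(x) {
  log(besselI(x, 0, expon.scaled = TRUE)) + x
}

log_bessel_I1 <- function(x) {
  log(besselI(x, 1, expon.scaled = TRUE)) + x
}

# A1(x) = I1(x)/I0(x), the mean resultant length of a von Mises distribution
# with concentration x.
bessel_A1 <- function(x) {
  ifelse(x == 0, 0, besselI(x, 1, expon.scaled = TRUE) /
           besselI(x, 0, expon.scaled = TRUE))
}

# Clip probabilities away from {0, 1}; used only where an odds transform needs
# an interior point.
clip_prob <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

# Deterministic per-patient seed stream: patient i's seed depends only on the
# master seed and i, never on cohort size. Kept strictly below 2^31.
patient_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 7919) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
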