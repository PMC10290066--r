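# Helpers shared across modules.

#' Degree/radian conversion
#' @param x angle in degrees (\code{deg2rad}) or radians (\code{rad2deg}).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Normalised von Mises density on the orientation ring (period pi), evaluated
# with the exponentially-scaled Bessel function so large kappa cannot overflow:
#   exp(kappa * cos(2x)) / (2 pi I0(kappa)) == exp(kappa * (cos(2x) - 1)) / (2 pi I0e(kappa))
vm_density <- function(x, kappa) {
  # besselI loses precision for very large kappa; switch to the asymptotic
  # expansion I0(k) e^-k ~ (1 + 1/8k + 9/128k^2) / sqrt(2 pi k)
  i0e <- if (kappa > 5e4) {
    (1 + 1 / (8 * kappa) + 9 / (128 * kappa^2)) / sqrt(2 * pi * kappa)
  } else {
    besselI(kappa, 0, expon.scaled = TRUE)
  }
  exp(kappa * (cos(2 * x) - 1)) / (2 * pi * i0e)
}

# Row-wise softmax with max-subtraction for stability.
softmax <- function(eta) {
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

# Linear interpolation on a circular domain of period `period`, where `x0`
# are equally spaced sample positions starting at x0[1].
circ_interp <- function(x0, y0, xout, period) {
  n <- length(x0)
  step <- period / n
  pos <- (xout - x0[1L]) %% period / step
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- (i0 %% n) + 1L
  i1 <- (i0 %% n) + 1L
  y0[i0] * (1 - frac) + y0[i1] * frac
}

# Tiny FNV-1a-style hash over a string, folded into 31 bits; avoids a
# dependency for seed derivation and config fingerprints.
fnv_hash <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

# Deterministic per-component seed derivation from a master seed, keeping the
# result a valid 32-bit integer.
derive_seed <- function(seed, ...) {
  fnv_hash(paste(c(seed, ...), collapse = "/"))
}

digest_fnv <- function(s) sprintf("%08x", fnv_hash(s))

`%||%` <- function(a, b) if (is.null(a)) b else a
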