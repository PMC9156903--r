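#' Log of the confluent hypergeometric function 1F1 (Kummer's M)
#'
#' Evaluates `log(1F1(a, b, z))` for `a > 0`, `b >= a`. Every use in this
#' package has the "balanced" form `b = 2a` (or `b - a = a` after shifting),
#' for which the Kummer transformation
#' `1F1(a, b, -x) = exp(-x) 1F1(b - a, b, x)` maps a negative argument onto a
#' series with all-positive terms. The positive series is summed in log space
#' (log-sum-exp), so there is no catastrophic cancellation and no overflow
#' even when `|z|` reaches 1e5-1e6, the scale of `2*N*s` at large N.
#'
#' @param a,b numerator and denominator parameters, `0 < a <= b`.
#' @param z argument (any sign).
#' @return `log(1F1(a, b, z))` as a double.
#' @examples
#' exp(log1f1(0.5, 1, 0))   # 1
#' @export
log1f1 <- function(a, b, z) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(z),
            length(a) == 1L, length(b) == 1L, length(z) == 1L,
            is.finite(a), is.finite(b), is.finite(z), a > 0, b >= a)
  out <- if (z >= 0) log1f1_pos(a, b, z) else z + log1f1_pos(b - a, b, -z)
  if (!is.finite(out)) {
    stop("1F1 evaluation failed (non-finite) at a=", a, " b=", b, " z=", z)
  }
  out
}

# log 1F1(a,b,x) for x >= 0 via the defining series; all terms positive.
# Truncation: term ratio ~ x/k for k >> x, so terms decay super-geometrically
# once k exceeds x; K = x + 12*sqrt(x) + 60 leaves a tail below 1e-16 of the
# peak term. The tail bound is asserted, not assumed.
log1f1_pos <- function(a, b, x) {
  if (x == 0) return(0)
  if (b == a) return(x)                     # 1F1(a,a,x) = e^x
  K <- ceiling(x + 12 * sqrt(x + 10) + 60)
  k <- seq.int(0L, K)
  logt <- lgamma(a + k) - lgamma(a) - lgamma(b + k) + lgamma(b) -
    lgamma(k + 1) + k * log(x)
  m <- max(logt)
  if (logt[length(logt)] > m - 36) {
    stop("1F1 series not converged at a=", a, " b=", b, " x=", x)
  }
  m + log(sum(exp(logt - m)))
}
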