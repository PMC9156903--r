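#' Establishment probability of a single beneficial lineage
#'
#' Probability that a lineage founded by one individual with selective
#' advantage `s` (Poisson-distributed offspring with mean `1 + s`) escapes
#' stochastic loss. It is the larger root of the fixed-point equation
#' `pi = 1 - exp(-(1 + s) * pi)`, solved by bisection on \[1e-12, 1\] to an
#' absolute tolerance of 1e-12. For `s <= 0` the only non-negative root is 0
#' and 0 is returned. For small `s`, `pi(s)` is close to (and below) `2s`.
#'
#' @param s selective advantage, `s > -1`; vectorized.
#' @return establishment probability in \[0, 1).
#' @examples
#' establishment_prob(0.001)      # ~ 0.002, so 1 - pi ~ 0.998
#' establishment_prob(c(0, 0.04))
#' @export
establishment_prob <- function(s) {
  stopifnot(is.numeric(s), all(is.finite(s)))
  if (any(s <= -1)) stop("establishment probability undefined for s <= -1")
  vapply(s, function(si) {
    if (si <= 0) return(0)
    f <- function(p) 1 - exp(-(1 + si) * p) - p
    lo <- 1e-12
    hi <- 1
    # f(lo) ~ s*lo > 0, f(1) = -exp(-(1+s)) < 0: root bracketed.
    while (hi - lo > 1e-12) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}
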