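#' Wright's stationary distribution of the survival-allele frequency
#'
#' Before the environmental change, the frequency `p` of the survival allele
#' in a population of size `N` is assumed to be at the stationary balance of
#' drift, purifying selection (cost `s_d`) and symmetric mutation (rate
#' `mu`):
#' \deqn{\phi(p) = C e^{-2 N s_d p} (p(1-p))^{2N\mu - 1},}
#' with `C` fixed by normalization. With `alpha = 2*N*mu` and
#' `gamma = 2*N*s_d`, the normalizer has the closed form
#' `1/C = 1F1(alpha, 2*alpha, -gamma) * Gamma(alpha)^2 / Gamma(2*alpha)`.
#' For `alpha < 1` (i.e. `N < 1/(2*mu)`, the regime of interest) the density
#' diverges at both endpoints but remains integrable.
#'
#' @param N population size (positive; treated as continuous).
#' @param mu symmetric mutation rate in (0, 1).
#' @param s_d selective cost, `>= 0`.
#' @return An object of class `wright_dist` with fields `N`, `mu`, `s_d`,
#'   `alpha`, `gamma` and `logC` (log of the normalization constant).
#' @examples
#' wd <- wright_dist(500, 1e-5, 0.001)
#' exp(wright_log_density(0.25, wd))
#' @export
wright_dist <- function(N, mu, s_d) {
  stopifnot(length(N) == 1L, is.finite(N), N >= 1,
            length(mu) == 1L, mu > 0, mu < 1,
            length(s_d) == 1L, s_d >= 0)
  alpha <- 2 * N * mu
  gamma <- 2 * N * s_d
  structure(
    list(N = N, mu = mu, s_d = s_d, alpha = alpha, gamma = gamma,
         logC = -wright_log_norm(N, mu, s_d)),
    class = "wright_dist"
  )
}

#' @export
print.wright_dist <- function(x, ...) {
  cat(sprintf(
    "Wright stationary distribution: N = %g, mu = %g, s_d = %g\n", x$N,
    x$mu, x$s_d))
  cat(sprintf("  alpha = 2N*mu = %g, gamma = 2N*s_d = %g, logC = %.6f\n",
              x$alpha, x$gamma, x$logC))
  invisible(x)
}

#' Log of the Wright normalization integral
#'
#' Returns `log(1/C)`, the log of
#' `integral_0^1 exp(-2 N s_d p) (p(1-p))^(2 N mu - 1) dp`, via the
#' confluent-hypergeometric closed form evaluated in log space.
#'
#' @inheritParams wright_dist
#' @return `log(1/C)`.
#' @export
wright_log_norm <- function(N, mu, s_d) {
  alpha <- 2 * N * mu
  gamma <- 2 * N * s_d
  log1f1(alpha, 2 * alpha, -gamma) + 2 * lgamma(alpha) - lgamma(2 * alpha)
}

#' Log-density of Wright's stationary distribution
#'
#' @param p allele frequency strictly inside (0, 1); vectorized. The density
#'   diverges at the endpoints when `2*N*mu < 1`, so `p` in \{0, 1\} is an
#'   error.
#' @param dist a [wright_dist()] object.
#' @return log phi(p).
#' @export
wright_log_density <- function(p, dist) {
  stopifnot(inherits(dist, "wright_dist"), is.numeric(p))
  if (any(p <= 0 | p >= 1)) {
    stop("wright_log_density is defined on the open interval (0, 1)")
  }
  dist$logC - dist$gamma * p + (dist$alpha - 1) * (log(p) + log1p(-p))
}

# ---- quadrature of integrals against the (unnormalized) Wright kernel ----
#
# kernel(p) = (p(1-p))^(alpha-1) exp(-gamma p), integrable endpoint
# singularities when alpha < 1. Integrals are computed by splitting at 1/2,
# mirroring the right half onto the left via q = 1 - p, panelizing
# log-spaced in p (so sharp interior features of exp(-gamma p) at large
# gamma fall inside a narrow panel), and removing the p = 0 singularity in
# the first panel by the exact substitution u = p^alpha, under which
# p^(alpha-1) dp = du / alpha and the integrand is bounded.

# integral over [lo, hi] subset of [0, 1/2] of kernel(p) * w(p) dp,
# where w is a vectorized bounded weight. `flip` mirrors the weight for use
# on the right half: the caller passes w(1 - q) there.
half_kernel_integral <- function(lo, hi, alpha, gamma, w, rel_tol = 1e-11) {
  if (hi <= lo) return(0)
  brk <- 10^seq(-9, log10(0.5), length.out = 12L)
  pts <- sort(unique(c(lo, hi, brk[brk > lo & brk < hi])))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    a <- pts[i]
    b <- pts[i + 1L]
    if (a == 0) {
      ub <- b^alpha
      if (ub <= 0) next   # alpha >> 1: kernel vanishes at this scale
      f <- function(u) {
        p <- u^(1 / alpha)
        exp((alpha - 1) * log1p(-p) - gamma * p) * w(p) / alpha
      }
      total <- total + stats::integrate(f, 0, ub, rel.tol = rel_tol,
                                        subdivisions = 200L)$value
    } else {
      f <- function(p) {
        exp((alpha - 1) * (log(p) + log1p(-p)) - gamma * p) * w(p)
      }
      total <- total + stats::integrate(f, a, b, rel.tol = rel_tol,
                                        subdivisions = 200L)$value
    }
  }
  total
}

# integral over [lo, hi] subset of [0, 1] of kernel(p) * w(p) dp
kernel_integral <- function(lo, hi, alpha, gamma, w = function(p) rep(1, length(p)),
                            rel_tol = 1e-11) {
  stopifnot(lo >= 0, hi <= 1, lo <= hi)
  left <- half_kernel_integral(lo, min(hi, 0.5), alpha, gamma, w, rel_tol)
  right <- 0
  if (hi > 0.5) {
    # q = 1 - p: kernel is symmetric up to the exponential factor
    wq <- function(q) exp(-gamma * (1 - q) + gamma * q) * w(1 - q)
    right <- half_kernel_integral(1 - hi, min(1 - lo, 0.5), alpha, gamma,
                                  wq, rel_tol)
  }
  left + right
}

# normalized expectation E[w(p)] (or partial mass) under the Wright
# distribution, by quadrature; the independent oracle for the closed forms.
wright_quad_moment <- function(N, mu, s_d, w = function(p) rep(1, length(p)),
                               lo = 0, hi = 1) {
  alpha <- 2 * N * mu
  gamma <- 2 * N * s_d
  kernel_integral(lo, hi, alpha, gamma, w) /
    kernel_integral(0, 1, alpha, gamma)
}

#' Mean frequency of the survival allele at stationarity
#'
#' Closed form
#' `pbar = (1/2) * 1F1(alpha + 1, 2*alpha + 1, -gamma) / 1F1(alpha, 2*alpha, -gamma)`
#' with `alpha = 2*N*mu`, `gamma = 2*N*s_d`. In small populations drift
#' dominates and `pbar` approaches 1/2 (symmetric mutation); in large
#' populations it approaches the deterministic mutation-selection balance
#' `mu / (s_d + 2*mu)`.
#'
#' @inheritParams wright_dist
#' @return mean frequency in (0, 0.5\].
#' @examples
#' mean_frequency(10, 1e-5, 0.001)    # ~ 0.495: drift-dominated
#' mean_frequency(1e6, 1e-5, 0.001)   # ~ mu / (s_d + 2 mu)
#' @export
mean_frequency <- function(N, mu, s_d) {
  vapply(N, function(n) {
    alpha <- 2 * n * mu
    gamma <- 2 * n * s_d
    if (gamma == 0) return(0.5)
    0.5 * exp(log1f1(alpha + 1, 2 * alpha + 1, -gamma) -
                log1f1(alpha, 2 * alpha, -gamma))
  }, numeric(1))
}

#' Probability that at least one copy of the survival allele is present
#'
#' Mass of Wright's stationary distribution above frequency `1/N`,
#' `P{at least 1 copy} = integral_{1/N}^1 phi(p) dp`, computed by
#' singularity-aware quadrature. For a mildly deleterious allele this
#' probability dips at intermediate population sizes (selection purges the
#' allele faster than drift restores it) before rising towards 1 as the
#' mutation supply grows with `N`.
#'
#' @inheritParams wright_dist
#' @param N population size, `>= 2`; vectorized.
#' @return probability in \[0, 1\].
#' @examples
#' prob_at_least_one_copy(100, 1e-5, 0.001)
#' @export
prob_at_least_one_copy <- function(N, mu, s_d) {
  stopifnot(all(N >= 2))
  vapply(N, function(n) {
    val <- wright_quad_moment(n, mu, s_d, lo = 1 / n, hi = 1)
    min(max(val, 0), 1)
  }, numeric(1))
}
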