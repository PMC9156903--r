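#' Find the vulnerable population size (local minimum of survival vs N)
#'
#' Scans the closed-form survival probability on a log-spaced grid of
#' population sizes, identifies interior grid points that are local minima,
#' and refines the rightmost one (largest N) by bounded scalar minimization
#' over continuous `N`. The rightmost interior minimum, when it exists, is
#' the vulnerable intermediate population size: populations of that size
#' are at greater risk of extinction than smaller ones facing the same
#' environmental challenge. Absence of a minimum is a valid result
#' (`exists = FALSE`), occurring e.g. when the pre-change cost `s_d` is so
#' small that the allele is effectively neutral over the whole range, or
#' when the benefit `s_b` or mutation rate `mu` is large enough that
#' survival grows monotonically with `N`.
#'
#' A candidate minimum must be at least `depth_tol` (in probability) below
#' both flanking grid values after refinement; this rejects spurious
#' minima arising from quadrature-level noise on near-flat curves.
#'
#' @param params a [model_params()] object.
#' @param N_lo,N_hi search range, `1 <= N_lo < N_hi`.
#' @param n_grid number of log-spaced grid points (default 240, >= 200).
#' @param depth_tol minimum depth in probability for a refined minimum to
#'   count (default 1e-6).
#' @return An object of class `minimum_report`: list with `exists`,
#'   `n_star` (NA when absent), `p_at_min` (NA when absent), and
#'   `search_range = c(N_lo, N_hi)`.
#' @examples
#' find_vulnerable_N(model_params(), 10, 1e6)
#' @export
find_vulnerable_N <- function(params, N_lo, N_hi, n_grid = 240L,
                              depth_tol = 1e-6) {
  params <- as_model_params(params)
  stopifnot(N_lo >= 1, N_lo < N_hi, n_grid >= 3L)
  grid <- exp(seq(log(N_lo), log(N_hi), length.out = n_grid))
  pv <- survival_probability(grid, params)
  n <- length(grid)
  interior <- 2:(n - 1L)
  is_min <- pv[interior] <= pv[interior - 1L] & pv[interior] <= pv[interior + 1L] &
    (pv[interior] < pv[interior - 1L] | pv[interior] < pv[interior + 1L])
  cand <- rev(interior[is_min])  # rightmost first
  f <- function(logN) survival_probability(exp(logN), params)
  for (i in cand) {
    opt <- stats::optimize(f, interval = log(c(grid[i - 1L], grid[i + 1L])),
                           tol = 1e-10)
    depth <- min(pv[i - 1L], pv[i + 1L]) - opt$objective
    if (depth >= depth_tol) {
      return(structure(
        list(exists = TRUE, n_star = exp(opt$minimum),
             p_at_min = opt$objective, search_range = c(N_lo, N_hi)),
        class = "minimum_report"))
    }
  }
  structure(
    list(exists = FALSE, n_star = NA_real_, p_at_min = NA_real_,
         search_range = c(N_lo, N_hi)),
    class = "minimum_report")
}

#' @export
print.minimum_report <- function(x, ...) {
  if (x$exists) {
    cat(sprintf(
      "Vulnerable population size: N* = %.1f (survival = %.6f) in [%g, %g]\n",
      x$n_star, x$p_at_min, x$search_range[1], x$search_range[2]))
  } else {
    cat(sprintf(
      "No interior local minimum of survival vs N in [%g, %g]\n",
      x$search_range[1], x$search_range[2]))
  }
  invisible(x)
}
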