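# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; cached.
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
    cache[[key]] <<- out
    out
  }
})

# vectorized per-interval Gauss-Legendre integration of f over each
# [lo[i], hi[i]]; f must be vectorized.
gl_panels <- function(f, lo, hi, n_nodes = 32L) {
  gl <- gauss_legendre(n_nodes)
  half <- (hi - lo) / 2
  mid <- (hi + lo) / 2
  x <- outer(half, gl$nodes) + mid          # n_panels x n_nodes
  vals <- matrix(f(as.vector(x)), nrow = length(lo))
  as.vector(vals %*% gl$weights) * half
}

#' Discretize Wright's stationary distribution onto the frequency grid
#'
#' Integrates the stationary density in bins with boundaries
#' `(0, 0.5/N, 1.5/N, ..., (N - 0.5)/N, 1)`: the two edge bins have width
#' `0.5/N` and every other bin is centred on a lattice frequency `j/N`.
#' The resulting `N + 1` masses over the frequencies `0, 1/N, ..., 1` are
#' the initial-condition distribution for the stochastic simulators.
#'
#' The density is steep (divergent, when `2*N*mu < 1`) at both boundaries,
#' so each bin is integrated after the exact substitution `u = p^alpha`
#' (mirrored on the right half), which removes the singularity; 32-node
#' Gauss-Legendre quadrature is applied per bin in the substituted
#' variable. Masses are checked against the closed-form normalizer to
#' 1e-10 and then renormalized to sum to exactly 1.
#'
#' @param N population size, integer `>= 2`.
#' @inheritParams wright_dist
#' @return numeric vector of length `N + 1`; element `j + 1` is the mass at
#'   frequency `j/N`. Names are the frequencies.
#' @examples
#' m <- discretize_wright(100, 1e-5, 0.001)
#' sum(m)  # 1
#' @export
discretize_wright <- function(N, mu, s_d) {
  stopifnot(length(N) == 1L, N >= 2, N == as.integer(N))
  alpha <- 2 * N * mu
  gamma <- 2 * N * s_d
  bnd <- c(0, (seq_len(N) - 0.5) / N, 1)   # N + 1 bins
  # split every bin at 0.5 so each piece lies in one half
  lo <- bnd[-length(bnd)]
  hi <- bnd[-1]
  # left pieces in u = p^alpha; right pieces mirrored via q = 1 - p
  left_mass <- function(a, b) {
    if (!length(a)) return(numeric(0))
    f <- function(u) {
      p <- u^(1 / alpha)
      exp((alpha - 1) * log1p(-p) - gamma * p) / alpha
    }
    gl_panels(f, a^alpha, b^alpha)
  }
  right_mass <- function(a, b) {  # [a, b] subset [0.5, 1]
    if (!length(a)) return(numeric(0))
    f <- function(v) {
      q <- v^(1 / alpha)          # q = 1 - p
      exp((alpha - 1) * log1p(-q) - gamma * (1 - q)) / alpha
    }
    gl_panels(f, (1 - b)^alpha, (1 - a)^alpha)
  }
  in_left <- hi <= 0.5
  in_right <- lo >= 0.5
  straddle <- !in_left & !in_right
  mass <- numeric(N + 1L)
  mass[in_left] <- left_mass(lo[in_left], hi[in_left])
  mass[in_right] <- right_mass(lo[in_right], hi[in_right])
  if (any(straddle)) {
    mass[straddle] <- left_mass(lo[straddle], 0.5) +
      right_mass(0.5, hi[straddle])
  }
  # Edge bins: p = u^(1/alpha) varies only in a thin layer near u = 1 when
  # alpha << 1, which fixed-order Gauss-Legendre misses; use adaptive
  # quadrature there instead.
  mass[1L] <- kernel_integral(0, hi[1L], alpha, gamma)
  mass[N + 1L] <- kernel_integral(lo[N + 1L], 1, alpha, gamma)
  total <- sum(mass)
  norm <- exp(wright_log_norm(N, mu, s_d))
  if (abs(total / norm - 1) > 1e-10) {
    stop("bin-mass quadrature failed: masses sum to ", total / norm,
         " of the closed-form normalizer at N = ", N)
  }
  mass <- mass / total
  names(mass) <- format(seq(0, N) / N, trim = TRUE)
  mass
}

#' Draw initial survival-allele frequencies from the discretized distribution
#'
#' Categorical draw from the `N + 1` lattice frequencies with the masses
#' returned by [discretize_wright()]. Uses R's global RNG stream, so draws
#' are reproducible under `set.seed()`.
#'
#' @param masses probability masses over `0, 1/N, ..., 1` (length `N + 1`).
#' @param size number of draws.
#' @return numeric vector of frequencies on the lattice.
#' @examples
#' set.seed(1)
#' sample_initial_frequency(discretize_wright(50, 1e-5, 0.001), 5)
#' @export
sample_initial_frequency <- function(masses, size = 1L) {
  stopifnot(is.numeric(masses), length(masses) >= 2, all(masses >= 0))
  N <- length(masses) - 1L
  (sample.int(N + 1L, size = size, replace = TRUE, prob = masses) - 1L) / N
}
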