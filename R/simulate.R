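#' Configuration for the stochastic simulators
#'
#' @param threshold survival-lineage count at which establishment is
#'   declared (default 2000; results are insensitive to this as long as a
#'   lineage that large is very unlikely to die out).
#' @param max_generations hard cap on simulated generations; replicates
#'   hitting it are reported as censored, distinct from both outcomes
#'   (default 1e6).
#' @param seed integer RNG seed for the root stream.
#' @param replicates number of independent replicates for
#'   [estimate_survival()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(threshold = 2000L, max_generations = 1e6,
                       seed = 1L, replicates = 1L) {
  stopifnot(threshold >= 1, replicates >= 1, max_generations >= 1)
  structure(list(threshold = as.integer(threshold),
                 max_generations = max_generations,
                 seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "sim_config")
}

#' Parameters of the Ricker density-regulated variant
#'
#' In the Ricker variant the environmental change acts through the
#' wild-type carrying capacity, which decays as `K_t = K0 * (1 - delta)^t`;
#' the survival allele's capacity stays at `K0`. Per-capita mean offspring
#' numbers are `exp(r * (1 - N_t / K_t))` for wild type and
#' `exp(r * (1 - N_t / K0))` for survival-allele carriers.
#'
#' @param K0 initial carrying capacity (individuals, `>= 2`); the
#'   population starts at `N_0 = K0`.
#' @param r intrinsic growth rate (> 0). Default 1.0 — a deliberate,
#'   visible configuration default, not a recovered value.
#' @return An object of class `ricker_params`.
#' @export
ricker_params <- function(K0, r = 1.0) {
  stopifnot(K0 >= 2, r > 0)
  structure(list(K0 = as.integer(K0), r = r), class = "ricker_params")
}

# Symmetric mutation applied to the offspring of one generation: each
# offspring individual flips allele independently with probability mu,
# implemented as two binomial thinnings. Total count is conserved.
mutate_offspring <- function(L_off, M_off, mu) {
  to_M <- stats::rbinom(1L, L_off, mu)
  to_L <- stats::rbinom(1L, M_off, mu)
  c(L = L_off - to_M + to_L, M = M_off - to_L + to_M)
}

sim_outcome <- function(survived, censored, generations, initial_p, L, M) {
  structure(list(survived = survived, censored = censored,
                 generations = generations, initial_p = initial_p,
                 final_L = L, final_M = M),
            class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  status <- if (x$censored) "censored" else if (x$survived) "survived" else "extinct"
  cat(sprintf("Simulation outcome: %s after %d generations (p0 = %g; final L = %g, M = %g)\n",
              status, x$generations, x$initial_p, x$final_L, x$final_M))
  invisible(x)
}

#' Branching-process rescue simulation
#'
#' One stochastic replicate of the independent-lineage model, started at
#' the moment of the environmental change. The initial survival-allele
#' frequency `p` is drawn from the discretized Wright stationary
#' distribution (or forced via `p_init`); `M_0 = round(p*N)` and
#' `L_0 = N - M_0`. Each generation, wild-type offspring are Poisson with
#' mean `(1 - delta) * L` and survival-lineage offspring Poisson with mean
#' `(1 - delta + s_b) * M`; every offspring then mutates independently with
#' probability `mu` (symmetric). The process stops at extinction
#' (`L + M = 0`) or establishment (`M >= threshold`).
#'
#' Uses the global RNG stream; wrap in `set.seed()` for reproducibility, or
#' use [estimate_survival()] for seeded replicate management.
#'
#' @param N initial population size (integer `>= 1`).
#' @param params a [model_params()] object.
#' @param config a [sim_config()] object.
#' @param p_init optional forced initial frequency in \[0, 1\] (bypasses the
#'   Wright draw; used for worked examples and tests).
#' @param masses optional precomputed [discretize_wright()] masses for this
#'   `N` (avoids recomputation across replicates).
#' @param mu_off if `TRUE`, run with mutation switched off (`mu = 0`)
#'   after the change; the stationary draw still uses `mu`.
#' @return a `sim_outcome` object.
#' @examples
#' set.seed(1)
#' simulate_branching(200, model_params(), sim_config())
#' @export
simulate_branching <- function(N, params, config = sim_config(),
                               p_init = NULL, masses = NULL, mu_off = FALSE) {
  params <- as_model_params(params)
  stopifnot(N >= 1)
  if (is.null(p_init)) {
    if (is.null(masses)) masses <- discretize_wright(N, params$mu, params$s_d)
    p_init <- sample_initial_frequency(masses, 1L)
  }
  stopifnot(p_init >= 0, p_init <= 1)
  M <- round(p_init * N)
  L <- N - M
  mu <- if (mu_off) 0 else params$mu
  mean_L <- 1 - params$delta
  mean_M <- 1 - params$delta + params$s_b
  gen <- 0L
  while (L + M > 0 && M < config$threshold) {
    if (gen >= config$max_generations) {
      return(sim_outcome(FALSE, TRUE, gen, p_init, L, M))
    }
    L_off <- stats::rpois(1L, mean_L * L)
    M_off <- stats::rpois(1L, mean_M * M)
    counts <- if (mu > 0) mutate_offspring(L_off, M_off, mu) else c(L_off, M_off)
    L <- counts[[1]]
    M <- counts[[2]]
    gen <- gen + 1L
  }
  sim_outcome(M >= config$threshold, FALSE, gen, p_init, L, M)
}

#' Ricker density-regulated rescue simulation
#'
#' One replicate of the variant in which survival lineages do not reproduce
#' independently: reproduction is density-regulated with per-capita mean
#' offspring `exp(r * (1 - N_t / K_t))` for wild type (capacity decaying as
#' `K_t = K0 (1 - delta)^t`) and `exp(r * (1 - N_t / K0))` for
#' survival-allele carriers (capacity unaffected). The population starts at
#' the Wright stationary distribution with `N_0 = K0`. Establishment is
#' declared when the survival-allele count reaches
#' `min(threshold, ceiling(K0 / 2))` — half the undiminished capacity —
#' since the capacity itself may be below the default threshold.
#'
#' @param ricker a [ricker_params()] object.
#' @inheritParams simulate_branching
#' @return a `sim_outcome` object.
#' @examples
#' set.seed(1)
#' simulate_ricker(ricker_params(200), model_params(), sim_config())
#' @export
simulate_ricker <- function(ricker, params, config = sim_config(),
                            p_init = NULL, masses = NULL) {
  params <- as_model_params(params)
  stopifnot(inherits(ricker, "ricker_params"))
  K0 <- ricker$K0
  r <- ricker$r
  if (is.null(p_init)) {
    if (is.null(masses)) masses <- discretize_wright(K0, params$mu, params$s_d)
    p_init <- sample_initial_frequency(masses, 1L)
  }
  M <- round(p_init * K0)
  L <- K0 - M
  goal <- min(config$threshold, ceiling(K0 / 2))
  mu <- params$mu
  gen <- 0L
  while (L + M > 0 && M < goal) {
    if (gen >= config$max_generations) {
      return(sim_outcome(FALSE, TRUE, gen, p_init, L, M))
    }
    Nt <- L + M
    Kt <- K0 * (1 - params$delta)^gen
    mean_L <- if (Kt > 0) exp(r * (1 - Nt / Kt)) else 0
    mean_M <- exp(r * (1 - Nt / K0))
    L_off <- stats::rpois(1L, mean_L * L)
    M_off <- stats::rpois(1L, mean_M * M)
    counts <- mutate_offspring(L_off, M_off, mu)
    L <- counts[[1]]
    M <- counts[[2]]
    gen <- gen + 1L
  }
  sim_outcome(M >= goal, FALSE, gen, p_init, L, M)
}

#' Estimate the survival fraction over replicate simulations
#'
#' Runs the branching-process (or Ricker) simulator `config$replicates`
#' times. The root seed deterministically spawns one sub-seed per
#' replicate, so results are reproducible and independent of replicate
#' order. Censored replicates (hitting `max_generations`) are excluded
#' from the fraction and reported separately.
#'
#' @param N initial population size (branching model) — ignored for
#'   `model = "ricker"`, where `ricker$K0` sets the size.
#' @param params a [model_params()] object.
#' @param config a [sim_config()] object (seed and replicate count live
#'   here).
#' @param model `"branching"` or `"ricker"`.
#' @param ricker a [ricker_params()] object (required for
#'   `model = "ricker"`).
#' @param p_init optional forced initial frequency applied to every
#'   replicate.
#' @param mu_off passed to [simulate_branching()].
#' @return An object of class `survival_estimate`: list with `fraction`,
#'   `se` (binomial standard error), `survived`, `censored`, `replicates`,
#'   `N`, `seed`.
#' @examples
#' estimate_survival(100, model_params(), sim_config(seed = 1, replicates = 50))
#' @export
estimate_survival <- function(N, params, config, model = c("branching", "ricker"),
                              ricker = NULL, p_init = NULL, mu_off = FALSE) {
  params <- as_model_params(params)
  model <- match.arg(model)
  reps <- config$replicates
  size <- if (model == "ricker") {
    stopifnot(inherits(ricker, "ricker_params"))
    ricker$K0
  } else N
  masses <- if (is.null(p_init)) {
    discretize_wright(size, params$mu, params$s_d)
  } else NULL
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  survived <- 0L
  censored <- 0L
  for (i in seq_len(reps)) {
    set.seed(sub_seeds[i])
    out <- if (model == "branching") {
      simulate_branching(N, params, config, p_init = p_init,
                         masses = masses, mu_off = mu_off)
    } else {
      simulate_ricker(ricker, params, config, p_init = p_init,
                      masses = masses)
    }
    if (out$censored) censored <- censored + 1L
    else if (out$survived) survived <- survived + 1L
  }
  n_eff <- reps - censored
  frac <- if (n_eff > 0) survived / n_eff else NA_real_
  structure(
    list(fraction = frac,
         se = if (n_eff > 0) sqrt(frac * (1 - frac) / n_eff) else NA_real_,
         survived = survived, censored = censored, replicates = reps,
         N = size, seed = config$seed),
    class = "survival_estimate")
}

#' @export
print.survival_estimate <- function(x, ...) {
  cat(sprintf(
    "Survival estimate at N = %g: %.4f (SE %.4f; %d/%d survived, %d censored)\n",
    x$N, x$fraction, x$se, x$survived, x$replicates - x$censored, x$censored))
  invisible(x)
}
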