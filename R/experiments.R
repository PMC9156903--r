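#' Specification of a parameter sweep
#'
#' @param varied name of the swept parameter: one of `"N"`, `"s_b"`,
#'   `"s_d"`, `"mu"`, `"delta"`, `"p_max"`.
#' @param values strictly increasing, non-empty vector of values for the
#'   swept parameter.
#' @param base [model_params()] defaults for every other parameter.
#' @param n_grid N-grid specification `c(lo, hi, points)`, log-spaced;
#'   default 60 points on \[10, 1e6\], spanning both `N_neut` and `N_mut`
#'   for the default parameters.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(varied, values, base = model_params(),
                       n_grid = c(10, 1e6, 60)) {
  varied <- match.arg(varied, c("N", "s_b", "s_d", "mu", "delta", "p_max"))
  stopifnot(length(values) >= 1, !is.unsorted(values, strictly = TRUE),
            length(n_grid) == 3, n_grid[1] < n_grid[2], n_grid[3] >= 2)
  structure(list(varied = varied, values = values,
                 base = as_model_params(base), n_grid = n_grid),
            class = "sweep_spec")
}

n_grid_values <- function(spec) {
  exp(seq(log(spec$n_grid[1]), log(spec$n_grid[2]),
          length.out = spec$n_grid[3]))
}

with_param <- function(base, name, value) {
  args <- list(s_b = base$s_b, s_d = base$s_d, delta = base$delta,
               mu = base$mu)
  args[[name]] <- value
  do.call(model_params, args)
}

#' Per-N summary table of the analytic quantities
#'
#' One row per population size with every closed-form quantity: marginal
#' survival, the standing/de-novo decomposition, mean stationary frequency
#' and the probability that at least one allele copy is present.
#'
#' @param N vector of population sizes.
#' @param params a [model_params()] object.
#' @return data.frame with columns `N`, `p_survival`, `p_stand`,
#'   `p_de_novo`, `p_total`, `p_mean`, `p_at_least_one_copy`.
#' @examples
#' survival_table(c(100, 1000, 1e4), model_params())
#' @export
survival_table <- function(N, params) {
  params <- as_model_params(params)
  comps <- lapply(N, survival_components, params = params)
  data.frame(
    N = N,
    p_survival = vapply(comps, `[[`, numeric(1), "p_closed_form"),
    p_stand = vapply(comps, `[[`, numeric(1), "p_stand"),
    p_de_novo = vapply(comps, `[[`, numeric(1), "p_de_novo"),
    p_total = vapply(comps, `[[`, numeric(1), "p_total"),
    p_mean = mean_frequency(N, params$mu, params$s_d),
    p_at_least_one_copy = prob_at_least_one_copy(pmax(N, 2), params$mu,
                                                 params$s_d)
  )
}

#' Stationary-distribution panels: mean frequency and presence probability
#'
#' For each value of the swept parameter (crossed with the N grid when the
#' sweep is not over N itself), tabulates the mean stationary frequency and
#' the probability that at least one copy of the survival allele is
#' present. Deterministic.
#'
#' @param spec a [sweep_spec()] object; `varied` must be one of `N`, `mu`,
#'   `s_d`.
#' @return data.frame with columns `N`, `mu`, `s_d`, `p_mean`,
#'   `p_at_least_one_copy`.
#' @export
run_wright_panels <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"),
            spec$varied %in% c("N", "mu", "s_d"))
  base <- spec$base
  grid <- if (spec$varied == "N") {
    data.frame(N = spec$values, mu = base$mu, s_d = base$s_d)
  } else {
    expand.grid(N = n_grid_values(spec), value = spec$values)
  }
  if (spec$varied == "mu") {
    grid <- data.frame(N = grid$N, mu = grid$value, s_d = base$s_d)
  } else if (spec$varied == "s_d") {
    grid <- data.frame(N = grid$N, mu = base$mu, s_d = grid$value)
  }
  grid$p_mean <- mapply(mean_frequency, grid$N, grid$mu, grid$s_d)
  grid$p_at_least_one_copy <- mapply(prob_at_least_one_copy,
                                     pmax(grid$N, 2), grid$mu, grid$s_d)
  grid
}

#' Survival-versus-N curves, optionally with simulation points
#'
#' For each value of the swept parameter, computes the closed-form survival
#' probability over the N grid. When `with_sim = TRUE`, a log-spaced
#' sub-grid of `sim_points` sizes is additionally estimated by the
#' branching-process simulator, with binomial standard errors.
#'
#' @param spec a [sweep_spec()] object (`varied` among `s_b`, `s_d`, `mu`,
#'   `delta`, or `N` for a single curve at the base parameters).
#' @param with_sim add Monte Carlo points?
#' @param config a [sim_config()] object (replicates and seed for the
#'   points).
#' @param sim_points number of simulated sizes per curve (default 12).
#' @return data.frame with columns `varied`, `value`, `N`, `p_survival`
#'   and, for simulated rows, `fraction`, `se`, `reps`, `censored`
#'   (NA elsewhere).
#' @export
run_survival_curves <- function(spec, with_sim = FALSE,
                                config = sim_config(replicates = 1000),
                                sim_points = 12L) {
  stopifnot(inherits(spec, "sweep_spec"))
  Ns <- if (spec$varied == "N") spec$values else n_grid_values(spec)
  vals <- if (spec$varied == "N") NA_real_ else spec$values
  out <- list()
  for (v in vals) {
    pars <- if (spec$varied == "N") spec$base else
      with_param(spec$base, spec$varied, v)
    df <- data.frame(varied = spec$varied, value = v, N = Ns,
                     p_survival = survival_probability(Ns, pars),
                     fraction = NA_real_, se = NA_real_,
                     reps = NA_integer_, censored = NA_integer_)
    if (with_sim) {
      idx <- unique(round(seq(1, length(Ns), length.out = sim_points)))
      for (i in idx) {
        n_int <- max(2L, round(Ns[i]))
        est <- estimate_survival(n_int, pars, config)
        df$fraction[i] <- est$fraction
        df$se[i] <- est$se
        df$reps[i] <- est$replicates
        df$censored[i] <- est$censored
      }
    }
    out[[length(out) + 1L]] <- df
  }
  do.call(rbind, out)
}

#' Standing-variation versus de novo decomposition over the N grid
#'
#' Tabulates [survival_table()] over the sweep's N grid at the base
#' parameters. The thresholds `N_neut = 1/s_d` and `N_mut = 1/mu` are
#' attached as attributes (and written as comment metadata by
#' [write_rescue_csv()]).
#'
#' @param spec a [sweep_spec()] object (only `base` and `n_grid` are used).
#' @return data.frame as [survival_table()], with attributes `N_neut`,
#'   `N_mut`.
#' @export
run_decomposition <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  df <- survival_table(n_grid_values(spec), spec$base)
  attr(df, "N_neut") <- spec$base$N_neut
  attr(df, "N_mut") <- spec$base$N_mut
  df
}

#' Sweep of the vulnerable population size
#'
#' For each value of the swept parameter (`mu` or `s_d`) and each level of
#' `s_b`, locates the rightmost local minimum of survival versus N. Rows
#' with `exists = FALSE` mark regimes where survival is monotone in N (the
#' strongly deleterious and effectively neutral extremes).
#'
#' @param spec a [sweep_spec()] object with `varied` in `mu`, `s_d`; the
#'   N search range is `spec$n_grid[1:2]`.
#' @param s_b_levels vector of `s_b` values to cross with the sweep.
#' @return data.frame with columns `varied`, `value`, `s_b`, `exists`,
#'   `n_star`, `p_at_min`.
#' @export
run_minimum_scan <- function(spec, s_b_levels = spec$base$s_b) {
  stopifnot(inherits(spec, "sweep_spec"), spec$varied %in% c("mu", "s_d"))
  rows <- list()
  for (sb in s_b_levels) {
    for (v in spec$values) {
      pars <- with_param(with_param(spec$base, "s_b", sb), spec$varied, v)
      rep <- find_vulnerable_N(pars, spec$n_grid[1], spec$n_grid[2])
      rows[[length(rows) + 1L]] <- data.frame(
        varied = spec$varied, value = v, s_b = sb, exists = rep$exists,
        n_star = rep$n_star, p_at_min = rep$p_at_min)
    }
  }
  do.call(rbind, rows)
}

#' Write a results table as CSV with comment metadata
#'
#' Deterministic writer: numeric columns at full precision, optional
#' `# key=value` comment lines (e.g. the `N_neut`/`N_mut` attributes of
#' [run_decomposition()]) before the header.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list/vector of metadata; defaults to the `N_neut` and
#'   `N_mut` attributes of `df` when present.
#' @return `path`, invisibly.
#' @export
write_rescue_csv <- function(df, path, meta = NULL) {
  if (is.null(meta)) {
    meta <- list()
    for (key in c("N_neut", "N_mut")) {
      if (!is.null(attr(df, key))) meta[[key]] <- attr(df, key)
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s=%.15g", key, as.numeric(meta[[key]])), con)
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
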