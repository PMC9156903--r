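#' Parameters of the environmental-change scenario
#'
#' Bundles the four primitive parameters of the haploid two-allele model and
#' the derived quantities used throughout: after the abrupt change the
#' wild type declines at rate `delta` per generation (absolute fitness
#' `1 - delta`) while carriers of the survival allele have fitness
#' `1 - delta + s_b`; before the change the survival allele carries a cost
#' `s_d`; mutation between the two alleles is symmetric at rate `mu` per
#' individual per generation.
#'
#' Derived fields: `s_r = s_b - delta` (net growth advantage after the
#' change), `N_neut = 1/s_d` (population size above which the cost is no
#' longer effectively neutral; `Inf` when `s_d = 0`) and `N_mut = 1/mu`
#' (size at which one new survival-allele copy arises per generation on
#' average).
#'
#' Defaults are the reference parameter set used for all worked examples:
#' `s_b = 0.05`, `delta = 0.01`, `s_d = 0.001`, `mu = 1e-5`.
#'
#' @param s_b selective benefit of the survival allele after the change
#'   (dimensionless, `s_b > delta`).
#' @param s_d selective cost before the change (dimensionless, `>= 0`).
#' @param delta per-generation decline rate of the wild type after the
#'   change, in (0, 1).
#' @param mu symmetric per-individual mutation rate, in (0, 1) and
#'   `mu < delta`.
#' @return An object of class `model_params`.
#' @examples
#' model_params()
#' model_params(s_b = 0.011)  # s_r = 0.001
#' @export
model_params <- function(s_b = 0.05, s_d = 0.001, delta = 0.01, mu = 1e-5) {
  stopifnot(is.numeric(s_b), is.numeric(s_d), is.numeric(delta), is.numeric(mu),
            length(s_b) == 1L, length(s_d) == 1L, length(delta) == 1L,
            length(mu) == 1L)
  if (!(delta > 0 && delta < 1)) stop("delta must lie in (0, 1)")
  if (!(mu > 0 && mu < 1)) stop("mu must lie in (0, 1)")
  if (s_d < 0) stop("s_d must be >= 0")
  if (!(s_b > delta)) stop("s_b must exceed delta (so s_r = s_b - delta > 0)")
  if (!(mu < delta)) stop("mu must be smaller than delta")
  structure(
    list(s_b = s_b, s_d = s_d, delta = delta, mu = mu,
         s_r = s_b - delta,
         N_neut = if (s_d > 0) 1 / s_d else Inf,
         N_mut = 1 / mu),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Environmental-change model parameters\n")
  cat(sprintf("  s_b = %g  s_d = %g  delta = %g  mu = %g\n",
              x$s_b, x$s_d, x$delta, x$mu))
  cat(sprintf("  derived: s_r = %g  N_neut = %g  N_mut = %g\n",
              x$s_r, x$N_neut, x$N_mut))
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  stop("'params' must be a model_params object; see model_params()")
}
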