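# Independent Monte-Carlo oracle for the establishment probability:
# vectorized branching lineages with Poisson(1 + s) offspring, started from
# a single copy; a lineage counts as established once it reaches `cap`
# copies (for the s values used, dying after that point is astronomically
# unlikely).
branching_establishment_fraction <- function(s, reps, cap = 2000L,
                                             max_gen = 5000L) {
  n <- rep(1, reps)
  for (g in seq_len(max_gen)) {
    active <- which(n > 0 & n < cap)
    if (!length(active)) break
    n[active] <- stats::rpois(length(active), (1 + s) * n[active])
  }
  mean(n >= cap)
}

default_params <- function() model_params()

fig2_parameter_sets <- function() {
  list(
    model_params(),                    # defaults
    model_params(s_b = 0.011),         # small net benefit, s_r = 0.001
    model_params(s_b = 0.5),           # large benefit
    model_params(mu = 1e-6),           # rare mutation
    model_params(mu = 1e-4),           # common mutation
    model_params(s_d = 0.1)            # strongly deleterious before change
  )
}
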