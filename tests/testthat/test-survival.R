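test_that("conditional survival reduces correctly at the endpoints of p", {
  params <- model_params()
  # p = 0: de-novo-only expression
  pi_sr <- establishment_prob(params$s_r)
  expect_equal(survival_given_p(0, 1000, params),
               1 - exp(-1000 * pi_sr * params$mu / params$delta))
  # p = 1 at small net benefit: complement of the x^N extinction probability
  p11 <- model_params(s_b = 0.011)  # s_r = 0.001
  x <- 1 - establishment_prob(0.001)
  expect_equal(survival_given_p(1, 500, p11), 1 - x^500, tolerance = 0.005)
  # vanishing mutation supply and no standing copies: extinction certain
  tiny_mu <- model_params(mu = 1e-12)
  expect_lt(survival_given_p(0, 1000, tiny_mu), 1e-6)
})

test_that("conditional survival is strictly increasing in p", {
  params <- model_params()
  p <- seq(0, 1, by = 0.05)
  for (N in c(10, 500, 1e4)) {
    v <- survival_given_p(p, N, params)
    expect_true(all(diff(v) >= 0))
    # strictly increasing wherever not saturated at 1 in double precision
    expect_true(all(diff(v[v < 1 - 1e-12]) > 0))
  }
})

test_that("closed form and quadrature marginals agree to 1e-6 across the parameter grid", {
  Ns <- c(10, 30, 100, 300, 1000, 3000, 1e4)
  for (params in fig2_parameter_sets()) {
    gap <- abs(survival_probability(Ns, params) -
                 survival_probability_quadrature(Ns, params))
    expect_lt(max(gap), 1e-6,
              label = sprintf("s_b=%g mu=%g s_d=%g", params$s_b, params$mu,
                              params$s_d))
  }
})

test_that("marginal survival is non-decreasing in s_b and in mu at fixed N", {
  for (N in c(100, 1000, 1e4)) {
    by_sb <- vapply(c(0.02, 0.05, 0.1, 0.3), function(sb)
      survival_probability(N, model_params(s_b = sb)), numeric(1))
    expect_true(all(diff(by_sb) >= -1e-12))
    by_mu <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3), function(mu)
      survival_probability(N, model_params(mu = mu)), numeric(1))
    expect_true(all(diff(by_mu) >= -1e-12))
  }
})

test_that("decomposition identity holds and components bracket the total", {
  params <- model_params()
  for (N in c(10, 100, 1000, 1e4, 1e5, 1e6)) {
    d <- survival_components(N, params)
    expect_identical(d$p_total, d$p_stand + (1 - d$p_stand) * d$p_de_novo)
    expect_gte(d$p_total, max(d$p_stand, d$p_de_novo))
    expect_equal(d$p_de_novo, survival_given_p(0, N, params))
    expect_true(all(unlist(d[c("p_stand", "p_de_novo", "p_total",
                               "p_closed_form")]) >= 0))
    expect_true(all(unlist(d[c("p_stand", "p_de_novo", "p_total",
                               "p_closed_form")]) <= 1))
    # composed total tracks the closed-form marginal when mu << delta
    expect_lt(abs(d$p_total - d$p_closed_form), 0.01)
  }
})

test_that("standing variation dominates at small N; de novo takes over near N_mut", {
  params <- model_params()
  small <- survival_components(30, params)
  expect_gt(small$p_stand, small$p_de_novo)
  near_mut <- survival_components(params$N_mut, params)
  expect_gt(near_mut$p_de_novo, 0.95)
})

test_that("restricted survival: no restriction reproduces the marginal", {
  params <- model_params()
  for (N in c(50, 1000)) {
    expect_equal(survival_restricted(N, params, p_max = 1),
                 survival_probability_quadrature(N, params),
                 tolerance = 1e-9)
  }
})

test_that("rescue-only restriction (p < delta/s_b) makes survival monotone in N", {
  params <- model_params()
  Ns <- exp(seq(log(10), log(1e4), length.out = 15))
  curve <- survival_restricted(Ns, params, p_max = params$delta / params$s_b)
  expect_true(all(diff(curve) >= -1e-9))
})

test_that("conditioning on low frequencies cannot increase survival", {
  params <- model_params(s_d = 1e-9)  # effectively neutral before the change
  for (N in c(100, 1000)) {
    expect_lte(survival_restricted(N, params, p_max = 0.5),
               survival_probability_quadrature(N, params) + 1e-9)
  }
})

test_that("degenerate conditioning is reported, not silently computed", {
  params <- model_params(s_d = 0.1)
  # at large N essentially all Wright mass sits at p < 1e-300 scale cuts
  expect_error(survival_restricted(5000, params, p_max = 1e-300),
               "degenerate conditioning")
})
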