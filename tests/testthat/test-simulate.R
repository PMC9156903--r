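test_that("no allele and no mutation means certain extinction", {
  params <- model_params()
  set.seed(1)
  for (i in 1:5) {
    out <- simulate_branching(200, params, sim_config(), p_init = 0,
                              mu_off = TRUE)
    expect_false(out$survived)
    expect_false(out$censored)
    expect_equal(out$final_L + out$final_M, 0)
  }
})

test_that("mutation step conserves the offspring total", {
  set.seed(5)
  for (i in 1:200) {
    L <- rpois(1, 500)
    M <- rpois(1, 50)
    counts <- rescuedip:::mutate_offspring(L, M, 0.05)
    expect_identical(sum(counts), L + M)
    expect_true(all(counts >= 0))
  }
})

test_that("survival outcome implies the lineage reached the threshold", {
  params <- model_params()
  cfg <- sim_config(threshold = 100)
  set.seed(42)
  hits <- 0
  for (i in 1:20) {
    out <- simulate_branching(500, params, cfg, p_init = 0.5)
    if (out$survived) {
      hits <- hits + 1
      expect_gte(out$final_M, 100)
    } else {
      expect_equal(out$final_L + out$final_M, 0)
    }
  }
  expect_gt(hits, 0)
})

test_that("hitting the generation cap is censored, distinct from both outcomes", {
  params <- model_params()
  set.seed(8)
  out <- simulate_branching(1000, params, sim_config(max_generations = 1),
                            p_init = 0.1)
  expect_true(out$censored)
  expect_false(out$survived)
})

test_that("replicate estimates are reproducible from the root seed", {
  params <- model_params()
  cfg <- sim_config(seed = 77, replicates = 40)
  a <- estimate_survival(300, params, cfg)
  b <- estimate_survival(300, params, cfg)
  expect_identical(a$fraction, b$fraction)
  expect_identical(a$survived, b$survived)
  cfg1 <- sim_config(seed = 77, replicates = 1)
  one <- estimate_survival(300, params, cfg1)
  expect_true(one$fraction %in% c(0, 1))
})

test_that("simulated survival matches the closed form at N = 1000", {
  params <- model_params()
  est <- estimate_survival(1000, params, sim_config(seed = 101, replicates = 800))
  analytic <- survival_probability(1000, params)
  se <- sqrt(analytic * (1 - analytic) / (est$replicates - est$censored))
  expect_lt(abs(est$fraction - analytic), 3 * se)
})

test_that("doubling the establishment threshold leaves the estimate unchanged within noise", {
  params <- model_params()
  a <- estimate_survival(1000, params, sim_config(seed = 55, replicates = 400,
                                                  threshold = 2000))
  b <- estimate_survival(1000, params, sim_config(seed = 56, replicates = 400,
                                                  threshold = 4000))
  se <- sqrt(a$fraction * (1 - a$fraction) / 400)
  expect_lt(abs(a$fraction - b$fraction), 3 * sqrt(2) * se)
})

test_that("Ricker: wild type collapses with the decaying capacity; criterion respected", {
  params <- model_params(mu = 1e-12)  # mutation supply effectively absent
  set.seed(31)
  out <- simulate_ricker(ricker_params(100), params, sim_config(), p_init = 0)
  expect_false(out$survived)
  expect_equal(out$final_L + out$final_M, 0)
  # with abundant standing variation the lineage establishes at min(threshold, K0/2)
  params2 <- model_params()
  set.seed(32)
  est <- 0
  for (i in 1:10) {
    o <- simulate_ricker(ricker_params(200), params2, sim_config(), p_init = 0.4)
    if (o$survived) {
      est <- est + 1
      expect_gte(o$final_M, min(2000, ceiling(200 / 2)))
    }
  }
  expect_gt(est, 0)
})

test_that("Ricker survival vs K0 stays non-monotonic under density regulation", {
  # With strong density feedback (large r) late de novo mutants get mean
  # offspring near exp(r) once the wild type has collapsed, which inflates
  # rescue and flattens the dip; at gentler growth (r = 0.1) the
  # non-monotonicity of survival in the initial capacity is unmistakable.
  params <- model_params()
  cfg <- sim_config(seed = 500, replicates = 150)
  fr <- vapply(c(100, 1000, 10000), function(K0)
    estimate_survival(K0, params, cfg, model = "ricker",
                      ricker = ricker_params(K0, r = 0.1))$fraction,
    numeric(1))
  # dip at intermediate capacity: middle estimate below both ends
  expect_lt(fr[2], fr[1])
  expect_lt(fr[2], fr[3])
})
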