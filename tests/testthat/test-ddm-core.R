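test_that("drift rate is the stated linear map of morph index", {
  p0 <- ddm_params(0.3, 0, a = 1, z_r = 0.5, t0 = 0.2)
  expect_equal(drift_rate(p0, 1), 0.3)   # slope-free case returns intercept
  expect_equal(drift_rate(p0, 15), 0.3)

  p <- ddm_params(-0.8, 0.1, a = 1, z_r = 0.5, t0 = 0.2)
  expect_equal(drift_rate(p, 8), 0)      # drift vanishes at the indifference point
  p2 <- ddm_params(-0.75, 0.1, a = 1, z_r = 0.5, t0 = 0.2)
  expect_equal(drift_rate(p2, 10), 0.25)

  # exact linearity: second difference over s is 0
  v <- drift_rate(p, 1:15)
  expect_equal(diff(v, differences = 2), rep(0, 13))

  expect_error(drift_rate(p, 0), "1..15")
  expect_error(drift_rate(p, 16), "1..15")
})

test_that("indifference point is -v_int/v_slope, flagged when out of range", {
  p <- ddm_params(-0.8, 0.1, a = 1, z_r = 0.5, t0 = 0.2)
  si <- indifference_point(p)
  expect_equal(as.numeric(si), 8.0)
  expect_false(attr(si, "out_of_range"))
  expect_equal(drift_rate(p, 8), 0)

  p2 <- ddm_params(0.2, 0.1, a = 1, z_r = 0.5, t0 = 0.2)
  si2 <- indifference_point(p2)
  expect_equal(as.numeric(si2), -2.0)
  expect_true(attr(si2, "out_of_range"))

  p3 <- ddm_params(0.2, 0, a = 1, z_r = 0.5, t0 = 0.2)
  expect_error(indifference_point(p3), "undefined")
})

test_that("choice probability matches the absorption formula and its limits", {
  # zero drift: probability equals the relative starting point
  p <- ddm_params(-0.8, 0.1, a = 1.3, z_r = 0.5, t0 = 0.2)
  expect_equal(choice_probability(p, 8), 0.5)
  p3 <- ddm_params(-0.8, 0.1, a = 1.3, z_r = 0.3, t0 = 0.2)
  expect_equal(choice_probability(p3, 8), 0.3)

  # v = 1, a = 2, z_r = 0.5: frozen value checked against a 10^6-path
  # Euler Monte Carlo run (observed 0.88046, binomial SE 3.2e-4)
  p4 <- ddm_params(1, 0, a = 2, z_r = 0.5, t0 = 0.2)
  expect_equal(choice_probability(p4, 5), 0.8807971, tolerance = 1e-6)

  # continuity across the v = 0 switch
  eps <- 1e-9
  pa <- choice_probability(ddm_params(eps, 0, a = 1.3, z_r = 0.3, t0 = 0), 8)
  expect_equal(pa, 0.3, tolerance = 1e-6)
})

test_that("choice probabilities and bias are invariant to common rescaling", {
  for (c_ in c(0.1, 3)) {
    p1 <- ddm_params(-0.9, 0.12, a = 1.2, z_r = 0.45, t0 = 0.2, sigma = 1)
    p2 <- ddm_params(-0.9 * c_, 0.12 * c_, a = 1.2 * c_, z_r = 0.45,
                     t0 = 0.2, sigma = c_)
    expect_equal(choice_probability(p1, 1:15), choice_probability(p2, 1:15),
                 tolerance = 1e-12)
    expect_equal(as.numeric(indifference_point(p1)),
                 as.numeric(indifference_point(p2)))
  }
})

test_that("first-passage density is zero before t0 and integrates to 1", {
  p <- ref_observer()
  expect_equal(wfpt_density(c(0.1, 0.25), p, 8, "angry"), c(0, 0))
  expect_error(wfpt_density(NA_real_, p, 8, "angry"), "non-finite")

  # normalization and boundary-split over a parameter grid (quadrature)
  grid <- expand.grid(v_int = c(-1.5, 0.4), v_slope = c(0, 0.25),
                      a = c(0.8, 1.6), z_r = c(0.3, 0.5), s = c(2L, 12L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pp <- ddm_params(g$v_int, g$v_slope, g$a, g$z_r, t0 = 0.2)
    ia <- integrate(function(t) wfpt_density(t, pp, g$s, "angry"),
                    0.2, Inf, rel.tol = 1e-8)$value
    ih <- integrate(function(t) wfpt_density(t, pp, g$s, "happy"),
                    0.2, Inf, rel.tol = 1e-8)$value
    expect_equal(ia + ih, 1, tolerance = 1e-5)
    expect_equal(ia, choice_probability(pp, g$s), tolerance = 1e-5)
  }
})

test_that("simulated trials respect t0, the seed, and the analytic choice law", {
  p <- ref_observer()
  tr <- simulate_trials(p, full_morph_sequence(), seed = 31)
  expect_true(all(tr$rt >= p$t0))
  expect_identical(tr, simulate_trials(p, full_morph_sequence(), seed = 31))

  # empirical angry fraction within 3 binomial SDs of the analytic value,
  # across 20 parameter/stimulus combinations
  set.seed(77)
  n <- 3000
  for (k in 1:20) {
    pp <- ddm_params(runif(1, -2, 1), runif(1, 0, 0.35),
                     a = runif(1, 0.8, 2), z_r = runif(1, 0.3, 0.7),
                     t0 = 0.2)
    s <- sample(1:15, 1)
    tr <- simulate_trials(pp, rep(s, n), seed = 1000 + k)
    pa <- choice_probability(pp, s)
    se <- sqrt(pa * (1 - pa) / n)
    expect_lt(abs(mean(tr$choice == "angry") - pa), 3 * se + 1e-3)
  }

  # zero-drift symmetry at the (rounded) indifference point
  tr8 <- simulate_trials(ref_observer(), rep(8L, 4000), seed = 9)
  expect_lt(abs(mean(tr8$choice == "angry") - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("negative log-likelihood follows its definition and prefers truth", {
  p <- ref_observer()
  expect_warning(nll0 <- negative_log_likelihood(p, toy_trials()[0, ]),
                 "empty")
  expect_equal(nll0, 0)

  one <- data.frame(participant = "x", run = 1L, s = 8L, choice = "angry",
                    rt = 0.6)
  expect_equal(negative_log_likelihood(p, one),
               -log(wfpt_density(0.6, p, 8, "angry")))

  # truth beats a +50 ms t0 perturbation on large simulated sets
  for (k in 1:20) {
    tr <- simulate_trials(p, rep(1:15, 67), seed = 400 + k)  # ~10^3 trials
    p_pert <- ddm_params(p$v_int, p$v_slope, p$a, p$z_r, p$t0 + 0.05)
    expect_lte(negative_log_likelihood(p, tr),
               negative_log_likelihood(p_pert, tr))
  }
})
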