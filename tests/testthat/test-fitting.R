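test_that("fitting recovers a simulated observer and respects the t0 bound", {
  # the reference observer of the model description: v_int = -0.96,
  # v_slope = 0.12 (bias exactly 8), fitted on the full 450-trial schedule.
  # Tolerance derives from the repeated-seed recovery distribution of this
  # (shallow) observer: per-seed ML errors have SD ~0.75, so the mean over
  # 8 seeds is tested within 2.5 SEM ~ 0.66, and the sensitivity sign must
  # be recovered every time.
  p <- ddm_params(-0.96, 0.12, a = 1.2, z_r = 0.5, t0 = 0.25)
  errs <- vapply(1:8, function(k) {
    tr <- simulate_trials(p, full_morph_sequence(), seed = 1000 + k)
    f <- fit_participant(tr, n_starts = 5, seed = 2000 + k)
    expect_true(f$converged)
    expect_lte(f$params$t0, min(tr$rt))
    expect_gt(f$sensitivity, 0)
    f$perceptual_bias - 8
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.66)

  # a steeper observer at generator-default sensitivity: per-seed ML errors
  # have SD ~0.25, so the mean over 6 seeds is tested within ~3 SEM
  p2 <- ref_observer(bias = 7.5)
  errs2 <- vapply(1:6, function(k) {
    tr2 <- simulate_trials(p2, full_morph_sequence(), seed = 4 + k)
    fit_participant(tr2, n_starts = 5, seed = 60 + k)$perceptual_bias - 7.5
  }, numeric(1))
  expect_lt(abs(mean(errs2)), 0.3)
})

test_that("degenerate one-response data are flagged, not silently fitted", {
  tr <- data.frame(participant = "p", run = 1L, s = rep(1:15, 2),
                   choice = "angry", rt = runif(30, 0.3, 0.8))
  f <- fit_participant(tr, n_starts = 2, seed = 1)
  expect_true(f$degenerate)
  expect_false(f$converged)
})

test_that("refitting with a different start set leaves the optimum unchanged", {
  tr <- simulate_trials(ref_observer(), full_morph_sequence(), seed = 21)
  f1 <- fit_participant(tr, n_starts = 5, seed = 100)
  f2 <- fit_participant(tr, n_starts = 5, seed = 200)
  expect_lt(abs(f1$nll - f2$nll), 1e-3)
})

test_that("bias recovery is accurate across observers and improves with data", {
  # median absolute s_indiff error < 0.3 and rank correlation of
  # sensitivities > 0.8, over 50 observers spanning biases 6.5..9.5
  truth <- seq(6.5, 9.5, length.out = 50)
  set.seed(1)
  vs_true <- rlnorm(50, log(0.3), 0.2)
  fit_err <- function(n_trials, seed_off) {
    vapply(1:50, function(i) {
      p <- ddm_params(-truth[i] * vs_true[i], vs_true[i], a = 1.2,
                      z_r = 0.5, t0 = 0.25)
      sched <- rep(1:15, n_trials / 15)
      tr <- simulate_trials(p, sched, seed = seed_off + i)
      f <- fit_participant(tr, n_starts = 5, seed = seed_off + 500 + i)
      c(f$perceptual_bias - truth[i], f$sensitivity)
    }, numeric(2))
  }
  r450 <- fit_err(450, 3000)
  expect_lt(median(abs(r450[1, ])), 0.3)
  expect_gt(cor(vs_true, r450[2, ], method = "spearman"), 0.8)

  # monotone data-size consistency: mean error shrinks from 150 to 450 trials
  r150 <- fit_err(150, 7000)
  expect_lt(mean(abs(r450[1, ])), mean(abs(r150[1, ])))
})

test_that("quantile-probability summaries match a sort-and-count oracle", {
  tr <- toy_trials()
  qp <- qp_summary(tr, min_n = 2L)
  # proportions per morph sum to 1
  agg <- as.vector(tapply(qp$prop, qp$s, sum))
  expect_equal(agg, rep(1, length(agg)))

  # all-angry toy input: angry proportion 1 at every present morph
  allang <- transform(tr, choice = "angry")
  qa <- qp_summary(allang, min_n = 1L)
  expect_true(all(qa$prop[qa$response == "angry"] == 1))

  # brute-force quantile oracle: sort and interpolate by hand (type-7 rule)
  hand_quantile <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  rts <- tr$rt[tr$s == 8 & tr$choice == "angry"]
  row <- qp[qp$s == 8 & qp$response == "angry", ]
  expect_equal(unname(unlist(row[paste0("q", c(10, 30, 50, 70, 90))])),
               vapply(c(.1, .3, .5, .7, .9), hand_quantile, numeric(1), x = rts))
  # quantiles nondecreasing
  qmat <- as.matrix(qp[qp$n >= 2, paste0("q", c(10, 30, 50, 70, 90))])
  expect_true(all(apply(qmat, 1, function(r) all(diff(r) >= 0))))

  # sparse cells are flagged and suppressed
  qs <- qp_summary(tr, min_n = 5L)
  expect_true(all(is.na(qs$q50)))
  expect_gt(length(attr(qs, "flagged")), 0)
})
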