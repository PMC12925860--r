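brute_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

test_that("metric-clinical correlations match the covariance formula", {
  set.seed(3)
  coh <- data.frame(sensitivity = c(0.1, 0.3, 0.2, 0.5, 0.4),
                    perceptual_bias = c(8.1, 7.4, 7.9, 8.6, 8.0),
                    scared_child = c(10, 30, 22, 41, 18),
                    scared_parent = c(12, 25, 30, 35, 20),
                    ari_child = c(2, 5, 4, 7, 3),
                    ari_parent = c(1, 6, 5, 8, 2))
  tab <- metric_clinical_correlations(coh)
  expect_equal(nrow(tab), 8L)                 # 2 metrics x 4 measures
  expect_equal(unique(tab$n_family), 8L)
  expect_equal(tab$df, tab$n - 2L)
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$r[i],
                 brute_pearson(coh[[tab$metric[i]]], coh[[tab$measure[i]]]),
                 tolerance = 1e-10)
  expect_equal(tab$p_adj, pmin(1, tab$p_raw * 8))

  # self-correlation r = 1; family of one keeps p_adj = p_raw
  coh$self <- coh$sensitivity
  t1 <- metric_clinical_correlations(coh, metrics = "sensitivity",
                                     measures = "self")
  expect_equal(t1$r, 1)
  t2 <- metric_clinical_correlations(coh, metrics = "sensitivity",
                                     measures = "scared_child")
  expect_equal(t2$p_adj, t2$p_raw)

  # constant column flagged, not crashed
  coh$flat <- 5
  tf <- metric_clinical_correlations(coh, metrics = "sensitivity",
                                     measures = "flat")
  expect_true(is.na(tf$r))
  expect_equal(tf$flag, "constant")
})

test_that("one-way ANOVA equals the hand sums-of-squares decomposition", {
  v <- c(3.1, 2.9, 3.4, 4.0, 4.4, 4.1, 5.2, 5.0, 4.8, 5.1)
  g <- rep(c("a", "b", "c"), c(3, 3, 4))
  res <- oneway_anova(v, g)
  # brute force
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  Fb <- (ssb / 2) / (ssw / 7)
  expect_equal(res$F, Fb, tolerance = 1e-10)
  expect_equal(res$df1, 2L); expect_equal(res$df2, 7L)
  expect_equal(res$p, pf(Fb, 2, 7, lower.tail = FALSE), tolerance = 1e-10)

  # two groups: F = t^2 of the pooled two-sample t
  v2 <- v[1:6]; g2 <- g[1:6]
  tt <- t.test(v2[g2 == "a"], v2[g2 == "b"], var.equal = TRUE)
  expect_equal(oneway_anova(v2, g2)$F, unname(tt$statistic)^2,
               tolerance = 1e-10)

  # invariance to shift and scale
  expect_equal(oneway_anova(v + 100, g)$F, res$F, tolerance = 1e-9)
  expect_equal(oneway_anova(v * 7, g)$F, res$F, tolerance = 1e-9)

  # degenerate and error cases
  expect_true(oneway_anova(rep(2, 6), rep(c("a", "b"), 3))$degenerate)
  expect_error(oneway_anova(v, rep(c("a", "b", "solo"), c(5, 4, 1))), "solo")
})

test_that("pairwise t tests pool the within-group SD and Bonferroni-correct", {
  set.seed(8)
  v <- c(rnorm(5, 0), rnorm(6, 1), rnorm(5, 2), rnorm(4, 0.5))
  g <- rep(c("w", "x", "y", "z"), c(5, 6, 5, 4))
  tab <- pairwise_t_bonferroni(v, g)
  expect_equal(nrow(tab), 6L)                       # 4 groups -> 6 pairs
  expect_equal(tab$p_adj, pmin(1, tab$p_raw * 6))
  # brute-force pooled-SD t for one pair
  k <- 4; N <- length(v)
  sp2 <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (N - k)
  i <- which(tab$group1 == "w" & tab$group2 == "y")
  tb <- (mean(v[g == "w"]) - mean(v[g == "y"])) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(tab$t[i], tb, tolerance = 1e-10)
  expect_equal(tab$df[i], N - k)
  # agreement with the standard implementation's p values
  ref <- pairwise.t.test(v, g, p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(tab$p_raw[i], ref$p.value["y", "w"], tolerance = 1e-10)

  # identical groups give t = 0
  vv <- c(1, 2, 3, 1, 2, 3); gg <- rep(c("a", "b"), each = 3)
  expect_equal(pairwise_t_bonferroni(vv, gg)$t, 0)
})

test_that("the age-sensitivity replication excludes healthy participants", {
  coh <- data.frame(age = c(8, 10, 12, 14, 16, 18),
                    diagnosis = c("DMDD", "ADHD", "Anxiety", "DMDD",
                                  "Healthy", "Healthy"))
  coh$sensitivity <- 0.01 * coh$age + 0.1   # exact linear in age
  res <- replicate_age_sensitivity(coh)
  expect_equal(res$r, 1)
  expect_equal(res$n, 4L)                    # healthy rows excluded
  expect_equal(res$df, 2L)

  # toy 6-row table against the brute-force formula (patients only)
  coh$sensitivity <- c(0.3, 0.1, 0.4, 0.2, 0.9, 0.9)
  pat <- coh[coh$diagnosis != "Healthy", ]
  expect_equal(replicate_age_sensitivity(coh)$r,
               brute_pearson(pat$age, pat$sensitivity), tolerance = 1e-10)

  expect_error(replicate_age_sensitivity(coh[c(1, 2, 5, 6), ]), "fewer than 3")
})
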