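#' Bonferroni-corrected correlations between model metrics and clinical scores
#'
#' Pearson correlations of each fitted metric (by default sensitivity and
#' perceptual bias) with each clinical measure (child- and parent-rated
#' anxiety and irritability totals), pairwise-complete, with Bonferroni
#' adjustment over all cells of the emitted table. The family size is always
#' reported alongside the adjusted p value.
#'
#' @param cohort Cohort data frame (one row per participant).
#' @param metrics Metric column names.
#' @param measures Clinical column names.
#' @return Data frame: `metric`, `measure`, `r`, `n`, `df`, `p_raw`, `p_adj`,
#'   `n_family`; undefined correlations (constant column) flagged as `NA`
#'   with `flag = "constant"`.
#' @export
metric_clinical_correlations <- function(cohort,
    metrics = c("sensitivity", "perceptual_bias"),
    measures = c("scared_child", "scared_parent", "ari_child", "ari_parent")) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(c(metrics, measures), names(cohort))
  if (length(miss)) stop("cohort missing column(s): ",
                         paste(miss, collapse = ", "))
  cells <- expand.grid(metric = metrics, measure = measures,
                       stringsAsFactors = FALSE)
  n_family <- nrow(cells)
  res <- lapply(seq_len(n_family), function(i) {
    x <- cohort[[cells$metric[i]]]; y <- cohort[[cells$measure[i]]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 3) stop("fewer than 3 complete pairs for ",
                    cells$metric[i], " x ", cells$measure[i])
    flag <- ""
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      r <- NA_real_; p <- NA_real_; flag <- "constant"
    } else {
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(metric = cells$metric[i], measure = cells$measure[i],
               r = r, n = n, df = n - 2L, p_raw = p,
               p_adj = pmin(1, p * n_family), n_family = n_family,
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' One-way analysis of variance
#'
#' Classical between/within sums-of-squares decomposition,
#' `df1 = k - 1`, `df2 = N - k`, computed through [stats::lm()]/[stats::anova()].
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (>= 2 groups, each with >= 2 observations).
#' @return List `F`, `df1`, `df2`, `p`, `degenerate` (all values identical:
#'   F is 0/0).
#' @export
oneway_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- complete.cases(values, groups)
  values <- values[ok]; groups <- factor(groups[ok])
  tab <- table(groups)
  if (length(tab) < 2L) stop("at least 2 groups required")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (sd(values) == 0)
    return(list(F = NA_real_, df1 = length(tab) - 1L,
                df2 = length(values) - length(tab), p = NA_real_,
                degenerate = TRUE))
  a <- stats::anova(stats::lm(values ~ groups))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1], degenerate = FALSE)
}

#' Bonferroni-corrected post hoc pairwise t tests
#'
#' All `k(k-1)/2` pairwise comparisons using the pooled within-group SD over
#' all groups (classical post hoc convention; `df = N - k`), Bonferroni
#' corrected over the number of pairs. `welch = TRUE` instead runs per-pair
#' Welch tests (no pooling).
#'
#' @inheritParams oneway_anova
#' @param welch Use Welch (unequal-variance) per-pair tests?
#' @return Data frame: `group1`, `group2`, `t`, `df`, `p_raw`, `p_adj`,
#'   `n_pairs`.
#' @export
pairwise_t_bonferroni <- function(values, groups, welch = FALSE) {
  stopifnot(length(values) == length(groups))
  ok <- complete.cases(values, groups)
  values <- values[ok]; groups <- factor(groups[ok])
  tab <- table(groups)
  if (length(tab) < 2L) stop("at least 2 groups required")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  lev <- names(tab)
  k <- length(lev)
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  N <- length(values)
  # pooled within-group SD over ALL groups
  sp2 <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / (N - k)
  res <- lapply(seq_len(n_pairs), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    v1 <- values[groups == g1]; v2 <- values[groups == g2]
    if (welch) {
      tt <- stats::t.test(v1, v2, var.equal = FALSE)
      tval <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    } else {
      se <- sqrt(sp2 * (1 / length(v1) + 1 / length(v2)))
      tval <- (mean(v1) - mean(v2)) / se
      df <- N - k
      p <- 2 * pt(-abs(tval), df)
    }
    data.frame(group1 = g1, group2 = g2, t = tval, df = df, p_raw = p,
               p_adj = min(1, p * n_pairs), n_pairs = n_pairs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Age–sensitivity correlation in the patient subsample
#'
#' Pearson correlation between age and diffusion-model sensitivity computed
#' on participants with a primary emotional/behavioural diagnosis — healthy
#' participants are excluded, mirroring the independent replication of
#' age-associated sensitivity gains.
#'
#' @param cohort Cohort data frame with `age`, `sensitivity`, `diagnosis`.
#' @param healthy_label Diagnosis value marking healthy volunteers.
#' @return List `r`, `n`, `df`, `p_raw`, `p_adj` (single-test family:
#'   `p_adj = p_raw`), `n_family = 1`.
#' @export
replicate_age_sensitivity <- function(cohort, healthy_label = "Healthy") {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(c("age", "sensitivity", "diagnosis"), names(cohort))
  if (length(miss)) stop("cohort missing column(s): ",
                         paste(miss, collapse = ", "))
  pat <- cohort[cohort$diagnosis != healthy_label, ]
  pat <- pat[complete.cases(pat$age, pat$sensitivity), ]
  if (nrow(pat) < 3L) stop("fewer than 3 patients with complete data")
  ct <- cor.test(pat$age, pat$sensitivity, method = "pearson")
  list(r = unname(ct$estimate), n = nrow(pat), df = nrow(pat) - 2L,
       p_raw = ct$p.value, p_adj = ct$p.value, n_family = 1L)
}
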