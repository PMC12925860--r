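#' Generate a face-emotion labeling task schedule
#'
#' Emulates the scanner task: 15 morphs x 30 presentations plus 90
#' fixation-only events, 540 events over 4 runs (stimulus events split
#' 113/113/112/112, fixation 23/23/22/22), pseudo-random order per seed.
#' Each run begins and ends with a 10 s fixation period. Inter-trial
#' intervals are drawn from a shifted exponential with a 500 ms minimum,
#' with the mean calibrated per run so the expected run duration is about
#' 421 s (stimulus events occupy 150 ms face + 250 ms mask before their ITI).
#'
#' @param seed Integer seed (required).
#' @return A `task_schedule`: list with `events` (data frame `run`, `type`,
#'   `s`, `onset`, `iti`) and `run_durations` (seconds).
#' @export
generate_task_schedule <- function(seed) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  stim_per_run <- c(113L, 113L, 112L, 112L)
  fix_per_run <- c(23L, 23L, 22L, 22L)
  morphs <- sample(rep(1:15, 30))          # 450 stimulus morphs, shuffled
  stim_dur <- 0.150 + 0.250                # face + white-noise mask
  lead_trail <- 10                         # fixation at run start and end
  target_run <- 421
  events <- list()
  run_durations <- numeric(4)
  offset <- 0L
  for (r in 1:4) {
    ns <- stim_per_run[r]; nf <- fix_per_run[r]
    s_run <- morphs[(offset + 1):(offset + ns)]
    offset <- offset + ns
    type <- sample(c(rep("stimulus", ns), rep("fixation", nf)))
    s <- integer(ns + nf); s[type == "stimulus"] <- s_run
    s[type == "fixation"] <- NA_integer_
    # mean ITI so that lead + stimuli + sum(ITI) + trail has expectation 421 s
    mean_iti <- (target_run - 2 * lead_trail - ns * stim_dur) / (ns + nf)
    iti <- 0.5 + rexp(ns + nf, rate = 1 / (mean_iti - 0.5))
    onset <- numeric(ns + nf)
    t <- lead_trail
    for (i in seq_along(type)) {
      onset[i] <- t
      t <- t + (if (type[i] == "stimulus") stim_dur else 0) + iti[i]
    }
    run_durations[r] <- t + lead_trail
    events[[r]] <- data.frame(run = r, type = type, s = s,
                              onset = onset, iti = iti,
                              stringsAsFactors = FALSE)
  }
  structure(list(events = do.call(rbind, events),
                 run_durations = run_durations, seed = seed),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  ev <- x$events
  cat(sprintf("Task schedule: %d events (%d stimulus, %d fixation) over 4 runs\n",
              nrow(ev), sum(ev$type == "stimulus"), sum(ev$type == "fixation")))
  cat(sprintf("  run durations (s): %s; min ITI %.3f s\n",
              paste(sprintf("%.1f", x$run_durations), collapse = ", "),
              min(ev$iti)))
  invisible(x)
}

#' Specification of a diagnostic group of diffusion observers
#'
#' Group-level distribution from which observers are drawn: the perceptual
#' bias (`s_indiff`) is normal with the given mean and SD; sensitivity
#' (`v_slope`) is lognormal; boundary separation, starting point and
#' non-decision time are normal, truncated to their admissible ranges. The
#' bias moments for the DMDD-like and control-like groups follow the
#' published group statistics; the remaining distributions are generator
#' defaults (not published quantities), exposed here for configuration.
#'
#' @param name Diagnosis label.
#' @param n Number of observers (> 0).
#' @param bias_mean,bias_sd Moments of the true indifference point (morph
#'   units; SD >= 0).
#' @param vslope_meanlog,vslope_sdlog Lognormal parameters for sensitivity.
#' @param a_mean,a_sd Boundary separation moments (truncated at 0.4).
#' @param zr_mean,zr_sd Relative starting point moments (clamped to
#'   (0.05, 0.95)).
#' @param t0_mean,t0_sd Non-decision time moments in seconds (truncated at
#'   0.1).
#' @return A `group_spec` list.
#' @export
group_spec <- function(name, n, bias_mean, bias_sd,
                       vslope_meanlog = log(0.3), vslope_sdlog = 0.2,
                       a_mean = 1.2, a_sd = 0.2,
                       zr_mean = 0.5, zr_sd = 0.05,
                       t0_mean = 0.25, t0_sd = 0.05) {
  if (!is.numeric(n) || n <= 0 || n != round(n)) stop("'n' must be a positive integer")
  if (bias_sd < 0 || a_sd < 0 || zr_sd < 0 || t0_sd < 0)
    stop("SDs must be >= 0")
  structure(list(name = name, n = as.integer(n), bias_mean = bias_mean,
                 bias_sd = bias_sd, vslope_meanlog = vslope_meanlog,
                 vslope_sdlog = vslope_sdlog, a_mean = a_mean, a_sd = a_sd,
                 zr_mean = zr_mean, zr_sd = zr_sd, t0_mean = t0_mean,
                 t0_sd = t0_sd),
            class = "group_spec")
}

#' Default diagnostic group specifications
#'
#' DMDD-like and healthy-control-like groups use the published perceptual
#' bias moments (7.52 +/- 0.95 and 8.48 +/- 1.40 morph units at the
#' published group sizes, 27 and 24). The ADHD, anxiety and ODD groups (no
#' published bias moments) sit between the two at an intermediate spread.
#'
#' @return Named list of [group_spec] objects.
#' @export
default_group_specs <- function() {
  list(DMDD = group_spec("DMDD", 27, 7.52, 0.95),
       Healthy = group_spec("Healthy", 24, 8.48, 1.40),
       ADHD = group_spec("ADHD", 23, 8.2, 1.2),
       Anxiety = group_spec("Anxiety", 19, 8.2, 1.2),
       ODD = group_spec("ODD", 2, 8.2, 1.2))
}

#' Draw a group of diffusion observers
#'
#' For each observer, the true indifference point and the remaining
#' parameters are drawn per the group specification, and the drift intercept
#' is set as `v_int = -s_indiff * v_slope` so the drawn bias is exact by
#' construction. Identical seeds give identical cohorts.
#'
#' @param spec A [group_spec].
#' @param seed Integer seed (required).
#' @param id_prefix Prefix for participant identifiers.
#' @return Data frame: `participant`, `diagnosis`, `v_int`, `v_slope`, `a`,
#'   `z_r`, `t0`, `s_indiff_true`.
#' @export
generate_observer_group <- function(spec, seed, id_prefix = spec$name) {
  stopifnot(inherits(spec, "group_spec"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  n <- spec$n
  s_indiff <- rnorm(n, spec$bias_mean, spec$bias_sd)
  v_slope <- rlnorm(n, spec$vslope_meanlog, spec$vslope_sdlog)
  a <- pmax(rnorm(n, spec$a_mean, spec$a_sd), 0.4)
  z_r <- pmin(pmax(rnorm(n, spec$zr_mean, spec$zr_sd), 0.05), 0.95)
  t0 <- pmax(rnorm(n, spec$t0_mean, spec$t0_sd), 0.1)
  data.frame(participant = sprintf("%s_%02d", id_prefix, seq_len(n)),
             diagnosis = spec$name,
             v_int = -s_indiff * v_slope, v_slope = v_slope,
             a = a, z_r = z_r, t0 = t0, s_indiff_true = s_indiff,
             stringsAsFactors = FALSE)
}

# ---- questionnaire scoring ----------------------------------------------

#' Score an ARI response sheet
#'
#' Sums the 6 irritability items (each scored 0-2), total 0-12.
#'
#' @param items Numeric vector of 6 item responses in 0..2.
#' @return Total score.
#' @export
score_ari <- function(items) {
  if (length(items) != 6L) stop("ARI has 6 items")
  if (any(!items %in% 0:2)) stop("ARI items are scored 0, 1 or 2")
  sum(items)
}

#' Score a SCARED response sheet
#'
#' Sums the 41 anxiety items (each scored 0-2), total 0-82.
#'
#' @param items Numeric vector of 41 item responses in 0..2.
#' @return Total score.
#' @export
score_scared <- function(items) {
  if (length(items) != 41L) stop("SCARED has 41 items")
  if (any(!items %in% 0:2)) stop("SCARED items are scored 0, 1 or 2")
  sum(items)
}

# ---- copula calibration --------------------------------------------------

# P(u > h, u' > k) for standard bivariate normal with correlation r
binorm_upper <- function(h, k, r) {
  r <- min(max(r, -0.9999), 0.9999)
  if (abs(r) < 1e-12) return(pnorm(-h) * pnorm(-k))
  integrate(function(x) dnorm(x) * pnorm((r * x - k) / sqrt(1 - r^2)),
            lower = h, upper = Inf, rel.tol = 1e-10)$value
}

# covariance between two items discretised to {0,1,2} at equal-mass
# cutpoints, given latent correlation r (item means are exactly 1)
item_pair_cov <- function(r) {
  cuts <- qnorm(c(1 / 3, 2 / 3))
  e <- 0
  for (h in cuts) for (k in cuts) e <- e + binorm_upper(h, k, r)
  e - 1
}

# Pearson correlation between two instrument totals (mA and mB items, item
# loading lambda on the instrument factor) given factor correlation rho
total_score_corr <- function(rho, mA, mB, lambda) {
  cv <- mA * mB * item_pair_cov(lambda * rho)
  vA <- mA * (2 / 3) + mA * (mA - 1) * item_pair_cov(lambda)
  vB <- mB * (2 / 3) + mB * (mB - 1) * item_pair_cov(lambda)
  cv / sqrt(vA * vB)
}

# invert total_score_corr for rho: the latent factor correlation that yields
# the target total-score correlation after item discretisation
solve_factor_corr <- function(target, mA, mB, lambda) {
  if (target == 0) return(0)
  hi <- total_score_corr(0.999, mA, mB, lambda)
  if (abs(target) >= hi)
    stop(sprintf("target correlation %.3f unattainable (max %.3f at these item counts)",
                 target, hi))
  uniroot(function(rho) total_score_corr(rho, mA, mB, lambda) - target,
          interval = c(-0.999, 0.999), tol = 1e-9)$root
}

#' Generate a synthetic clinical cohort
#'
#' Draws child- and parent-rated anxiety (SCARED, 41 items scored 0-2, total
#' 0-82) and irritability (ARI, 6 items scored 0-2, total 0-12) through a
#' Gaussian copula: four latent instrument factors with a calibrated
#' correlation matrix, item latents loading `lambda` on their factor,
#' discretised at equal-mass cutpoints and summed. The factor correlations
#' are solved deterministically (numerical integration + root finding) so the
#' post-discretisation Pearson correlations between totals hit the targets —
#' by default the published cross-informant (anxiety 0.58, irritability
#' 0.56) and cross-measure (child 0.46, parent 0.50) values. Ages are
#' uniform on 8-22 years; primary diagnoses are sampled with the published
#' sample composition (27 DMDD / 23 ADHD / 19 Anxiety / 2 ODD / 24 Healthy
#' per 95).
#'
#' @param n Number of participants.
#' @param seed Integer seed (required).
#' @param targets Named list of total-score correlation targets:
#'   `anxiety_cross_informant`, `irritability_cross_informant`,
#'   `cross_measure_child`, `cross_measure_parent`, and
#'   `cross_measure_cross_informant` (the cells the publication does not
#'   print; default 0.40).
#' @param lambda Item loading on the instrument factor, in (0, 1).
#' @return Data frame: `participant`, `age`, `sex`, `diagnosis`,
#'   `scared_child`, `scared_parent`, `ari_child`, `ari_parent`; attribute
#'   `factor_corr` carries the calibrated latent matrix.
#' @export
generate_clinical_cohort <- function(n, seed,
    targets = list(anxiety_cross_informant = 0.58,
                   irritability_cross_informant = 0.56,
                   cross_measure_child = 0.46,
                   cross_measure_parent = 0.50,
                   cross_measure_cross_informant = 0.40),
    lambda = 0.5) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(n >= 1, lambda > 0, lambda < 1)
  m <- c(scared_child = 41L, scared_parent = 41L,
         ari_child = 6L, ari_parent = 6L)
  R <- diag(4)
  dimnames(R) <- list(names(m), names(m))
  fill <- function(i, j, target)
    R[i, j] <<- R[j, i] <<- solve_factor_corr(target, m[i], m[j], lambda)
  fill(1, 2, targets$anxiety_cross_informant)
  fill(3, 4, targets$irritability_cross_informant)
  fill(1, 3, targets$cross_measure_child)
  fill(2, 4, targets$cross_measure_parent)
  fill(1, 4, targets$cross_measure_cross_informant)
  fill(2, 3, targets$cross_measure_cross_informant)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("calibrated factor correlation matrix is not positive semi-definite")

  set.seed(seed)
  F <- matrix(rnorm(n * 4), n, 4) %*% chol(R)
  cuts <- qnorm(c(1 / 3, 2 / 3))
  totals <- matrix(0L, n, 4, dimnames = list(NULL, names(m)))
  for (j in 1:4) {
    u <- sqrt(lambda) * F[, j] +
      sqrt(1 - lambda) * matrix(rnorm(n * m[j]), n, m[j])
    items <- (u > cuts[1]) + (u > cuts[2])
    totals[, j] <- as.integer(rowSums(items))
  }
  out <- data.frame(participant = sprintf("P%04d", seq_len(n)),
                    age = runif(n, 8, 22),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    diagnosis = sample(
                      c("DMDD", "ADHD", "Anxiety", "ODD", "Healthy"), n,
                      replace = TRUE, prob = c(27, 23, 19, 2, 24) / 95),
                    totals, stringsAsFactors = FALSE)
  attr(out, "factor_corr") <- R
  attr(out, "targets") <- targets
  out
}

#' Generate per-participant ROI beta profiles
#'
#' Forward model for the desk-scale contrast analysis: each participant's
#' 15-morph beta profile is an intercept plus a linear-valence component
#' whose slope increases with the participant's standardised symptom score
#' (`base_slope + coupling * z`), a quadratic-ambiguity component, and iid
#' Gaussian noise. With `coupling = 0` and `noise_sd = 0` every profile is
#' identical.
#'
#' @param cohort Cohort data frame carrying the symptom column.
#' @param symptom Symptom column name (default `"ari_parent"`).
#' @param coupling Symptom-slope coupling (per SD of symptom).
#' @param base_slope Mean linear-valence coefficient.
#' @param quad_coef Quadratic-ambiguity coefficient.
#' @param intercept Mean signal level.
#' @param noise_sd SD of additive noise per beta.
#' @param seed Integer seed (required).
#' @return Numeric matrix, participants x 15 morphs, rownames from
#'   `cohort$participant`.
#' @export
generate_roi_betas <- function(cohort, symptom = "ari_parent", coupling = 0,
                               base_slope = 0.5, quad_coef = 0.2,
                               intercept = 1, noise_sd = 0.1, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (!symptom %in% names(cohort)) stop("no column '", symptom, "' in cohort")
  sc <- cohort[[symptom]]
  z <- if (sd(sc) > 0) (sc - mean(sc)) / sd(sc) else rep(0, length(sc))
  w <- morph_contrast_weights(15L)
  set.seed(seed)
  n <- nrow(cohort)
  slopes <- base_slope + coupling * z
  profiles <- intercept +
    outer(slopes, w$linear) + outer(rep(quad_coef, n), w$quadratic) +
    matrix(rnorm(n * 15, 0, noise_sd), n, 15)
  rownames(profiles) <- cohort$participant
  colnames(profiles) <- paste0("beta_s", 1:15)
  profiles
}
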