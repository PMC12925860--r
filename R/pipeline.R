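#' Configuration for the end-to-end synthetic pipeline
#'
#' Bundles the seeds, QC thresholds, fit settings, group specifications and
#' statistics settings for [run_pipeline()]. Validation happens here, before
#' any computation.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Master integer seed (required); stage seeds are derived from
#'   it.
#' @param group_specs Named list of [group_spec] objects.
#' @param n_trials Stimulus presentations per participant (<= 450 uses a
#'   truncated schedule; default the full 450).
#' @param rt_threshold Fast-RT exclusion cutoff (s, > 0).
#' @param accuracy_threshold Extreme-morph inclusion threshold in (0, 1].
#' @param n_starts Optimisation starts per participant fit.
#' @param inflection_df Degrees of freedom for the inflection comparison.
#' @param roi_coupling,roi_noise_sd ROI beta generator settings.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed,
                            group_specs = default_group_specs(),
                            n_trials = 450L,
                            rt_threshold = 0.150,
                            accuracy_threshold = 0.80,
                            n_starts = 5L,
                            inflection_df = 50,
                            roi_coupling = 0.04,
                            roi_noise_sd = 0.1) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a scalar integer 'seed' is required")
  if (rt_threshold <= 0 || accuracy_threshold <= 0)
    stop("thresholds must be positive")
  if (n_trials < 15L) stop("n_trials must cover the morph range")
  stopifnot(all(vapply(group_specs, inherits, TRUE, "group_spec")))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 group_specs = group_specs, n_trials = as.integer(n_trials),
                 rt_threshold = rt_threshold,
                 accuracy_threshold = accuracy_threshold,
                 n_starts = as.integer(n_starts),
                 inflection_df = inflection_df,
                 roi_coupling = roi_coupling, roi_noise_sd = roi_noise_sd),
            class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> QC -> fit -> analyze -> replicate -> report. Generates a
#' cohort of diffusion observers per diagnostic group, simulates the
#' labeling task, applies trial- and participant-level QC, fits the
#' diffusion model per participant, joins a synthetic clinical cohort, and
#' writes six artifacts to `config$out_dir`: the per-participant parameter
#' table, the metric-by-clinical correlation table, the ANOVA + post hoc
#' report, the 4PL group-curve replication report, the age-sensitivity
#' replication, and the ROI contrast association report. Every artifact is
#' accompanied by `metadata.json` carrying the seed and a configuration
#' hash; identical configurations reproduce identical tables.
#'
#' @param config A [pipeline_config].
#' @param verbose Print stage progress?
#' @return Invisibly, a list with the in-memory results and the artifact
#'   paths.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[faceddm] ", ...)
  seed <- config$seed

  # --- simulate ----------------------------------------------------------
  say("stage simulate: observers, schedules, trials")
  schedule <- generate_task_schedule(seed)
  stim <- schedule$events[schedule$events$type == "stimulus", ]
  stim <- stim[seq_len(min(config$n_trials, nrow(stim))), ]
  observers <- do.call(rbind, lapply(seq_along(config$group_specs),
    function(i) generate_observer_group(config$group_specs[[i]],
                                        seed = seed + 1000L + i)))
  trials <- do.call(rbind, lapply(seq_len(nrow(observers)), function(i) {
    p <- observers[i, ]
    simulate_trials(ddm_params(p$v_int, p$v_slope, p$a, p$z_r, p$t0),
                    stim$s, seed = seed + 2000L + i,
                    participant = p$participant)
  }))
  trials$run <- rep(stim$run, times = nrow(observers))

  # --- qc ----------------------------------------------------------------
  say("stage qc: fast-RT filter + inclusion check")
  qc <- lapply(split(trials, trials$participant), apply_qc,
               rt_threshold = config$rt_threshold,
               threshold = config$accuracy_threshold)
  included <- names(qc)[vapply(qc, function(q) isTRUE(q$report$included), TRUE)]
  kept <- do.call(rbind, lapply(qc[included], `[[`, "trials"))

  # --- fit ---------------------------------------------------------------
  say("stage fit: ", length(included), " participants")
  fits <- lapply(seq_along(included), function(i) {
    fit_participant(kept[kept$participant == included[i], ],
                    n_starts = config$n_starts, seed = seed + 3000L + i)
  })
  names(fits) <- included
  par_tab <- do.call(rbind, lapply(included, function(id) {
    f <- fits[[id]]
    data.frame(participant = id,
               diagnosis = observers$diagnosis[observers$participant == id],
               v_int = f$params$v_int, v_slope = f$params$v_slope,
               a = f$params$a, z_r = f$params$z_r, t0 = f$params$t0,
               sensitivity = f$sensitivity,
               perceptual_bias = f$perceptual_bias,
               nll = f$nll, n_trials = f$n_trials,
               converged = f$converged, stringsAsFactors = FALSE)
  }))

  # --- analyze -----------------------------------------------------------
  say("stage analyze: clinical join, correlations, ANOVA")
  clin <- generate_clinical_cohort(nrow(par_tab), seed = seed + 4000L)
  cohort <- cbind(par_tab,
                  clin[seq_len(nrow(par_tab)),
                       c("age", "sex", "scared_child", "scared_parent",
                         "ari_child", "ari_parent")])
  cors <- metric_clinical_correlations(cohort)
  an <- oneway_anova(cohort$perceptual_bias, cohort$diagnosis)
  ph <- pairwise_t_bonferroni(cohort$perceptual_bias, cohort$diagnosis)

  # --- replicate ---------------------------------------------------------
  say("stage replicate: 4PL inflections, age-sensitivity")
  fits4 <- lapply(c("DMDD", "Healthy"), function(g) {
    sub <- kept[kept$participant %in%
                  observers$participant[observers$diagnosis == g], ]
    gp <- group_proportions(sub)
    fit_4pl(gp$s, gp$prop_angry)
  })
  names(fits4) <- c("DMDD", "Healthy")
  infl <- compare_inflections(fits4$DMDD, fits4$Healthy,
                              df = config$inflection_df)
  age_sens <- replicate_age_sensitivity(cohort)

  # --- contrasts ---------------------------------------------------------
  say("stage contrasts: ROI betas + association")
  betas <- generate_roi_betas(cohort, coupling = config$roi_coupling,
                              noise_sd = config$roi_noise_sd,
                              seed = seed + 5000L)
  slopes <- fit_individual_slopes(betas)
  assoc <- slope_symptom_association(slopes$linear, cohort$ari_parent,
                                     betas = betas)

  # --- report ------------------------------------------------------------
  say("stage report: writing artifacts to ", config$out_dir)
  fmt <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)
  paths <- list(
    params = file.path(config$out_dir, "ddm_parameters.csv"),
    correlations = file.path(config$out_dir, "metric_clinical_correlations.csv"),
    anova = file.path(config$out_dir, "anova_posthoc.txt"),
    psychometric = file.path(config$out_dir, "psychometric_4pl.txt"),
    age = file.path(config$out_dir, "age_sensitivity.txt"),
    contrasts = file.path(config$out_dir, "contrast_association.txt"))
  write.csv(par_tab, paths$params, row.names = FALSE)
  write.csv(cors, paths$correlations, row.names = FALSE)
  writeLines(c(
    sprintf("one-way ANOVA on perceptual bias by diagnosis: F(%d,%d) = %s, p = %s",
            an$df1, an$df2, fmt(an$F), fmt(an$p)),
    "post hoc pairwise t (pooled SD, Bonferroni):",
    sprintf("  %s vs %s: t(%s) = %s, p_adj = %s", ph$group1, ph$group2,
            fmt(ph$df), fmt(ph$t), fmt(ph$p_adj))), paths$anova)
  writeLines(c(
    sprintf("4PL group fits (gamma, lam, beta, x0 [SE]):"),
    sprintf("  DMDD:    %s %s %s %s [%s]", fmt(fits4$DMDD$gamma),
            fmt(fits4$DMDD$lam), fmt(fits4$DMDD$beta), fmt(fits4$DMDD$x0),
            fmt(fits4$DMDD$se_x0)),
    sprintf("  Healthy: %s %s %s %s [%s]", fmt(fits4$Healthy$gamma),
            fmt(fits4$Healthy$lam), fmt(fits4$Healthy$beta),
            fmt(fits4$Healthy$x0), fmt(fits4$Healthy$se_x0)),
    sprintf("inflection comparison: t(%s) = %s, p = %s",
            fmt(infl$df), fmt(infl$t), fmt(infl$p))), paths$psychometric)
  writeLines(sprintf(
    "age-sensitivity correlation (patients only): r(%d) = %s, p = %s, n = %d",
    age_sens$df, fmt(age_sens$r), fmt(age_sens$p_raw), age_sens$n), paths$age)
  writeLines(c(
    sprintf("linear-coefficient x symptom association: r(%d) = %s, p = %s, n = %d",
            assoc$df, fmt(assoc$r), fmt(assoc$p_raw), assoc$n),
    sprintf("median-split mean profiles at cut %s:", fmt(assoc$median_split$cut)),
    sprintf("  low:  %s", paste(fmt(assoc$median_split$low), collapse = " ")),
    sprintf("  high: %s", paste(fmt(assoc$median_split$high), collapse = " "))),
    paths$contrasts)

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  meta <- list(seed = seed,
               config_hash = sum(utf8ToInt(paste(
                 capture_config(cfg_for_hash), collapse = ""))),
               n_observers = nrow(observers),
               n_included = length(included),
               artifacts = vapply(paths, basename, ""))
  jsonlite::write_json(meta, file.path(config$out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(observers = observers, qc = qc, fits = fits,
                 parameters = par_tab, cohort = cohort,
                 correlations = cors, anova = an, posthoc = ph,
                 fits_4pl = fits4, inflection = infl,
                 age_sensitivity = age_sens, roi_betas = betas,
                 association = assoc, paths = paths))
}

# stable textual form of a config for hashing
capture_config <- function(x) {
  unlist(lapply(x, function(el) {
    if (inherits(el, "group_spec")) paste(unlist(el), collapse = ",")
    else if (is.list(el)) capture_config(el)
    else paste(el, collapse = ",")
  }))
}
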