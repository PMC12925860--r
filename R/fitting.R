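#' Maximum-likelihood fit of the diffusion model to one participant
#'
#' Minimises [negative_log_likelihood()] over `(v_int, v_slope, a, z_r, t0)`
#' by bounded quasi-Newton (L-BFGS-B) from multiple jittered starts; the best
#' converged start wins. The two headline metrics are derived from the winning
#' parameters: sensitivity (`v_slope`) and perceptual bias
#' (`s_indiff = -v_int/v_slope`). `t0` is constrained below the minimum
#' observed RT. Trials should have passed QC first (see [filter_fast_rt()],
#' [inclusion_check()]).
#'
#' Start values combine a moment heuristic (the regression of signed choice on
#' morph index for the drift line, a fraction of the minimum RT for `t0`) with
#' multiplicative jitter per start.
#'
#' @param trials Trial data frame (`s`, `choice`, `rt` in seconds).
#' @param n_starts Number of optimisation starts (>= 1; default 5).
#' @param seed Optional seed controlling the start jitter.
#' @param control Passed to [stats::optim()]'s `control` (L-BFGS-B).
#' @return A `ddm_fit`: list with `params` ([ddm_params]), `sensitivity`,
#'   `perceptual_bias`, `nll`, `n_trials`, `converged`, `n_starts`,
#'   `degenerate` (single response type everywhere).
#' @examples
#' p <- ddm_params(-0.96, 0.12, a = 1.2, z_r = 0.5, t0 = 0.25)
#' tr <- simulate_trials(p, rep(1:15, 10), seed = 1)
#' f <- fit_participant(tr, n_starts = 3, seed = 1)
#' f$perceptual_bias
#' @export
fit_participant <- function(trials, n_starts = 5, seed = NULL,
                            control = list(maxit = 300)) {
  check_trials(trials)
  n <- nrow(trials)
  if (n == 0L) stop("no trials to fit")
  degenerate <- length(unique(trials$choice)) < 2L
  min_rt <- min(trials$rt)

  rt <- trials$rt
  s <- as.integer(trials$s)
  up <- as.integer(trials$choice == "angry")

  obj <- function(th) {
    .ddm_nll_cpp(rt, s, up, th[1], th[2], th[3], th[4], th[5])
  }

  lower <- c(-10, -2, 0.2, 0.02, 0)
  upper <- c(10, 2, 5, 0.98, min_rt * 0.999)

  # moment-style start heuristic: linear trend of signed choice over morphs
  pa <- tapply(up, s, mean)
  ss <- as.numeric(names(pa))
  co <- if (length(ss) >= 2) stats::coef(stats::lm(I(2 * pa - 1) ~ ss)) else c(0, 0.1)
  v_slope0 <- max(min(unname(co[2]) * 1.5, 1.5), 0.01)
  v_int0 <- max(min(unname(co[1]) * 1.5, 5), -5)
  base <- c(v_int0, v_slope0, 1.2, 0.5, 0.85 * min_rt)

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  clean_val <- Inf   # best value among runs with a clean convergence code
  for (k in seq_len(n_starts + 1L)) {
    th0 <- if (k == 1) base
      else if (k == n_starts + 1L && !is.null(best)) best$par  # polish run
      else {
        jit <- base * exp(rnorm(5, 0, 0.25))
        jit[1] <- base[1] + rnorm(1, 0, 0.5)  # intercept jitter must allow sign changes
        jit[4] <- min(max(base[4] + rnorm(1, 0, 0.1), 0.05), 0.95)
        jit
      }
    th0 <- pmin(pmax(th0, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = control),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence == 0) clean_val <- min(clean_val, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  if (is.null(best)) {
    out <- list(params = NULL, sensitivity = NA_real_,
                perceptual_bias = NA_real_, nll = NA_real_, n_trials = n,
                converged = FALSE, n_starts = n_starts,
                degenerate = degenerate)
    class(out) <- "ddm_fit"
    return(out)
  }

  th <- best$par
  params <- ddm_params(th[1], th[2], th[3], th[4], th[5])
  bias <- if (th[2] != 0) -th[1] / th[2] else NA_real_
  out <- list(params = params,
              sensitivity = th[2],
              perceptual_bias = bias,
              nll = best$value,
              n_trials = n,
              converged = (clean_val <= best$value + 1e-3) && !degenerate,
              n_starts = n_starts,
              degenerate = degenerate)
  class(out) <- "ddm_fit"
  out
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Diffusion-model fit:", x$n_trials, "trials,",
      if (isTRUE(x$converged)) "converged" else "NOT converged",
      sprintf("(%d starts)\n", x$n_starts))
  if (!is.null(x$params)) {
    print(x$params)
    cat(sprintf("  sensitivity (v_slope) = %.4f; perceptual bias (s_indiff) = %.3f; nll = %.2f\n",
                x$sensitivity, x$perceptual_bias, x$nll))
  }
  if (isTRUE(x$degenerate))
    cat("  flagged: single response type in the data\n")
  invisible(x)
}

#' Quantile-probability summary of a trial set
#'
#' Per-morph response proportions and response-conditional RT quantiles (the
#' conventional 0.1/0.3/0.5/0.7/0.9 set), the ingredients of a
#' quantile-probability plot for assessing diffusion-model fit quality.
#' Quantiles for a response type with fewer than `min_n` trials at a morph are
#' returned as `NA` and flagged.
#'
#' @param trials Trial data frame.
#' @param probs Quantile probabilities.
#' @param min_n Minimum responses per (morph, response) cell for quantiles.
#' @return Data frame, one row per (morph, response) with `n`, `prop`
#'   (response proportion at that morph; `prop` sums to 1 within morph) and
#'   one column per quantile; attribute `flagged` lists suppressed cells.
#' @export
qp_summary <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                       min_n = 5L) {
  check_trials(trials)
  if (nrow(trials) == 0L) stop("non-empty trials required")
  out <- list(); flagged <- character()
  for (si in sort(unique(trials$s))) {
    sub <- trials[trials$s == si, ]
    for (resp in c("happy", "angry")) {
      rts <- sub$rt[sub$choice == resp]
      q <- if (length(rts) >= min_n) quantile(rts, probs, names = FALSE)
           else rep(NA_real_, length(probs))
      if (length(rts) < min_n)
        flagged <- c(flagged, sprintf("s=%d/%s", si, resp))
      out[[length(out) + 1L]] <- data.frame(
        s = si, response = resp, n = length(rts),
        prop = length(rts) / nrow(sub),
        t(setNames(q, paste0("q", probs * 100))))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "flagged") <- flagged
  res
}
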