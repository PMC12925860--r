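#' Group-level proportion of angry judgements per morph
#'
#' For each morph, the mean over participants of that participant's
#' proportion of "angry" responses — each participant contributes equally
#' regardless of trial count.
#'
#' @param trials Trial data frame for one or more participants.
#' @return Data frame `s`, `prop_angry`, `n_participants`; morphs with no
#'   data are absent (listed in attribute `missing_morphs`).
#' @export
group_proportions <- function(trials) {
  check_trials(trials)
  if (!"participant" %in% names(trials))
    stop("trial table must carry a 'participant' column")
  if (nrow(trials) == 0L) stop("at least one participant required")
  ag <- stats::aggregate(list(prop = trials$choice == "angry"),
                         by = list(participant = trials$participant,
                                   s = trials$s), FUN = mean)
  res <- stats::aggregate(list(prop_angry = ag$prop),
                          by = list(s = ag$s), FUN = mean)
  cnt <- stats::aggregate(list(n_participants = ag$participant),
                          by = list(s = ag$s), FUN = function(x) length(unique(x)))
  res <- merge(res, cnt, by = "s")
  res <- res[order(res$s), ]
  rownames(res) <- NULL
  attr(res, "missing_morphs") <- setdiff(1:15, res$s)
  res
}

#' Four-parameter logistic fit to a group psychometric curve
#'
#' Least-squares fit of
#' `p(s) = gamma + (lam - gamma) / (1 + exp(-beta * (s - x0)))`
#' to per-morph proportions of angry judgements. The free lower and upper
#' asymptotes adjust the inflection for the maximum probability of either
#' judgement. The fit is multi-started over a grid of inflection (`x0`)
#' values; standard errors come from the Jacobian at the optimum. Unweighted
#' by default; `weighted = TRUE` applies binomial weights `n_per_point`.
#'
#' @param morphs Morph indices (>= 6 points spanning both asymptote regions).
#' @param proportions Proportion angry at each morph, in `[0, 1]`.
#' @param n_per_point Responses per point (for binomial weighting).
#' @param weighted Use binomial weights? Default `FALSE`.
#' @param x0_grid Start values for the inflection.
#' @return A `fourpl_fit`; see [fourpl_fit()].
#' @export
fit_4pl <- function(morphs, proportions, n_per_point = NULL,
                    weighted = FALSE, x0_grid = seq(3, 13, by = 2)) {
  stopifnot(length(morphs) == length(proportions))
  if (length(morphs) < 6L) stop("at least 6 points required")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (weighted && is.null(n_per_point))
    stop("'n_per_point' required for weighted fitting")
  dat <- data.frame(s = morphs, p = proportions)
  w <- if (weighted) n_per_point else rep(1, length(morphs))

  lo <- c(0, 0, 1e-4, min(morphs) - 5)
  hi <- c(1, 1, 50, max(morphs) + 5)
  try_start <- function(start) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        p ~ gamma + (lam - gamma) / (1 + exp(-beta * (s - x0))),
        data = dat, weights = w, start = start, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(fit = fit, rss = sum(w * stats::resid(fit)^2))
  }
  best <- NULL
  for (x0s in x0_grid) for (b0 in c(0.5, 1.5, 3)) {
    cand <- try_start(list(gamma = max(min(proportions), 1e-3),
                           lam = min(max(proportions), 1 - 1e-3),
                           beta = b0, x0 = x0s))
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss - 1e-12))
      best <- cand
  }
  # a Levenberg-Marquardt run can stall with an asymptote pinned at its
  # bound; restart once from the best point nudged into the interior
  if (!is.null(best)) {
    cf <- coef(best$fit)
    cf["gamma"] <- min(max(cf["gamma"], 0.005), 0.3)
    cf["lam"] <- min(max(cf["lam"], 0.7), 0.995)
    cand <- try_start(as.list(cf))
    if (!is.null(cand) && cand$rss < best$rss - 1e-12) best <- cand
  }
  if (is.null(best))
    return(fourpl_fit(NA, NA, NA, NA, NA, converged = FALSE))

  cf <- coef(best$fit)
  vc <- tryCatch(vcov(best$fit), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf))))
  fourpl_fit(gamma = unname(cf["gamma"]), lam = unname(cf["lam"]),
             beta = unname(cf["beta"]), x0 = unname(cf["x0"]),
             se_x0 = sqrt(vc["x0", "x0"]), vcov = vc, converged = TRUE,
             rss = best$rss)
}

#' Construct a 4PL fit object
#'
#' Container for 4-parameter logistic estimates; also usable to wrap
#' published estimates (an inflection and its standard error) for
#' [compare_inflections()].
#'
#' @param gamma,lam Lower and upper asymptotes (proportions).
#' @param beta Slope per morph step.
#' @param x0 Inflection point (morph units).
#' @param se_x0 Standard error of `x0`.
#' @param vcov Optional 4x4 covariance of the estimates.
#' @param converged Convergence flag.
#' @param rss Residual sum of squares at the optimum.
#' @return Object of class `fourpl_fit`.
#' @export
fourpl_fit <- function(gamma, lam, beta, x0, se_x0, vcov = NULL,
                       converged = TRUE, rss = NA_real_) {
  if (isTRUE(converged) && !anyNA(c(gamma, lam))) {
    if (!(gamma >= 0 && gamma < lam && lam <= 1))
      stop("asymptotes must satisfy 0 <= gamma < lam <= 1")
    if (!is.na(se_x0) && se_x0 < 0) stop("se_x0 must be >= 0")
  }
  structure(list(gamma = gamma, lam = lam, beta = beta, x0 = x0,
                 se_x0 = se_x0, vcov = vcov, converged = converged,
                 rss = rss),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("4PL fit: NOT converged\n"); return(invisible(x))
  }
  cat(sprintf("4PL fit: gamma = %.4f, lam = %.4f, beta = %.3f, x0 = %.3f (SE %.4f)\n",
              x$gamma, x$lam, x$beta, x$x0, x$se_x0))
  invisible(x)
}

#' Predicted 4PL curve
#' @param object A `fourpl_fit`.
#' @param s Morph indices.
#' @param ... Unused.
#' @return Predicted proportion angry at `s`.
#' @export
predict.fourpl_fit <- function(object, s, ...) {
  object$gamma + (object$lam - object$gamma) /
    (1 + exp(-object$beta * (s - object$x0)))
}

#' Wald comparison of two psychometric inflection points
#'
#' `t = (x0_A - x0_B) / sqrt(se_A^2 + se_B^2)`, two-sided p at `df` degrees
#' of freedom. The degrees of freedom are a configured quantity (default 50),
#' reported alongside the statistic.
#'
#' @param fitA,fitB Converged `fourpl_fit` objects with positive `se_x0`.
#' @param df Degrees of freedom for the reference t distribution.
#' @return List `t`, `p`, `df`, `diff` (x0_A - x0_B).
#' @export
compare_inflections <- function(fitA, fitB, df = 50) {
  stopifnot(inherits(fitA, "fourpl_fit"), inherits(fitB, "fourpl_fit"))
  if (!isTRUE(fitA$converged) || !isTRUE(fitB$converged))
    stop("both fits must have converged")
  if (!all(is.finite(c(fitA$se_x0, fitB$se_x0))) ||
      fitA$se_x0 < 0 || fitB$se_x0 < 0 ||
      (fitA$se_x0 == 0 && fitB$se_x0 == 0))
    stop("standard errors must be finite and not both zero")
  tval <- (fitA$x0 - fitB$x0) / sqrt(fitA$se_x0^2 + fitB$se_x0^2)
  list(t = tval, p = 2 * pt(-abs(tval), df = df), df = df,
       diff = fitA$x0 - fitB$x0)
}
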