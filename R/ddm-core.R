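#' Diffusion-model parameters for one observer
#'
#' Container for the stimulus-dependent-drift diffusion model. The drift rate
#' is linear in the morph index `s` (1 = prototypically happy, 15 =
#' prototypically angry, 8 = most ambiguous): `v(s) = v_int + s * v_slope`.
#' `v_slope` is the observer's sensitivity to changing facial affect;
#' the morph index at which `v(s) = 0`, `s_indiff = -v_int / v_slope`, is the
#' perceptual bias (point of indifference). The upper boundary codes an
#' "angry" response, the lower "happy"; positive drift favours angry.
#'
#' The diffusion constant `sigma` is fixed at 1 by convention (it is not
#' identifiable jointly with `v` and `a`; some traditions use 0.1 — all
#' derived quantities reported here, `s_indiff` and parameter orderings, are
#' convention-free).
#'
#' @param v_int Drift intercept (evidence/s).
#' @param v_slope Drift increment per morph step (sensitivity).
#' @param a Boundary separation, must be > 0.
#' @param z_r Relative starting point in (0, 1); 0.5 is unbiased.
#' @param t0 Non-decision time in seconds, >= 0.
#' @param sigma Diffusion constant; fixed at 1 for all fits.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v_int = -0.96, v_slope = 0.12, a = 1.2, z_r = 0.5, t0 = 0.25)
#' drift_rate(p, 8)
#' indifference_point(p)
#' @export
ddm_params <- function(v_int, v_slope, a, z_r, t0, sigma = 1) {
  stopifnot(is.numeric(v_int), is.numeric(v_slope), length(v_int) == 1L,
            length(v_slope) == 1L)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("boundary separation 'a' must be a positive number")
  if (!is.numeric(z_r) || length(z_r) != 1L || z_r <= 0 || z_r >= 1)
    stop("relative starting point 'z_r' must lie strictly in (0, 1)")
  if (!is.numeric(t0) || length(t0) != 1L || t0 < 0)
    stop("non-decision time 't0' must be >= 0")
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(v_int = v_int, v_slope = v_slope, a = a, z_r = z_r,
                 t0 = t0, sigma = sigma),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Diffusion-model parameters (drift linear in morph index)\n")
  cat(sprintf("  v_int = %.4f, v_slope = %.4f, a = %.4f, z_r = %.4f, t0 = %.4f s (sigma = %g)\n",
              x$v_int, x$v_slope, x$a, x$z_r, x$t0, x$sigma))
  if (x$v_slope != 0)
    cat(sprintf("  indifference point s_indiff = %.3f\n", -x$v_int / x$v_slope))
  invisible(x)
}

check_morph <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 1) || any(s > 15) ||
      any(s != round(s)))
    stop("morph index 's' must be an integer in 1..15")
  as.integer(s)
}

#' Drift rate at a morph index
#'
#' `v(s) = v_int + s * v_slope`: the mean evidence-accumulation rate when the
#' observer views morph `s`.
#'
#' @param params A [ddm_params] object.
#' @param s Morph index (integer in 1..15, vectorised).
#' @return Drift rate(s), evidence/s.
#' @export
drift_rate <- function(params, s) {
  stopifnot(inherits(params, "ddm_params"))
  s <- check_morph(s)
  params$v_int + s * params$v_slope
}

#' Perceptual bias: the indifference point
#'
#' The (real-valued) morph index at which the drift rate vanishes,
#' `s_indiff = -v_int / v_slope`. Values below the continuum midpoint (8)
#' indicate a shift toward angry judgements. A value outside the stimulus
#' range 1..15 is returned unclipped, with attribute `out_of_range = TRUE`.
#'
#' @param params A [ddm_params] object with `v_slope != 0`.
#' @return `s_indiff` in morph units; attribute `out_of_range` flags values
#'   outside `[1, 15]`.
#' @export
indifference_point <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  if (params$v_slope == 0)
    stop("perceptual bias is undefined when v_slope is 0")
  s_indiff <- -params$v_int / params$v_slope
  attr(s_indiff, "out_of_range") <- (s_indiff < 1 || s_indiff > 15)
  s_indiff
}

#' Analytic probability of an "angry" response
#'
#' Absorption probability at the upper (angry) boundary for the Wiener
#' process with drift `v = v(s)`, boundaries `0` and `a`, start `z = z_r * a`:
#' `P(angry) = (1 - exp(-2 v z / sigma^2)) / (1 - exp(-2 v a / sigma^2))`,
#' with the continuous limit `z_r` as `v -> 0`. Serves as the exact oracle for
#' the simulator and the likelihood.
#'
#' @inheritParams drift_rate
#' @return Probability in (0, 1), vectorised over `s`.
#' @export
choice_probability <- function(params, s) {
  v <- drift_rate(params, s) / params$sigma^2
  a <- params$a
  z <- params$z_r * a
  p <- ifelse(abs(v * a) < 1e-10,
              params$z_r,
              expm1(-2 * v * z) / expm1(-2 * v * a))
  unname(p)
}

#' Wiener first-passage-time density
#'
#' Defective density of the response time `t` at the named boundary: the
#' first-passage density of the decision time `t - t0` for the drifting
#' diffusion, zero for `t <= t0`. Computed with a small-time / large-time
#' series switch whose truncation error is bounded by `eps` per evaluation;
#' the representation needing fewer terms is chosen at each point.
#'
#' @param t Response times in seconds (vectorised).
#' @param params A [ddm_params] object.
#' @param s Morph index (scalar).
#' @param boundary `"angry"` (upper) or `"happy"` (lower).
#' @param eps Series truncation bound per evaluation.
#' @return Density values (1/s); integrates over `t` to the corresponding
#'   [choice_probability].
#' @export
wfpt_density <- function(t, params, s, boundary = c("angry", "happy"),
                         eps = 1e-7) {
  stopifnot(inherits(params, "ddm_params"))
  boundary <- match.arg(boundary)
  if (any(!is.finite(t))) stop("non-finite t")
  s <- check_morph(s)
  stopifnot(length(s) == 1L)
  # reduce to sigma = 1 by rescaling evidence units
  v <- drift_rate(params, s) / params$sigma
  a <- params$a / params$sigma
  .wfpt_density_cpp(as.numeric(t), v, a, params$z_r, params$t0,
                    upper = (boundary == "angry"), eps = eps)
}

#' Simulate labeling trials from a diffusion observer
#'
#' Forward-simulates one trial per schedule entry by Euler–Maruyama
#' integration of the diffusion (step `dt`); the response time is the
#' first-passage time plus `t0`. Reproducible given `seed`.
#'
#' @param params A [ddm_params] object.
#' @param schedule Either an integer vector of morph indices or a
#'   [task_schedule] object (its stimulus events are used, with run numbers).
#' @param seed Integer seed (required).
#' @param participant Participant identifier stamped on the records.
#' @param dt Euler time step in seconds.
#' @return A trial data frame with columns `participant`, `run`, `s`,
#'   `choice` (`"happy"`/`"angry"`), `rt` (seconds).
#' @export
simulate_trials <- function(params, schedule, seed, participant = "sim",
                            dt = 1e-4) {
  stopifnot(inherits(params, "ddm_params"))
  if (missing(seed)) stop("'seed' is required")
  if (inherits(schedule, "task_schedule")) {
    ev <- schedule$events[schedule$events$type == "stimulus", ]
    s <- ev$s
    run <- ev$run
  } else {
    s <- check_morph(schedule)
    run <- rep(1L, length(s))
  }
  if (length(s) == 0L) stop("empty schedule")
  set.seed(seed)
  sim <- .ddm_simulate_cpp(as.integer(s),
                           params$v_int / params$sigma,
                           params$v_slope / params$sigma,
                           params$a / params$sigma,
                           params$z_r, params$t0, dt = dt)
  data.frame(participant = participant, run = run, s = as.integer(s),
             choice = ifelse(sim$upper == 1L, "angry", "happy"),
             rt = sim$rt, stringsAsFactors = FALSE)
}

#' Negative log-likelihood of a trial set
#'
#' `-sum(log f(rt_i))` where `f` is the defective first-passage density at the
#' observed boundary for the observed morph. Any trial with `rt <= t0`
#' receives a large penalty (the density is zero there).
#'
#' @param params A [ddm_params] object.
#' @param trials Trial data frame (`s`, `choice`, `rt`).
#' @return Scalar negative log-likelihood; 0 (with a warning) for an empty
#'   trial set.
#' @export
negative_log_likelihood <- function(params, trials) {
  stopifnot(inherits(params, "ddm_params"))
  if (nrow(trials) == 0L) {
    warning("empty trial set: log-likelihood is an empty sum")
    return(0)
  }
  check_trials(trials)
  .ddm_nll_cpp(trials$rt, as.integer(trials$s),
               as.integer(trials$choice == "angry"),
               params$v_int / params$sigma, params$v_slope / params$sigma,
               params$a / params$sigma, params$z_r, params$t0)
}

# shared trial-table validation (columns s, choice, rt)
check_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  need <- c("s", "choice", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!trials$choice %in% c("happy", "angry")))
    stop("choice must be 'happy' or 'angry'")
  if (any(!is.finite(trials$rt)) || any(trials$rt <= 0))
    stop("all RTs must be positive and finite")
  check_morph(trials$s)
  invisible(trials)
}
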