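#' Read a trial table from delimited text
#'
#' Expects the dialect `participant,run,morph,choice,rt_s` (comma-separated,
#' header required). RTs are stored in seconds internally; a file carrying
#' milliseconds can be read with `rt_unit = "ms"`. Malformed rows (missing
#' values, non-numeric RT, morph outside 1..15, unknown choice labels) abort
#' with an error naming the offending data rows.
#'
#' @param path File path.
#' @param rt_unit `"s"` (default) or `"ms"`; milliseconds are converted.
#' @return Trial data frame with columns `participant`, `run`, `s`, `choice`,
#'   `rt` (seconds). Empty file with a header yields zero rows.
#' @export
read_trials <- function(path, rt_unit = c("s", "ms")) {
  rt_unit <- match.arg(rt_unit)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("participant", "run", "morph", "choice", "rt_s")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L)
    return(data.frame(participant = character(), run = integer(),
                      s = integer(), choice = character(),
                      rt = numeric(), stringsAsFactors = FALSE))
  run <- suppressWarnings(as.integer(raw$run))
  morph <- suppressWarnings(as.numeric(raw$morph))
  rt <- suppressWarnings(as.numeric(raw$rt_s))
  bad <- which(is.na(run) | is.na(morph) | morph != round(morph) |
                 morph < 1 | morph > 15 | is.na(rt) | rt <= 0 |
                 !raw$choice %in% c("happy", "angry") |
                 is.na(raw$participant) | raw$participant == "")
  if (length(bad))
    stop("malformed trial row(s): ", paste(bad, collapse = ", "),
         " (data row numbers, header excluded)")
  if (rt_unit == "ms") rt <- rt / 1000
  data.frame(participant = raw$participant, run = run,
             s = as.integer(morph), choice = raw$choice, rt = rt,
             stringsAsFactors = FALSE)
}

#' Write a trial table as delimited text
#'
#' Inverse of [read_trials()]: writes the `participant,run,morph,choice,rt_s`
#' dialect so that write-then-read reproduces the records.
#'
#' @param trials Trial data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  out <- data.frame(participant = trials$participant, run = trials$run,
                    morph = trials$s, choice = trials$choice,
                    rt_s = trials$rt)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove anticipatory (fast-RT) trials
#'
#' Drops trials with RT strictly below `threshold` (default 150 ms); trials
#' at exactly the threshold are kept. Order is preserved and the operation is
#' idempotent.
#'
#' @param trials Trial data frame (RTs in seconds).
#' @param threshold Seconds; default 0.150.
#' @return List with `trials` (kept rows) and `report` (a list:
#'   `n_trials_in`, `n_trials_fast_removed`).
#' @export
filter_fast_rt <- function(trials, threshold = 0.150) {
  check_trials(trials)
  keep <- trials$rt >= threshold
  list(trials = trials[keep, , drop = FALSE],
       report = list(n_trials_in = nrow(trials),
                     n_trials_fast_removed = sum(!keep)))
}

#' Participant inclusion check on extreme-morph accuracy
#'
#' A participant is included when accuracy on the two most extreme morphs —
#' "happy" responses at `s = 1` and "angry" at `s = 15` — reaches at least
#' `threshold` (default 80%). By default responses are pooled over the two
#' extremes; `mode = "per_morph"` instead requires each extreme separately to
#' reach the threshold. With no extreme-morph trials the status is
#' indeterminate (`included = NA`), never silently passed.
#'
#' @param trials Trial data frame for one participant.
#' @param threshold Accuracy threshold in `[0, 1]`.
#' @param mode `"pooled"` (default) or `"per_morph"`.
#' @param fast_rt_report Optional report fragment from [filter_fast_rt()] to
#'   carry through.
#' @return A `qc_report`: `n_trials_in`, `n_trials_fast_removed`,
#'   `extreme_morph_accuracy`, `included`.
#' @export
inclusion_check <- function(trials, threshold = 0.80,
                            mode = c("pooled", "per_morph"),
                            fast_rt_report = NULL) {
  check_trials(trials)
  mode <- match.arg(mode)
  ext <- trials[trials$s %in% c(1L, 15L), ]
  correct <- (ext$s == 1L & ext$choice == "happy") |
    (ext$s == 15L & ext$choice == "angry")
  if (nrow(ext) == 0L) {
    acc <- NA_real_; inc <- NA
  } else if (mode == "pooled") {
    acc <- mean(correct)
    inc <- acc >= threshold
  } else {
    acc1 <- if (any(ext$s == 1L)) mean(correct[ext$s == 1L]) else NA_real_
    acc15 <- if (any(ext$s == 15L)) mean(correct[ext$s == 15L]) else NA_real_
    acc <- mean(correct)
    inc <- if (anyNA(c(acc1, acc15))) NA else (acc1 >= threshold && acc15 >= threshold)
  }
  out <- list(n_trials_in = if (is.null(fast_rt_report))
                nrow(trials) else fast_rt_report$n_trials_in,
              n_trials_fast_removed = if (is.null(fast_rt_report))
                0L else fast_rt_report$n_trials_fast_removed,
              extreme_morph_accuracy = acc,
              included = inc)
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d trials in, %d fast-RT removed; extreme-morph accuracy %s; %s\n",
              x$n_trials_in, x$n_trials_fast_removed,
              if (is.na(x$extreme_morph_accuracy)) "indeterminate"
              else sprintf("%.1f%%", 100 * x$extreme_morph_accuracy),
              if (is.na(x$included)) "status INDETERMINATE"
              else if (x$included) "INCLUDED" else "EXCLUDED"))
  invisible(x)
}

#' Apply the full trial/participant QC sequence
#'
#' Fast-RT filtering first, then the extreme-morph accuracy inclusion check
#' on the remaining trials.
#'
#' @inheritParams inclusion_check
#' @param rt_threshold Fast-RT cutoff in seconds.
#' @return List with `trials` (filtered) and `report` (a `qc_report`).
#' @export
apply_qc <- function(trials, rt_threshold = 0.150, threshold = 0.80,
                     mode = c("pooled", "per_morph")) {
  f <- filter_fast_rt(trials, rt_threshold)
  rep <- inclusion_check(f$trials, threshold, mode,
                         fast_rt_report = f$report)
  list(trials = f$trials, report = rep)
}
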