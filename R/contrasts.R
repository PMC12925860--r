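#' Linear and quadratic morph contrasts centred on the middle morph
#'
#' Valence (linear) and ambiguity (quadratic) contrast weights over an odd
#' number of morph regressors. The linear weights are proportional to
#' `s - mid` (antisymmetric about the middle morph, zero there); the
#' quadratic weights are `(s - mid)^2` centred to zero sum, hence orthogonal
#' to the linear set. Both are normalised to unit sum of squares so projected
#' coefficients are comparable across ROIs.
#'
#' @param n_morphs Odd number of morph levels (default 15).
#' @return List of class `contrast_weights`: `linear`, `quadratic` (length
#'   `n_morphs` each), `mid`.
#' @export
morph_contrast_weights <- function(n_morphs = 15L) {
  if (n_morphs < 3L || n_morphs %% 2L == 0L)
    stop("n_morphs must be odd and >= 3 (no middle morph otherwise)")
  s <- seq_len(n_morphs)
  mid <- (n_morphs + 1L) / 2L
  lin <- s - mid
  quad <- (s - mid)^2
  quad <- quad - mean(quad)
  lin <- lin / sqrt(sum(lin^2))
  quad <- quad / sqrt(sum(quad^2))
  structure(list(linear = lin, quadratic = quad, mid = mid),
            class = "contrast_weights")
}

#' Per-participant linear and quadratic contrast coefficients
#'
#' Least-squares projection of a 15-value ROI beta profile (one beta per
#' morph regressor) onto the linear and quadratic contrasts plus an
#' intercept. Because the regressors are orthonormal the coefficients are the
#' inner products with the centred profile.
#'
#' @param betas Numeric vector of length `n_morphs`, or a matrix/data frame
#'   with one participant per row.
#' @param weights A `contrast_weights` object (default for 15 morphs).
#' @return For a vector: named vector `c(linear, quadratic)`. For a matrix:
#'   data frame with `linear`, `quadratic` per row.
#' @export
fit_individual_slopes <- function(betas, weights = morph_contrast_weights()) {
  stopifnot(inherits(weights, "contrast_weights"))
  n <- length(weights$linear)
  if (is.matrix(betas) || is.data.frame(betas)) {
    m <- as.matrix(betas)
    if (ncol(m) != n) stop("expected ", n, " beta columns")
    if (any(!is.finite(m))) stop("non-finite betas")
    out <- data.frame(linear = as.vector(m %*% weights$linear),
                      quadratic = as.vector(m %*% weights$quadratic))
    rownames(out) <- rownames(betas)
    return(out)
  }
  if (length(betas) != n) stop("expected ", n, " betas")
  if (any(!is.finite(betas))) stop("non-finite betas")
  c(linear = sum(betas * weights$linear),
    quadratic = sum(betas * weights$quadratic))
}

#' Association between individual contrast coefficients and a symptom score
#'
#' Pearson correlation between per-participant linear (valence) coefficients
#' and a clinical measure, with median-split group mean profiles for
#' plotting.
#'
#' @param coefs Numeric vector of per-participant linear coefficients.
#' @param scores Symptom scores, same length.
#' @param betas Optional participant-by-morph beta matrix; when given, the
#'   median-split mean beta profiles (high/low symptom group) are returned.
#' @return List `r`, `n`, `df`, `p_raw`, `flag` (`"constant"` when either
#'   input is constant) and, when `betas` is supplied, `median_split` with
#'   mean profiles for the low/high groups.
#' @export
slope_symptom_association <- function(coefs, scores, betas = NULL) {
  stopifnot(length(coefs) == length(scores))
  ok <- complete.cases(coefs, scores)
  coefs <- coefs[ok]; scores <- scores[ok]
  n <- length(coefs)
  if (n < 3L) stop("at least 3 participants required")
  if (sd(coefs) == 0 || sd(scores) == 0) {
    res <- list(r = NA_real_, n = n, df = n - 2L, p_raw = NA_real_,
                flag = "constant")
  } else {
    ct <- cor.test(coefs, scores, method = "pearson")
    res <- list(r = unname(ct$estimate), n = n, df = n - 2L,
                p_raw = ct$p.value, flag = "")
  }
  if (!is.null(betas)) {
    m <- as.matrix(betas)[ok, , drop = FALSE]
    hi <- scores > median(scores)
    res$median_split <- list(low = colMeans(m[!hi, , drop = FALSE]),
                             high = colMeans(m[hi, , drop = FALSE]),
                             cut = median(scores))
  }
  res
}
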