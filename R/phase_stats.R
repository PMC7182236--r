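#' A set of per-trial phases
#'
#' @param angles Numeric vector of phase angles in radians (any range;
#'   stored wrapped to `(-pi, pi]`).
#' @return An object of class `fpvs_phases` with elements `angles` and
#'   `n`.
#' @export
phase_set <- function(angles) {
  if (!is.numeric(angles) || !all(is.finite(angles))) {
    abort("Phases must be finite numerics.", class = "fpvs_domain_error")
  }
  ang <- -((-angles + pi) %% (2 * pi) - pi)  # wrap, keeping pi -> pi
  structure(list(angles = ang, n = length(ang)), class = "fpvs_phases")
}

as_phases <- function(x) {
  if (inherits(x, "fpvs_phases")) x else phase_set(x)
}

#' Cosine-similarity phase-clustering index (pairwise form)
#'
#' The mean cosine of the phase difference over all trial pairs,
#' `CS = 2 / (n (n - 1)) * sum_{i<j} cos(theta_i - theta_j)`,
#' computed by explicit pairwise summation. Ranges from `-1/(n-1)`
#' (maximally dispersed) to 1 (identical phases) with expectation 0 under
#' uniform phases at any trial count.
#'
#' @param phases A [phase_set()] or numeric vector of angles; at least
#'   two trials.
#' @return The CS value, with the trial count as attribute `"n"`.
#' @seealso [cs_index_closed()] for the O(n) production form, [itc()].
#' @examples
#' cs_index(c(0, pi / 2, pi))  # -1/3
#' @export
cs_index <- function(phases) {
  p <- as_phases(phases)
  if (p$n < 2) abort("CS needs at least 2 trials.", class = "fpvs_domain_error")
  dm <- outer(p$angles, p$angles, function(a, b) cos(a - b))
  value <- sum(dm[upper.tri(dm)]) * 2 / (p$n * (p$n - 1))
  structure(value, n = p$n)
}

#' Cosine-similarity index (closed form)
#'
#' Algebraically identical to [cs_index()] but O(n): with resultant
#' length `R = |sum_i exp(1i theta_i)|`, `CS = (R^2 - n) / (n (n - 1))`.
#' This is the production path; the pairwise form is retained as its
#' oracle.
#'
#' @inheritParams cs_index
#' @return The CS value, with the trial count as attribute `"n"`.
#' @export
cs_index_closed <- function(phases) {
  p <- as_phases(phases)
  if (p$n < 2) abort("CS needs at least 2 trials.", class = "fpvs_domain_error")
  R2 <- Mod(sum(exp(1i * p$angles)))^2
  structure((R2 - p$n) / (p$n * (p$n - 1)), n = p$n)
}

#' Inter-trial coherence
#'
#' Length of the mean resultant of the unit phase vectors, `R / n` in
#' `[0, 1]`. Unlike CS it is positively biased at small trial counts
#' (expectation about `sqrt(pi / (4 n))` under uniform phases).
#'
#' @inheritParams cs_index
#' @return The ITC value.
#' @export
itc <- function(phases) {
  p <- as_phases(phases)
  if (p$n < 1) abort("ITC needs at least 1 trial.", class = "fpvs_domain_error")
  Mod(sum(exp(1i * p$angles))) / p$n
}

#' Phase-shuffled null distribution of CS
#'
#' Destroys inter-trial phase alignment by rotating each trial's phase by
#' an independent uniform angle, and recomputes CS; repeated `n_perm`
#' times this yields the null distribution against which an observed CS
#' can be ranked (e.g. its 95th percentile).
#'
#' @inheritParams cs_index
#' @param n_perm Number of shuffles.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_perm` null CS values.
#' @export
cs_null <- function(phases, n_perm = 200, seed = NULL) {
  p <- as_phases(phases)
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      as.numeric(cs_index_closed(p$angles + runif(p$n, 0, 2 * pi)))
    }, numeric(1))
  })
}
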