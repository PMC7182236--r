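#' Analysis window
#'
#' The portion of each epoch entering spectral analysis: it starts
#' `start_offset` seconds after RSVP onset (excluding the initial
#' event-related transient) and lasts `length` seconds — 3 s for the
#' 15 Hz designs, 6.5 s for the 6 Hz designs.
#'
#' @param start_offset Seconds after epoch start.
#' @param length Window length in seconds.
#' @return A list of class `fpvs_window`.
#' @export
analysis_window <- function(start_offset = 0.5, length = 3) {
  stopifnot(start_offset >= 0, length > 0)
  structure(list(start_offset = start_offset, length = length),
            class = "fpvs_window")
}

#' Truncate epochs to the analysis window and remove linear trends
#'
#' @param epochs An [epoch_set()].
#' @param window An [analysis_window()]; must fit inside the epoch.
#' @return The truncated epoch set, each channel's best-fit line removed.
#' @export
truncate_detrend <- function(epochs, window = analysis_window()) {
  fs <- epochs$sampling_rate
  first <- as.integer(round(window$start_offset * fs)) + 1L
  len <- as.integer(round(window$length * fs))
  if (first + len - 1L > n_samples(epochs)) {
    abort("Analysis window exceeds the epoch.", class = "fpvs_window_error")
  }
  d <- dim(epochs$data)
  x <- epochs$data[, , first:(first + len - 1L), drop = FALSE]
  # residual projector for an intercept + slope fit, shared by all series
  t0 <- seq_len(len)
  X <- cbind(1, t0)
  H <- X %*% solve(crossprod(X), t(X))
  flat <- matrix(aperm(x, c(3, 1, 2)), len, d[1] * d[2])
  flat <- flat - H %*% flat
  epochs$data <- aperm(array(flat, c(len, d[1], d[2])), c(2, 3, 1))
  dimnames(epochs$data) <- list(NULL, epochs$montage$channel, NULL)
  epochs
}

#' Zero-phase Gaussian narrowband filter
#'
#' Frequency-domain Gaussian with unit gain at the centre frequency and
#' the given full width at half maximum, applied symmetrically to
#' positive and negative frequencies (zero phase shift).
#'
#' @param x Numeric matrix `channels x samples` (or a vector).
#' @param center Centre frequency (Hz), below Nyquist.
#' @param fwhm Full width at half maximum of the amplitude response (Hz).
#' @param fs Sampling rate (Hz).
#' @return The filtered series, same shape as `x`.
#' @export
narrowband <- function(x, center, fwhm, fs) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  ns <- ncol(x)
  if (center >= fs / 2) abort("`center` must be below Nyquist.",
                              class = "fpvs_config_error")
  f <- (seq_len(ns) - 1) * fs / ns
  f <- pmin(f, fs - f)  # folded frequency axis
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gain <- exp(-(f - center)^2 / (2 * sigma^2))
  out <- Re(t(mvfft(mvfft(t(x)) * gain, inverse = TRUE))) / ns
  if (vec) out[1, ] else out
}

#' Spatial-filter parameters
#'
#' @param signal_bandwidth Half-bandwidth of the signal band (Hz); the
#'   signal filter is a Gaussian with FWHM twice this value.
#' @param noise_offset Distance of the two flanking noise bands from the
#'   target frequency (Hz).
#' @param noise_fwhm FWHM of the noise-band Gaussians (Hz).
#' @param shrinkage Diagonal loading of the noise covariance, as a
#'   fraction of its mean eigenvalue.
#' @return A list of class `fpvs_filter_params`.
#' @export
filter_params <- function(signal_bandwidth = 0.5, noise_offset = 1,
                          noise_fwhm = 0.5, shrinkage = 0.01) {
  stopifnot(signal_bandwidth > 0, noise_offset > 0, noise_fwhm > 0,
            shrinkage >= 0)
  if (noise_offset - noise_fwhm / 2 <= signal_bandwidth / 2) {
    abort("Noise bands must be disjoint from the signal band.",
          class = "fpvs_config_error")
  }
  structure(list(signal_bandwidth = signal_bandwidth,
                 noise_offset = noise_offset, noise_fwhm = noise_fwhm,
                 shrinkage = shrinkage),
            class = "fpvs_filter_params")
}

trial_cov_mean <- function(epochs, scalp, center, fwhm) {
  fs <- epochs$sampling_rate
  n <- n_trials(epochs)
  acc <- 0
  for (i in seq_len(n)) {
    xf <- narrowband(epochs$data[i, scalp, ], center, fwhm, fs)
    xf <- xf - rowMeans(xf)
    acc <- acc + tcrossprod(xf) / (ncol(xf) - 1)
  }
  acc / n
}

#' Fit a RESS spatial filter
#'
#' Derives the channel weighting that maximises narrowband power at the
#' target frequency against the flanking noise bands, by generalized
#' eigendecomposition: `S` is the mean per-trial covariance of the
#' signal-band-filtered data, `R` the mean covariance of the two
#' neighbouring noise bands, regularised by diagonal loading
#' (`shrinkage` times its mean eigenvalue); the filter is the leading
#' generalized eigenvector of `S w = lambda R w`.
#'
#' @param epochs An [epoch_set()], truncated and detrended; at least two
#'   trials. Only scalp channels enter the filter.
#' @param f_target Target frequency (Hz).
#' @param params [filter_params()].
#' @return An object of class `fpvs_filter`: `weights` (named channel
#'   vector, largest-magnitude entry positive), `eigenvalue`,
#'   `f_target`, `condition` (when unique in the epochs), and
#'   `topography` (unit-norm back-projection `S w`).
#' @export
ress_fit <- function(epochs, f_target, params = filter_params()) {
  if (n_trials(epochs) < 2) abort("Need at least 2 trials.")
  if (!all(is.finite(epochs$data))) abort("Non-finite data.",
                                          class = "fpvs_data_error")
  scalp <- which(epochs$montage$type == "scalp")
  S <- trial_cov_mean(epochs, scalp, f_target, 2 * params$signal_bandwidth)
  R <- (trial_cov_mean(epochs, scalp, f_target - params$noise_offset,
                       params$noise_fwhm) +
        trial_cov_mean(epochs, scalp, f_target + params$noise_offset,
                       params$noise_fwhm)) / 2
  eR <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  R_reg <- R + diag(params$shrinkage * mean(eR), nrow(R))
  eS <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  # average-referenced data always has one null direction; warn only
  # beyond that
  if (sum(eS < max(eS) * 1e-12) > 1) {
    warn("Signal covariance is rank deficient; solution is pseudo-stabilized.")
  }
  # whiten by R_reg, then an ordinary symmetric eigenproblem
  er <- eigen(R_reg, symmetric = TRUE)
  W <- er$vectors %*% diag(1 / sqrt(pmax(er$values, max(er$values) * 1e-12))) %*%
    t(er$vectors)
  em <- eigen(W %*% S %*% W, symmetric = TRUE)
  w <- as.vector(W %*% em$vectors[, 1])
  if (w[which.max(abs(w))] < 0) w <- -w
  topo <- as.vector(S %*% w)
  topo <- topo / sqrt(sum(topo^2))
  cond <- if ("condition" %in% names(epochs$info) &&
              length(unique(epochs$info$condition)) == 1) {
    epochs$info$condition[1]
  } else NA_character_
  labels <- epochs$montage$channel[scalp]
  structure(list(weights = setNames(w, labels),
                 eigenvalue = em$values[1], f_target = f_target,
                 condition = cond, topography = setNames(topo, labels),
                 montage = epochs$montage[scalp, ]),
            class = "fpvs_filter")
}

#' @export
print.fpvs_filter <- function(x, ...) {
  cat(sprintf("<fpvs_filter> %g Hz, eigenvalue %.3g%s\n", x$f_target,
              x$eigenvalue,
              if (!is.na(x$condition)) paste0(", condition ", x$condition) else ""))
  invisible(x)
}

#' Project epochs through a spatial filter
#'
#' @param epochs An [epoch_set()] on the montage the filter was fit to.
#' @param filter An `fpvs_filter`.
#' @return A numeric matrix `trials x samples` of the filter-projected
#'   single-trial time series.
#' @export
ress_project <- function(epochs, filter) {
  idx <- match(names(filter$weights), epochs$montage$channel)
  if (anyNA(idx)) abort("Montage mismatch between filter and epochs.",
                        class = "fpvs_montage_error")
  d <- dim(epochs$data)
  out <- matrix(0, d[1], d[3])
  for (i in seq_len(d[1])) {
    out[i, ] <- filter$weights %*% epochs$data[i, idx, ]
  }
  out
}

tukey_window <- function(n, alpha = 0.25) {
  if (alpha <= 0) return(rep(1, n))
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Windowed, zero-padded single-trial spectra
#'
#' Each trial is multiplied with a Tukey taper and zero-padded to
#' `pad_to` seconds before the discrete Fourier transform, putting all
#' experiments on a common frequency grid of spacing `1 / pad_to`
#' (0.1 Hz for the default 10 s).
#'
#' @param trials Numeric matrix `trials x samples` (or a vector for one
#'   trial), e.g. from [ress_project()].
#' @param fs Sampling rate (Hz).
#' @param tukey_alpha Tapered fraction of the Tukey window.
#' @param pad_to Padded length in seconds; must be at least the data
#'   length.
#' @return An object of class `fpvs_spectrum`: complex coefficients
#'   `trials x bins` and the frequency grid from 0 Hz.
#' @export
spectrum_fft <- function(trials, fs, tukey_alpha = 0.25, pad_to = 10) {
  if (is.null(dim(trials))) trials <- matrix(trials, 1)
  ns <- ncol(trials)
  N <- as.integer(round(pad_to * fs))
  if (N < ns) abort("`pad_to` is shorter than the data.",
                    class = "fpvs_config_error")
  w <- tukey_window(ns, tukey_alpha)
  padded <- matrix(0, N, nrow(trials))
  padded[seq_len(ns), ] <- t(trials) * w
  coef <- t(mvfft(padded))
  structure(list(coef = coef, freq = (seq_len(N) - 1) * fs / N, fs = fs,
                 n_time = ns, window = w),
            class = "fpvs_spectrum")
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("<fpvs_spectrum> %d trials, %.3g Hz resolution up to %g Hz\n",
              nrow(x$coef), x$freq[2], max(x$freq)))
  invisible(x)
}

spectrum_bin <- function(spec, f, tol = 1e-9) {
  bin <- which(abs(spec$freq - f) < tol)
  if (length(bin) != 1) {
    abort(sprintf("Frequency %g Hz is not on the %g Hz grid.", f, spec$freq[2]),
          class = "fpvs_grid_error")
  }
  bin
}

#' Per-trial Fourier phases at one frequency
#'
#' The angle of the complex Fourier coefficient at the exact requested
#' grid frequency (no nearest-bin snapping).
#'
#' @param spec An `fpvs_spectrum`.
#' @param f Frequency in Hz; must lie on the spectrum's grid.
#' @return A [phase_set()] of per-trial angles in `(-pi, pi]`.
#' @export
phase_at <- function(spec, f) {
  phase_set(Arg(spec$coef[, spectrum_bin(spec, f)]))
}

#' Per-trial amplitudes at one frequency
#'
#' Window-compensated amplitude of the coefficient at the exact grid
#' frequency (a unit sinusoid maps to approximately 1).
#'
#' @inheritParams phase_at
#' @return Numeric vector of per-trial amplitudes.
#' @export
amplitude_at <- function(spec, f) {
  2 * Mod(spec$coef[, spectrum_bin(spec, f)]) / sum(spec$window)
}

#' Export filter weights and topography as TSV
#'
#' @param filter An `fpvs_filter`.
#' @param path Output path.
#' @return The filter, invisibly.
#' @export
write_filter_tsv <- function(filter, path) {
  readr::write_tsv(tibble(channel = names(filter$weights),
                          weight = unname(filter$weights),
                          topography = unname(filter$topography)), path)
  invisible(filter)
}
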