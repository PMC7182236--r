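#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used for the trial-to-trial phase of
#' the regularity-driven source, whose concentration `kappa` controls the
#' planted inter-trial phase clustering.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0; 0 is the circular uniform).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, n - length(out))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3 - 0.5)[ok] * acos(f[ok])
    out <- c(out, th)
  }
  ang <- out[seq_len(n)] + mu
  ((ang + pi) %% (2 * pi)) - pi
}

#' Expected cosine-similarity index under von Mises phases
#'
#' For independent trial phases with concentration `kappa`, the
#' expectation of `cos(theta_i - theta_j)` for any trial pair — and hence
#' of the CS index — is the squared Bessel ratio `(I1(kappa)/I0(kappa))^2`.
#' This is the analytic bridge between the simulator's planted
#' concentration and the CS statistic.
#'
#' @param kappa Von Mises concentration (>= 0).
#' @param n Trial count the CS would be computed from (must be >= 2; the
#'   expectation itself does not depend on it).
#' @return The expected CS in `[0, 1]`.
#' @examples
#' expected_cs(0)   # uniform phases: 0
#' expected_cs(2)   # ~0.487
#' @export
expected_cs <- function(kappa, n = 2) {
  stopifnot(all(kappa >= 0))
  if (any(n < 2)) abort("`n` must be at least 2.", class = "fpvs_domain_error")
  r <- ifelse(is.infinite(kappa) | kappa > 1e5,
              # asymptotic ratio, exact to O(1/kappa^2); besselI loses
              # precision for very large arguments
              1 - 1 / (2 * pmax(kappa, 1)),
              besselI(kappa, 1, expon.scaled = TRUE) /
                besselI(kappa, 0, expon.scaled = TRUE))
  r <- ifelse(is.infinite(kappa), 1, r)
  r^2
}

#' Concentration producing a given expected CS
#'
#' Inverse of [expected_cs()]; used to plant condition effect sizes on
#' the CS scale.
#'
#' @param cs Target expected CS in `[0, 1)`.
#' @return The von Mises concentration.
#' @export
kappa_for_cs <- function(cs) {
  stopifnot(cs >= 0, cs < 1)
  if (cs == 0) return(0)
  uniroot(function(k) expected_cs(k) - cs, c(1e-8, 1e4), tol = 1e-10)$root
}

# Smooth unit-norm scalp field: Gaussian in angular distance from a pole.
topography_bump <- function(montage, center, width = 0.8) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  p <- p / sqrt(rowSums(p^2))
  ang <- acos(pmin(pmax(p %*% center / sqrt(sum(center^2)), -1), 1))
  w <- exp(-(ang / width)^2)
  w[montage$type != "scalp"] <- 0
  as.vector(w / sqrt(sum(w^2)))
}

#' Forward model for the synthetic EEG
#'
#' Defines where the simulated sources project on the scalp and how the
#' background noise is spatially correlated. The stimulation- and
#' regularity-driven sources get parieto-occipital fields (slightly
#' offset from one another), the alpha source a broader occipito-parietal
#' field; all are unit-norm channel vectors. Channel noise is correlated
#' by distance (`exp(-angle / lambda)`), which is symmetric positive
#' definite by construction.
#'
#' @param montage Channel tibble from [synthetic_montage()].
#' @param noise_lambda Spatial correlation length of the noise, in
#'   radians of inter-electrode angle.
#' @return An object of class `fpvs_forward_model`.
#' @export
forward_model <- function(montage, noise_lambda = 0.7) {
  occ <- c(0, -0.85, 0.55)   # parieto-occipital pole
  occ2 <- c(0.25, -0.8, 0.6) # regularity source, offset laterally
  par <- c(0, -0.5, 0.9)
  cs <- montage_cosines(montage)
  corr <- exp(-acos(cs) / noise_lambda)
  # EOG channels decorrelated from the scalp beyond geometry
  eog <- montage$type == "eog"
  corr[eog, !eog] <- corr[eog, !eog] * 0.3
  corr[!eog, eog] <- corr[!eog, eog] * 0.3
  corr <- corr + diag(1e-6, nrow(corr))
  structure(
    list(montage = montage,
         topo_stim = topography_bump(montage, occ, 0.7),
         topo_reg = topography_bump(montage, occ2, 0.7),
         topo_alpha = topography_bump(montage, par, 1.1),
         noise_corr = corr,
         noise_chol = t(chol(corr))),
    class = "fpvs_forward_model")
}

#' Per-condition effect presets for the simulator
#'
#' Maps each condition cell of a design to a regularity-source amplitude
#' and phase concentration. Regular conditions are assigned
#' concentrations whose expected CS mirrors the magnitudes typical of
#' this paradigm (neutral above angry, high above low identity
#' variability, on the order of 0.02-0.09); irregular conditions have no
#' regularity source (`amp_reg = 0`). The mapping is a preset: pass your
#' own `cs` column to plant different effects.
#'
#' @param spec An [experiment_spec()].
#' @param cs Optional named numeric vector of target expected CS values,
#'   keyed `regularity` or `regularity.variability`.
#' @param amp_reg Regularity-source amplitude (microvolts) for regular
#'   conditions.
#' @return A tibble with one row per condition cell: factors, `amp_reg`,
#'   `kappa`, `mu` (mean phase).
#' @export
condition_effects <- function(spec, cs = NULL, amp_reg = 10) {
  base <- c(angry = 0.03, neutral = 0.05)
  varmul <- c(none = 1, high = 1.25, low = 0.75)
  cells <- spec$conditions
  key2 <- paste(cells$regularity, cells$variability, sep = ".")
  target <- ifelse(cells$regularity == "irregular", 0,
                   base[cells$regularity] * varmul[cells$variability])
  if (!is.null(cs)) {
    hit2 <- key2 %in% names(cs)
    target[hit2] <- cs[key2[hit2]]
    hit1 <- !hit2 & cells$regularity %in% names(cs)
    target[hit1] <- cs[cells$regularity[hit1]]
  }
  dplyr::mutate(cells,
                amp_reg = ifelse(cells$regularity == "irregular", 0, amp_reg),
                kappa = purrr::map_dbl(pmin(target, 0.999), kappa_for_cs),
                mu = 0)
}

#' Simulation configuration
#'
#' Collects the signal, noise and artifact parameters of the forward
#' simulation. Amplitudes are source amplitudes in microvolts (the
#' unit-norm topographies distribute them over channels); background
#' noise is `1/f^beta` with RMS `noise_sd` per channel plus a 10 Hz alpha
#' rhythm; ocular artifacts are 400 ms raised-cosine transients on the
#' EOG channels with 10 percent leakage into the scalp.
#'
#' @param f_stim Stimulation rate (Hz).
#' @param f_reg Regularity rate (Hz); must equal `f_stim / 3`.
#' @param sampling_rate Sampling rate (Hz).
#' @param effects Per-condition effect tibble from [condition_effects()].
#' @param amp_stim Stimulation-source amplitude (microvolts).
#' @param kappa_stim Phase concentration of the stimulation response
#'   (large: tightly stimulus-locked).
#' @param noise_sd Per-channel RMS of the background noise (microvolts);
#'   0 disables noise.
#' @param noise_exponent Spectral slope beta of the `1/f^beta` noise.
#' @param alpha_amp Alpha-source amplitude (microvolts).
#' @param alpha_freq Alpha frequency (Hz).
#' @param blink_rate Blink events per minute on the EOG channels.
#' @param blink_amp Blink peak amplitude (microvolts).
#' @return An object of class `fpvs_sim_config`.
#' @export
simulation_config <- function(f_stim, f_reg = f_stim / 3, sampling_rate = 256,
                              effects = NULL, amp_stim = 20, kappa_stim = 50,
                              noise_sd = 10, noise_exponent = 1,
                              alpha_amp = 5, alpha_freq = 10,
                              blink_rate = 0, blink_amp = 200) {
  if (abs(f_reg - f_stim / 3) > 1e-9) {
    abort("`f_reg` must equal `f_stim / 3`.", class = "fpvs_config_error")
  }
  if (!is.null(effects) && any(effects$amp_reg[effects$regularity == "irregular"] != 0)) {
    abort("Irregular conditions must have `amp_reg = 0`.",
          class = "fpvs_config_error")
  }
  if (!is.null(effects) && any(effects$kappa < 0)) {
    abort("`kappa` must be non-negative.", class = "fpvs_config_error")
  }
  structure(list(f_stim = f_stim, f_reg = f_reg, sampling_rate = sampling_rate,
                 effects = effects, amp_stim = amp_stim,
                 kappa_stim = kappa_stim, noise_sd = noise_sd,
                 noise_exponent = noise_exponent, alpha_amp = alpha_amp,
                 alpha_freq = alpha_freq, blink_rate = blink_rate,
                 blink_amp = blink_amp),
            class = "fpvs_sim_config")
}

# 1/f^beta noise, spatially colored by the Cholesky factor of the noise
# correlation: white channel noise is shaped in the frequency domain
# (exact spectral control), then mixed across channels.
colored_noise <- function(model, n_ch, n_samp, fs, sd_target, beta) {
  white <- matrix(rnorm(n_ch * n_samp), n_samp, n_ch)
  f <- seq(0, fs - fs / n_samp, length.out = n_samp)
  f[f > fs / 2] <- fs - f[f > fs / 2]
  gain <- c(0, f[-1]^(-beta / 2))
  shaped <- Re(mvfft(mvfft(white) * gain, inverse = TRUE)) / n_samp
  shaped <- shaped / sqrt(mean(shaped^2)) * sd_target
  t(model$noise_chol %*% t(shaped))
}

raised_cosine <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

#' Simulate one EEG trial
#'
#' Forward-simulates a channels x samples epoch for one stimulus
#' sequence: a stimulation-rate sinusoid on the stimulation topography, a
#' regularity-rate sinusoid (regular conditions only) whose trial phase
#' is von Mises with the condition's concentration, spatially correlated
#' `1/f^beta` noise, an alpha rhythm and optional EOG blinks.
#'
#' @param sequence A [build_sequence()] result (supplies condition and
#'   trial duration), or a bare condition list together with `duration`.
#' @param model A [forward_model()].
#' @param config A [simulation_config()] with `effects` covering the
#'   sequence's condition.
#' @param seed Optional integer seed.
#' @param duration Trial duration in seconds (only when `sequence` is a
#'   bare condition list).
#' @return A numeric matrix `channels x samples` (microvolts), channel
#'   names from the montage.
#' @export
simulate_trial <- function(sequence, model, config, seed = NULL,
                           duration = NULL) {
  if (inherits(sequence, "fpvs_sequence")) {
    cond <- attr(sequence, "condition")
    duration <- nrow(sequence) / config$f_stim
  } else {
    cond <- as.list(sequence)
    if (is.null(duration)) abort("`duration` required for a bare condition.")
  }
  eff <- config$effects
  if (!is.null(eff)) {
    row <- eff[eff$orientation == cond$orientation &
                 eff$regularity == cond$regularity &
                 eff$variability == cond$variability, ]
    if (nrow(row) != 1) abort("Condition has no configured effects.",
                              class = "fpvs_config_error")
  } else {
    row <- tibble(amp_reg = 0, kappa = 0, mu = 0)
  }
  with_seed(seed, {
    fs <- config$sampling_rate
    # sample instants k/fs for k = 0..floor(duration * fs): a 0-3.8 s
    # epoch at 256 Hz holds 973 samples
    ns <- as.integer(floor(duration * fs + 1e-9)) + 1L
    t <- (seq_len(ns) - 1) / fs
    n_ch <- nrow(model$montage)
    x <- matrix(0, n_ch, ns)
    if (config$amp_stim > 0) {
      phi <- rvonmises(1, 0, config$kappa_stim)
      x <- x + model$topo_stim %o% (config$amp_stim * sin(2 * pi * config$f_stim * t + phi))
    }
    if (row$amp_reg > 0) {
      theta <- rvonmises(1, row$mu, row$kappa)
      x <- x + model$topo_reg %o% (row$amp_reg * sin(2 * pi * config$f_reg * t + theta))
    }
    if (config$alpha_amp > 0) {
      x <- x + model$topo_alpha %o%
        (config$alpha_amp * sin(2 * pi * config$alpha_freq * t + runif(1, -pi, pi)))
    }
    if (config$noise_sd > 0) {
      x <- x + t(colored_noise(model, n_ch, ns, fs, config$noise_sd,
                               config$noise_exponent))
    }
    if (config$blink_rate > 0) {
      n_blink <- rpois(1, config$blink_rate * duration / 60)
      if (n_blink > 0) {
        wlen <- round(0.4 * fs)
        eog <- model$montage$type == "eog"
        leak <- ifelse(eog, 1, 0.1)
        for (b in seq_len(n_blink)) {
          start <- sample.int(max(1L, ns - wlen), 1)
          span <- start:min(ns, start + wlen - 1L)
          wave <- config$blink_amp * raised_cosine(wlen)[seq_along(span)]
          x[, span] <- x[, span] + leak %o% wave
        }
      }
    }
    rownames(x) <- model$montage$channel
    x
  })
}

#' Simulate a whole session
#'
#' One epoch per trial of the plan, labels carried through.
#'
#' @param plan A session plan from [build_session_plan()] (optionally
#'   with targets scheduled).
#' @param model A [forward_model()].
#' @param config A [simulation_config()].
#' @param seed Optional integer seed; the same seed reproduces the epoch
#'   set exactly.
#' @return An [epoch_set()] of `nrow(plan)` epochs.
#' @export
simulate_experiment <- function(plan, model, config, seed = NULL) {
  n <- nrow(plan)
  fs <- config$sampling_rate
  info_cols <- intersect(c("trial", "orientation", "regularity", "variability",
                           "condition", "target_trial"), names(plan))
  if (n == 0) {
    dur <- 0L
    return(epoch_set(array(0, c(0, nrow(model$montage), 0)),
                     plan[info_cols], model$montage, fs))
  }
  seeds <- child_seeds(seed, n)
  ns <- as.integer(floor(nrow(plan$cycles[[1]]) / config$f_stim * fs + 1e-9)) + 1L
  arr <- array(0, c(n, nrow(model$montage), ns))
  for (i in seq_len(n)) {
    arr[i, , ] <- simulate_trial(plan$cycles[[i]], model, config,
                                 seed = seeds[[i]])
  }
  epoch_set(arr, plan[info_cols], model$montage, fs)
}
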