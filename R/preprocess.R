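#' Artifact-screening parameters
#'
#' Thresholds of the z-score screening cascade: channel and epoch metrics
#' are z-scored and flagged beyond `z_threshold`; epoch kurtosis is
#' flagged beyond `kurtosis_sd` standard deviations of the single- and
#' all-channel means; epochs with more than `max_interpolated` repaired
#' channels are discarded; epoch spectra may not deviate from the
#' subject's baseline by more than 50 dB in the 0-2 Hz window (blinks) or
#' +25/-100 dB in the 20-40 Hz window (muscle).
#'
#' @param z_threshold Two-sided z cutoff for channel/epoch metrics.
#' @param kurtosis_sd SD cutoff for the kurtosis screen.
#' @param max_interpolated Maximum repaired channels per epoch.
#' @param spectral_windows List of `(lo, hi, max_up, max_down)` dB rules.
#' @return A list of class `fpvs_screening_params`.
#' @export
screening_params <- function(z_threshold = 3, kurtosis_sd = 5,
                             max_interpolated = 12,
                             spectral_windows = list(
                               c(lo = 0, hi = 2, up = 50, down = 50),
                               c(lo = 20, hi = 40, up = 25, down = 100))) {
  stopifnot(z_threshold > 0, kurtosis_sd > 0, max_interpolated > 0)
  structure(list(z_threshold = z_threshold, kurtosis_sd = kurtosis_sd,
                 max_interpolated = max_interpolated,
                 spectral_windows = spectral_windows),
            class = "fpvs_screening_params")
}

#' Re-reference an epoch set
#'
#' Average mode subtracts the mean over scalp electrodes (EOG channels
#' are left untouched); channel mode subtracts one electrode's trace.
#'
#' @param epochs An [epoch_set()].
#' @param mode `"average"` or `"channel"`.
#' @param channel Reference electrode label for channel mode.
#' @return The re-referenced epoch set.
#' @export
rereference <- function(epochs, mode = c("average", "channel"),
                        channel = "Cz") {
  mode <- match.arg(mode)
  scalp <- epochs$montage$type == "scalp"
  d <- dim(epochs$data)
  if (mode == "average") {
    ref <- colMeans(aperm(epochs$data[, scalp, , drop = FALSE], c(2, 1, 3)))
  } else {
    idx <- match(channel, epochs$montage$channel)
    if (is.na(idx)) abort(paste0("No channel '", channel, "' in montage."))
    ref <- epochs$data[, idx, ]
    dim(ref) <- c(d[1], d[3])
  }
  for (ch in which(scalp)) epochs$data[, ch, ] <- epochs$data[, ch, ] - ref
  epochs
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# median/MAD z: immune to masking when many channels of one epoch are
# corrupted at once (a mean/sd z over 64 channels can never flag more
# than ~7, which would make the 12-channel discard rule unreachable)
zscore_robust <- function(x) {
  m <- median(x)
  s <- mad(x, center = m)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - m) / s
}

# Remove the smooth spatial trend a reference choice imprints on channel
# metrics (e.g. vanishing variance near the reference electrode):
# residuals of a quadratic surface in electrode position.
# Residuals of v against a design matrix, refit once without gross
# outliers so corrupted channels cannot drag the trend toward themselves.
resid_robust <- function(v, X) {
  ok <- is.finite(v)
  if (sum(ok) < 4 * ncol(X)) return(ifelse(ok, v - median(v[ok]), 0))
  res <- rep(0, length(v))
  res[ok] <- stats::lm.fit(X[ok, , drop = FALSE], v[ok])$residuals
  keep <- ok & abs(zscore_robust(res)) <= 3
  if (sum(keep) >= 2 * ncol(X) && any(ok & !keep)) {
    beta <- stats::lm.fit(X[keep, , drop = FALSE], v[keep])$coefficients
    beta[is.na(beta)] <- 0
    res[ok] <- v[ok] - X[ok, , drop = FALSE] %*% beta
  }
  res[!ok] <- 0
  res
}

spatial_resid <- function(v, pos) {
  # quadratic surface; z^2 dropped (collinear with the intercept on the
  # unit sphere)
  resid_robust(v, cbind(1, pos, pos[, 1]^2, pos[, 2]^2,
                        pos[, 1] * pos[, 2], pos[, 1] * pos[, 3],
                        pos[, 2] * pos[, 3]))
}

# Detrended fluctuation analysis over dyadic windows; the slope of
# log F(s) against log s estimates the Hurst exponent.
dfa_hurst <- function(x, scales = 2^(4:8)) {
  x <- x[seq_len(min(length(x), 32768L))]
  y <- cumsum(x - mean(x))
  fl <- purrr::map_dbl(scales, function(s) {
    nwin <- length(y) %/% s
    if (nwin < 2) return(NA_real_)
    Y <- matrix(y[seq_len(nwin * s)], s, nwin)
    X <- cbind(1, seq_len(s))
    R <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
    sqrt(mean(R^2))
  })
  ok <- is.finite(fl) & fl > 0
  if (sum(ok) < 2) return(0.5)
  coef(lm(log(fl[ok]) ~ log(scales[ok])))[[2]]
}

#' Screen channels over the whole recording
#'
#' Computes, per scalp channel over all concatenated epochs: variance,
#' mean correlation with the other scalp channels, and the Hurst exponent
#' (by detrended fluctuation analysis). Each metric is z-scored across
#' channels; channels beyond the two-sided threshold on any metric are
#' flagged for interpolation.
#'
#' @param epochs An [epoch_set()].
#' @param params [screening_params()].
#' @return Character vector of flagged channel labels, with the z-score
#'   table attached as attribute `"metrics"`.
#' @export
screen_channels <- function(epochs, params = screening_params()) {
  scalp <- which(epochs$montage$type == "scalp")
  if (length(scalp) < 4) abort("Need at least 4 scalp channels.")
  d <- dim(epochs$data)
  mat <- matrix(aperm(epochs$data[, scalp, , drop = FALSE], c(3, 1, 2)),
                d[1] * d[3], length(scalp))
  colnames(mat) <- epochs$montage$channel[scalp]
  v <- apply(mat, 2, var)
  if (all(v == 0)) {
    warn("Recording is constant; channel screening is not meaningful.")
    return(character(0))
  }
  cm <- cor(mat)
  diag(cm) <- NA
  mean_cor <- colMeans(cm, na.rm = TRUE)
  hurst <- apply(mat, 2, dfa_hurst)
  pos <- as.matrix(epochs$montage[scalp, c("x", "y", "z")])
  z <- cbind(variance = zscore(spatial_resid(log(pmax(v, 1e-300)), pos)),
             correlation = zscore(spatial_resid(mean_cor, pos)),
             hurst = zscore(hurst))
  # correlation flags the low side only: a channel agreeing with its
  # neighbours unusually well is not an artifact
  hit <- abs(z[, "variance"]) > params$z_threshold |
    z[, "correlation"] < -params$z_threshold |
    abs(z[, "hurst"]) > params$z_threshold
  flagged <- colnames(mat)[hit]
  attr(flagged, "metrics") <- as_tibble(cbind(
    tibble(channel = colnames(mat)), as.data.frame(z)))
  flagged
}

moment_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}

# per-epoch, per-channel summary stats on the scalp block
epoch_channel_stats <- function(data, scalp) {
  n <- dim(data)[1]
  rng <- apply(data[, scalp, , drop = FALSE], c(1, 2), function(x) diff(range(x)))
  vr <- apply(data[, scalp, , drop = FALSE], c(1, 2), var)
  chmean <- apply(data[, scalp, , drop = FALSE], c(1, 2), mean)
  list(range = rng, var = vr, chmean = chmean)
}

#' Screen and repair epochs
#'
#' The epoch-level artifact cascade, applied in order: (ii) whole-epoch
#' rejection when the channel-mean amplitude range, variance or channel
#' deviation is a z-outlier across epochs; (iii) within-epoch channel
#' repair: channels whose variance, median gradient, amplitude range or
#' deviation is a z-outlier within the epoch are spherical-spline
#' interpolated; (iv) per-condition rejection on the same epoch metrics
#' plus the maximum absolute EOG value, z-scored within condition; (v)
#' rejection of epochs with more than `max_interpolated` repaired
#' channels; then the kurtosis screen (single- and all-channel mean, in
#' SD units) and the spectral-deviation screen against the median
#' log-spectrum baseline.
#'
#' @param epochs An [epoch_set()] (channel screening already applied).
#' @param params [screening_params()].
#' @return A list of class `fpvs_screening` with elements `epochs` (the
#'   retained, repaired epochs), and `report` (an `fpvs_report`: per-epoch
#'   verdicts with reason codes, interpolated channels, and per-condition
#'   rejection percentages).
#' @export
screen_epochs <- function(epochs, params = screening_params()) {
  d <- dim(epochs$data)
  n <- d[1]
  scalp <- which(epochs$montage$type == "scalp")
  eog <- which(epochs$montage$type == "eog")
  cond <- if ("condition" %in% names(epochs$info)) epochs$info$condition
          else rep("all", n)
  trial_id <- if ("trial" %in% names(epochs$info)) epochs$info$trial
              else seq_len(n)
  reasons <- vector("list", n)
  interp <- vector("list", n)

  st <- epoch_channel_stats(epochs$data, scalp)
  grand_channel_mean <- colMeans(st$chmean)
  dev <- abs(sweep(st$chmean, 2, grand_channel_mean))

  # (ii) epoch-level: mean across channels of range / variance / deviation
  m_rng <- rowMeans(st$range); m_var <- rowMeans(st$var); m_dev <- rowMeans(dev)
  z2 <- cbind(amplitude_range = zscore(m_rng), variance = zscore(m_var),
              channel_deviation = zscore(m_dev))
  for (i in seq_len(n)) {
    hit <- colnames(z2)[abs(z2[i, ]) > params$z_threshold]
    reasons[[i]] <- c(reasons[[i]], hit)
  }
  alive <- lengths(reasons) == 0

  # (iii) within-epoch channel repair
  for (i in which(alive)) {
    # metrics are assessed on an average-referenced copy: a point
    # reference (e.g. Cz) imprints a steep distance gradient on every
    # scale metric that the z-screen would misread as outliers; the
    # repair below still happens in the data's own reference frame
    x <- epochs$data[i, scalp, ]
    x <- sweep(x, 2, colMeans(x))
    vr <- apply(x, 1, var)
    live_ch <- vr > 1e-12
    mg <- apply(x, 1, function(ch) median(abs(diff(ch))))
    lv <- log(vr); lv[!live_ch] <- NA
    metrics <- cbind(lv, log(pmax(mg, 1e-300)),
                     log(pmax(apply(x, 1, function(ch)
                       diff(range(ch))), 1e-300)),
                     rowMeans(x) - mean(x))
    # two-stage flagging: a median/MAD z at a high cutoff catches gross
    # corruption without masking (a mean/sd z over 64 channels can never
    # flag more than ~7, which would make the 12-channel discard rule
    # unreachable); the ordinary z = +/-3 screen then runs with mean and
    # sd taken over the non-gross channels
    z_rob <- apply(metrics, 2, zscore_robust)
    gross <- rowSums(abs(z_rob) > 8) > 0
    z_std <- apply(metrics, 2, function(v) {
      ref <- v[!gross & is.finite(v)]
      if (length(ref) < 4 || sd(ref) == 0) return(rep(0, length(v)))
      ifelse(is.finite(v), (v - mean(ref)) / sd(ref), 0)
    })
    flag <- (gross | rowSums(abs(z_std) > params$z_threshold) > 0) & live_ch
    bad <- epochs$montage$channel[scalp][flag]
    interp[[i]] <- bad
    if (length(bad) > 0 && length(bad) <= params$max_interpolated) {
      one <- subset_epochs(epochs, i)
      one <- interpolate_channels(one, bad)
      epochs$data[i, , ] <- one$data[1, , ]
    }
  }

  # (iv) per-condition screening, including max EOG amplitude
  st2 <- epoch_channel_stats(epochs$data, scalp)
  dev2 <- abs(sweep(st2$chmean, 2, colMeans(st2$chmean)))
  eog_max <- if (length(eog)) {
    apply(abs(epochs$data[, eog, , drop = FALSE]), 1, max)
  } else rep(0, n)
  for (cl in unique(cond)) {
    idx <- which(cond == cl & alive)
    if (length(idx) < 2) next
    z4 <- cbind(amplitude_range = abs(zscore(rowMeans(st2$range[idx, , drop = FALSE]))),
                variance = abs(zscore(rowMeans(st2$var[idx, , drop = FALSE]))),
                channel_deviation = abs(zscore(rowMeans(dev2[idx, , drop = FALSE]))),
                # one-sided: only abnormally large ocular activity is an
                # artifact, a quiet EOG channel is not
                eog_max = pmax(zscore(eog_max[idx]), 0))
    for (j in seq_along(idx)) {
      hit <- colnames(z4)[z4[j, ] > params$z_threshold]
      reasons[[idx[j]]] <- c(reasons[[idx[j]]], hit)
    }
  }
  alive <- lengths(reasons) == 0

  # (v) over-interpolated epochs
  over <- lengths(interp) > params$max_interpolated
  for (i in which(over & alive)) reasons[[i]] <- c(reasons[[i]], "over_interpolated")
  alive <- lengths(reasons) == 0

  # kurtosis screen: an epoch is discarded when a channel's kurtosis
  # deviates beyond the cutoff from both its own channel's mean and the
  # all-channel mean (spikes or flat stretches)
  ku <- apply(epochs$data[, scalp, , drop = FALSE], c(1, 2), moment_kurtosis)
  sc_mean <- colMeans(ku); sc_sd <- apply(ku, 2, sd)
  sc_sd[sc_sd == 0] <- Inf
  z_sc <- abs(sweep(sweep(ku, 2, sc_mean), 2, sc_sd, "/"))
  ac_sd <- sd(ku)
  z_ac <- if (ac_sd > 0) abs(ku - mean(ku)) / ac_sd else ku * 0
  bad_k <- rowSums(z_sc > params$kurtosis_sd & z_ac > params$kurtosis_sd) > 0
  for (i in which(bad_k & alive)) reasons[[i]] <- c(reasons[[i]], "kurtosis")
  alive <- lengths(reasons) == 0

  # spectral-deviation screen against the median log-spectrum baseline
  freqs <- (seq_len(d[3]) - 1) * epochs$sampling_rate / d[3]
  spec_db <- matrix(0, n, d[3])
  for (i in seq_len(n)) {
    p <- abs(mvfft(t(epochs$data[i, scalp, ])))^2
    spec_db[i, ] <- 10 * log10(pmax(rowMeans(p), 1e-300))
  }
  base <- apply(spec_db, 2, median)
  devi <- sweep(spec_db, 2, base)
  for (w in params$spectral_windows) {
    sel <- freqs >= w[["lo"]] & freqs <= w[["hi"]]
    if (!any(sel)) next
    hit <- apply(devi[, sel, drop = FALSE], 1, function(x)
      any(x > w[["up"]]) || any(x < -w[["down"]]))
    for (i in which(hit & alive)) reasons[[i]] <- c(reasons[[i]], "spectral_deviation")
    alive <- lengths(reasons) == 0
  }

  report <- new_rejection_report(trial_id, cond, reasons, interp)
  if (any(!alive)) {
    lost <- setdiff(unique(cond), unique(cond[alive]))
    if (length(lost)) {
      warn(paste0("All epochs rejected in condition(s): ",
                  paste(lost, collapse = ", ")))
    }
  }
  structure(list(epochs = subset_epochs(epochs, which(alive)),
                 report = report),
            class = "fpvs_screening")
}

new_rejection_report <- function(trial_id, cond, reasons, interp) {
  tbl <- tibble(
    epoch = trial_id, condition = cond,
    rejected = lengths(reasons) > 0,
    reasons = purrr::map_chr(reasons, ~ paste(unique(.x), collapse = ";")),
    n_interpolated = lengths(interp),
    interpolated = purrr::map(interp, identity)
  )
  pct <- dplyr::summarise(dplyr::group_by(tbl, .data$condition),
                          n = dplyr::n(), n_rejected = sum(.data$rejected),
                          pct_rejected = 100 * mean(.data$rejected),
                          .groups = "drop")
  structure(list(epochs = tbl, by_condition = pct), class = "fpvs_report")
}

#' @export
print.fpvs_report <- function(x, ...) {
  cat(sprintf("<fpvs_report> %d/%d epochs rejected\n",
              sum(x$epochs$rejected), nrow(x$epochs)))
  print(x$by_condition)
  invisible(x)
}

#' Full preprocessing cascade
#'
#' Average-references the recording, screens and repairs bad channels
#' over the whole recording, re-references to `Cz`, runs the epoch
#' screening cascade, and finally re-references the retained epochs to
#' the average of the scalp electrodes.
#'
#' @param epochs An [epoch_set()].
#' @param params [screening_params()].
#' @return A list of class `fpvs_screening` with `epochs`, `report` and
#'   `bad_channels`.
#' @export
preprocess <- function(epochs, params = screening_params()) {
  epochs <- rereference(epochs, "average")
  bad <- screen_channels(epochs, params)
  epochs <- interpolate_channels(epochs, bad)
  epochs <- rereference(epochs, "channel", "Cz")
  res <- screen_epochs(epochs, params)
  res$epochs <- rereference(res$epochs, "average")
  res$bad_channels <- bad
  res
}

#' Write a rejection report to JSON and/or TSV
#'
#' @param report An `fpvs_report`.
#' @param json,tsv Output paths (either may be `NULL`). The TSV holds the
#'   per-condition rejection percentages; the JSON the full per-epoch
#'   verdicts.
#' @return The report, invisibly.
#' @export
write_rejection_report <- function(report, json = NULL, tsv = NULL) {
  if (!is.null(tsv)) readr::write_tsv(report$by_condition, tsv)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(epochs = report$epochs[, c("epoch", "condition", "rejected",
                                      "reasons", "n_interpolated")],
           by_condition = report$by_condition),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
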