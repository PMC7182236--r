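#' Construct an epoch set
#'
#' The package's container for segmented multichannel EEG: a
#' trials x channels x samples array in microvolts, the per-trial
#' condition info, the montage and the sampling rate.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param info Tibble with one row per trial; must at least hold
#'   `trial` and `condition` (condition factors are carried through the
#'   pipeline when present).
#' @param montage Channel tibble as from [synthetic_montage()]; its rows
#'   must match the channel dimension.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `fpvs_epochs`.
#' @export
epoch_set <- function(data, info, montage, sampling_rate) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3-d array.")
  if (dim(data)[1] != nrow(info)) abort("`info` rows must match trials.")
  if (dim(data)[2] != nrow(montage)) abort("`montage` rows must match channels.")
  dimnames(data) <- list(NULL, montage$channel, NULL)
  structure(list(data = data, info = as_tibble(info),
                 montage = as_tibble(montage),
                 sampling_rate = sampling_rate),
            class = "fpvs_epochs")
}

#' @export
print.fpvs_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fpvs_epochs> %d trials x %d channels x %d samples @ %g Hz (%.3g s)\n",
              d[1], d[2], d[3], x$sampling_rate, d[3] / x$sampling_rate))
  if ("condition" %in% names(x$info) && d[1] > 0) {
    tb <- table(x$info$condition)
    cat("  conditions: ",
        paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.fpvs_epochs <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

# Time axis in seconds, first sample at t = 0 (RSVP onset).
epoch_times <- function(x) (seq_len(n_samples(x)) - 1) / x$sampling_rate

#' Subset epochs by trial-info predicates
#'
#' dplyr-style filtering on the per-trial info table; the data array is
#' subset to the matching trials.
#'
#' @param x An `fpvs_epochs` object.
#' @param ... Logical predicates evaluated in the info tibble.
#' @return The filtered `fpvs_epochs`.
#' @examples
#' # filter_epochs(ep, regularity != "irregular", !target_trial)
#' @export
filter_epochs <- function(x, ...) {
  keep <- which(purrr::reduce(
    purrr::map(rlang::enquos(...), ~ rlang::eval_tidy(.x, data = x$info)),
    `&`, .init = rep(TRUE, n_trials(x))))
  subset_epochs(x, keep)
}

subset_epochs <- function(x, trials) {
  x$data <- x$data[trials, , , drop = FALSE]
  x$info <- x$info[trials, ]
  x
}

subset_channels <- function(x, channels) {
  idx <- match(channels, x$montage$channel)
  if (anyNA(idx)) abort("Unknown channel(s) requested.")
  x$data <- x$data[, idx, , drop = FALSE]
  x$montage <- x$montage[idx, ]
  x
}

#' Tidy long view of an epoch set
#'
#' @param x An `fpvs_epochs` object.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `channel`, `time` (s),
#'   `amplitude` (microvolts) joined to the trial info.
#' @export
as_tibble.fpvs_epochs <- function(x, ...) {
  d <- dim(x$data)
  out <- tibble(
    trial = rep(x$info$trial, times = d[2] * d[3]),
    channel = rep(rep(x$montage$channel, each = d[1]), times = d[3]),
    time = rep(epoch_times(x), each = d[1] * d[2]),
    amplitude = as.vector(x$data)
  )
  dplyr::left_join(out, x$info, by = "trial")
}

#' Write / read an epoch set (Parquet)
#'
#' Columnar serialization of the long view plus montage and metadata via
#' the `arrow` package.
#'
#' @param x An `fpvs_epochs` object.
#' @param dir Directory to write to / read from.
#' @return `write_epoch_set` returns `x` invisibly; `read_epoch_set`
#'   returns an `fpvs_epochs`.
#' @export
write_epoch_set <- function(x, dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("Package 'arrow' is required for epoch-set serialization.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arrow::write_parquet(as_tibble(x), file.path(dir, "epochs.parquet"))
  arrow::write_parquet(x$montage, file.path(dir, "montage.parquet"))
  jsonlite::write_json(list(sampling_rate = x$sampling_rate, dims = dim(x$data)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(x)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("Package 'arrow' is required for epoch-set serialization.")
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  long <- arrow::read_parquet(file.path(dir, "epochs.parquet"))
  montage <- as_tibble(arrow::read_parquet(file.path(dir, "montage.parquet")))
  d <- meta$dims
  arr <- array(long$amplitude, dim = d)
  info_cols <- setdiff(names(long), c("channel", "time", "amplitude"))
  info <- dplyr::distinct(long[long$channel == long$channel[1] &
                                 long$time == long$time[1], info_cols])
  epoch_set(arr, info, montage, meta$sampling_rate)
}
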