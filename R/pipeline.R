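#' Per-condition CS from an epoch set
#'
#' For each condition in the (truncated, detrended) epochs: fit a RESS
#' filter at the target frequency, project the trials through it, take
#' windowed zero-padded spectra and the phases at the exact frequency
#' bin, and compute CS and ITC.
#'
#' @param epochs An [epoch_set()], already truncated and detrended.
#' @param f Target frequency (Hz); must land on the 0.1 Hz padded grid.
#' @param params [filter_params()] for the spatial filter.
#' @param tukey_alpha,pad_to Passed to [spectrum_fft()].
#' @param common_filter Fit one filter on all trials instead of one per
#'   condition (off by default: per-condition filters are the primary
#'   analysis).
#' @return A tibble with one row per condition: factors, `n_trials`,
#'   `cs`, `itc`; phase sets are attached in the list column `phases`.
#' @export
cs_by_condition <- function(epochs, f, params = filter_params(),
                            tukey_alpha = 0.25, pad_to = 10,
                            common_filter = FALSE) {
  conds <- unique(epochs$info$condition)
  flt_all <- if (common_filter) ress_fit(epochs, f, params) else NULL
  rows <- purrr::map(conds, function(cl) {
    ep <- filter_epochs(epochs, .data$condition == cl)
    flt <- if (common_filter) flt_all else ress_fit(ep, f, params)
    spec <- spectrum_fft(ress_project(ep, flt), ep$sampling_rate,
                         tukey_alpha, pad_to)
    ph <- phase_at(spec, f)
    fac <- dplyr::distinct(ep$info[intersect(
      c("orientation", "regularity", "variability", "condition"),
      names(ep$info))])
    dplyr::mutate(fac, n_trials = ph$n,
                  cs = as.numeric(cs_index_closed(ph)), itc = itc(ph),
                  phases = list(ph))
  })
  dplyr::bind_rows(rows)
}

default_window <- function(spec) {
  analysis_window(0.5, if (spec$stimulation_rate >= 15) 3 else 6.5)
}

#' Simulate and analyse a full multi-participant study
#'
#' The end-to-end synthetic pipeline: for each participant, build a
#' session plan, schedule targets, simulate the epochs, drop target
#' trials, optionally run the artifact-screening cascade, truncate and
#' detrend, and compute per-condition CS at the regularity (and
#' optionally stimulation) frequency through per-condition RESS filters.
#'
#' @param spec An [experiment_spec()].
#' @param participants Number of simulated participants.
#' @param effects Per-condition effects ([condition_effects()]).
#' @param config A [simulation_config()]; built from `spec` and
#'   `effects` when `NULL`.
#' @param model A [forward_model()]; a default montage is used when
#'   `NULL`.
#' @param window [analysis_window()]; defaults to 3 s for 15 Hz designs
#'   and 6.5 s for 6 Hz designs, starting 0.5 s after RSVP onset.
#' @param frequencies `"regularity"`, `"stimulation"`, or both.
#' @param screen Run the artifact-screening cascade (slower); clean
#'   synthetic data can skip it.
#' @param conditions Optional subset of condition labels to simulate.
#' @param experiment Label recorded in the output.
#' @param seed Optional integer seed.
#' @return A tibble: `participant`, `experiment`, condition factors,
#'   `frequency`, `n_trials`, `cs`, `itc`.
#' @export
run_study <- function(spec, participants = 1,
                      effects = condition_effects(spec), config = NULL,
                      model = NULL, window = NULL,
                      frequencies = "regularity", screen = FALSE,
                      conditions = NULL, experiment = "synthetic",
                      seed = NULL) {
  if (is.null(model)) model <- forward_model(synthetic_montage())
  if (is.null(config)) {
    config <- simulation_config(f_stim = spec$stimulation_rate,
                                effects = effects)
  }
  if (is.null(window)) window <- default_window(spec)
  seeds <- child_seeds(seed, participants)
  freq_hz <- c(regularity = spec$regularity_rate,
               stimulation = spec$stimulation_rate)[frequencies]
  out <- purrr::map(seq_len(participants), function(p) {
    s2 <- child_seeds(seeds[[p]], 3)
    plan <- build_session_plan(spec, seed = s2[[1]])
    plan <- schedule_targets(plan, spec, seed = s2[[2]])
    if (!is.null(conditions)) plan <- plan[plan$condition %in% conditions, ]
    plan <- plan[!plan$target_trial, ]
    epochs <- simulate_experiment(plan, model, config, seed = s2[[3]])
    epochs <- if (screen) preprocess(epochs)$epochs
              else rereference(epochs, "average")
    epochs <- truncate_detrend(epochs, window)
    purrr::imap(freq_hz, function(f, fname) {
      res <- cs_by_condition(epochs, f)
      res$phases <- NULL
      dplyr::mutate(res, participant = p, experiment = experiment,
                    frequency = fname, .before = 1)
    })
  })
  dplyr::bind_rows(purrr::list_flatten(out))
}
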