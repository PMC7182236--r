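# Shared fixtures: montage and forward model are deterministic, build once.
fx_montage <- synthetic_montage()
fx_model <- forward_model(fx_montage)

# A reduced upright-only design: the post-target-discard trial count of
# the 15 Hz experiments (60 per condition) with the 9-identity pool.
small_spec <- function(trials = 20,
                       regularities = c("angry", "neutral", "irregular")) {
  experiment_spec(15, 3.8, trials_per_condition = trials,
                  orientations = "upright", regularities = regularities,
                  identities = list(none = paste0("id", 1:9)))
}

pilot1_cond <- function(regularity = "angry", orientation = "upright") {
  list(orientation = orientation, regularity = regularity,
       variability = "none")
}

# Simulated CS table with known cell means (delta planted on neutral).
make_cs_table <- function(n_subj = 16, delta = 0, sd_res = 0.02,
                          sd_subj = 0.01, base = 0.02) {
  cells <- tidyr::expand_grid(orientation = c("upright", "inverted"),
                              regularity = c("angry", "neutral", "irregular"))
  truth <- base + ifelse(cells$regularity == "neutral", delta, 0)
  dplyr::bind_rows(purrr::map(seq_len(n_subj), function(p) {
    dplyr::mutate(cells, participant = p,
                  cs = truth + rnorm(1, 0, sd_subj) +
                    rnorm(nrow(cells), 0, sd_res))
  }))
}

# Noise-free single-source epochs: a sinusoid at `f` on a fixed
# topography with per-trial phases `thetas`, optional white noise.
planted_epochs <- function(thetas, f, topo = fx_model$topo_reg, amp = 1,
                           noise_sd = 0, duration = 3, fs = 256,
                           montage = fx_montage) {
  ns <- as.integer(duration * fs)
  t <- (seq_len(ns) - 1) / fs
  n <- length(thetas)
  arr <- array(0, c(n, nrow(montage), ns))
  for (i in seq_len(n)) {
    arr[i, , ] <- topo %o% (amp * sin(2 * pi * f * t + thetas[i]))
    if (noise_sd > 0) {
      arr[i, , ] <- arr[i, , ] + rnorm(nrow(montage) * ns, sd = noise_sd)
    }
  }
  epoch_set(arr, tibble::tibble(trial = seq_len(n), condition = "planted"),
            montage, fs)
}
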