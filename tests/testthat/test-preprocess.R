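# small noisy epoch set shared by several screening tests
make_noise_epochs <- function(n = 12, seed = 1, ns = 512) {
  set.seed(seed)
  arr <- array(rnorm(n * 68 * ns), c(n, 68, ns))
  epoch_set(arr, tibble::tibble(trial = seq_len(n),
                                condition = rep(c("a", "b"), length.out = n)),
            fx_montage, 256)
}

test_that("re-referencing has the stated fixed points and is idempotent", {
  ep <- make_noise_epochs()
  avg <- rereference(ep, "average")
  scalp <- fx_montage$type == "scalp"
  means <- apply(avg$data[, scalp, ], c(1, 3), mean)
  expect_lt(max(abs(means)), 1e-10)
  expect_equal(rereference(avg, "average")$data, avg$data, tolerance = 1e-12)

  cz <- rereference(ep, "channel", "Cz")
  expect_true(all(abs(cz$data[, 1, ]) < 1e-12))
  expect_error(rereference(ep, "channel", "nope"))
})

test_that("channel screening flags planted variance outliers only", {
  ep <- make_noise_epochs(n = 8, seed = 3)
  ep$data[, 20, ] <- ep$data[, 20, ] * 10
  bad <- screen_channels(ep)
  expect_true(fx_montage$channel[20] %in% bad)

  # homogeneous iid channels: ~0.5 expected false flags over 64 channels
  # x 3 metrics at |z| > 3, so more than 3 has probability < 0.01
  clean <- make_noise_epochs(n = 8, seed = 4)
  expect_lte(length(screen_channels(clean)), 3)

  # a channel duplicating its neighbour has high, not low, correlation
  dup <- make_noise_epochs(n = 8, seed = 5)
  dup$data[, 21, ] <- dup$data[, 22, ]
  flagged <- screen_channels(dup)
  m <- attr(flagged, "metrics")
  expect_gt(m$correlation[21], 0)  # high agreement, not low
  expect_false(fx_montage$channel[21] %in% flagged)
})

test_that("spherical splines reconstruct smooth scalp fields", {
  # potential = smooth function of electrode position, identical samples
  scalp <- which(fx_montage$type == "scalp")
  field <- 2 * fx_montage$z + fx_montage$x^2 - 0.5 * fx_montage$y
  ns <- 64
  arr <- array(0, c(2, 68, ns))
  for (i in 1:2) arr[i, , ] <- field %o% (1 + 0.3 * sin(2 * pi * seq_len(ns) / ns + i))
  ep <- epoch_set(arr, tibble::tibble(trial = 1:2, condition = "x"),
                  fx_montage, 256)
  target <- fx_montage$channel[scalp[25]]
  interp <- interpolate_channels(ep, target)
  rel_rms <- sqrt(mean((interp$data[, scalp[25], ] - ep$data[, scalp[25], ])^2)) /
    sqrt(mean(ep$data[, scalp[25], ]^2))
  expect_lt(rel_rms, 0.01)
  # variance of the repaired channel stays within the neighbours' range
  expect_lte(var(as.vector(interp$data[, scalp[25], ])),
             max(apply(ep$data[, setdiff(scalp, scalp[25]), ], 2, var)))

  expect_identical(interpolate_channels(ep, character(0)), ep)
  expect_error(interpolate_channels(ep, "EXG1"))
  expect_error(interpolate_channels(ep, fx_montage$channel[scalp[1:20]]),
               class = "fpvs_interpolation_error")
})

test_that("identical epochs pass the whole cascade untouched", {
  ns <- 512
  t <- seq_len(ns) / 256
  # channel-homogeneous waveform, identical in every epoch
  base <- outer(seq_len(68), t, function(ch, tt) sin(2 * pi * 15 * tt + ch))
  arr <- array(0, c(6, 68, ns))
  for (i in 1:6) arr[i, , ] <- base
  ep <- epoch_set(arr, tibble::tibble(trial = 1:6,
                                      condition = rep(c("a", "b"), 3)),
                  fx_montage, 256)
  res <- screen_epochs(ep)
  expect_equal(sum(res$report$epochs$rejected), 0)
  expect_equal(dim(res$epochs)[1], 6)
})

test_that("a large EOG transient is rejected with reason eog_max", {
  spec <- small_spec(12, regularities = "neutral")
  plan <- build_session_plan(spec, seed = 8)
  cfg <- simulation_config(15, effects = condition_effects(spec))
  ep <- simulate_experiment(plan, fx_model, cfg, seed = 9)
  eog <- which(fx_montage$type == "eog")
  blink <- 300 * fpvs:::raised_cosine(102)
  for (ch in eog) ep$data[4, ch, 301:402] <- ep$data[4, ch, 301:402] + blink
  res <- screen_epochs(ep)
  rep4 <- res$report$epochs[res$report$epochs$epoch == ep$info$trial[4], ]
  expect_true(rep4$rejected)
  expect_match(rep4$reasons, "eog_max")
})

test_that("epochs with more than 12 corrupted channels are discarded", {
  spec <- small_spec(10, regularities = "neutral")
  plan <- build_session_plan(spec, seed = 10)
  cfg <- simulation_config(15, effects = condition_effects(spec))
  ep <- simulate_experiment(plan, fx_model, cfg, seed = 11)
  set.seed(12)
  scalp <- which(fx_montage$type == "scalp")
  ep$data[5, scalp[1:13], ] <- ep$data[5, scalp[1:13], ] * 40
  res <- screen_epochs(ep)
  rep5 <- res$report$epochs[res$report$epochs$epoch == ep$info$trial[5], ]
  expect_true(rep5$rejected)
  expect_match(rep5$reasons, "over_interpolated")
})

test_that("screening verdicts are invariant to epoch order", {
  spec <- small_spec(8)
  plan <- build_session_plan(spec, seed = 13)
  cfg <- simulation_config(15, effects = condition_effects(spec),
                           blink_rate = 6, blink_amp = 300)
  ep <- simulate_experiment(plan, fx_model, cfg, seed = 14)
  res1 <- screen_epochs(ep)
  perm <- sample(seq_len(dim(ep)[1]))
  res2 <- screen_epochs(fpvs:::subset_epochs(ep, perm))
  r1 <- res1$report$epochs[order(res1$report$epochs$epoch), ]
  r2 <- res2$report$epochs[order(res2$report$epochs$epoch), ]
  expect_equal(r1$rejected, r2$rejected)
  expect_equal(r1$reasons, r2$reasons)
})

test_that("epoch accounting is exact per condition", {
  spec <- small_spec(10)
  plan <- build_session_plan(spec, seed = 15)
  cfg <- simulation_config(15, effects = condition_effects(spec),
                           blink_rate = 4, blink_amp = 250)
  ep <- simulate_experiment(plan, fx_model, cfg, seed = 16)
  res <- screen_epochs(ep)
  acc <- dplyr::left_join(
    res$report$by_condition,
    dplyr::count(res$epochs$info, .data$condition, name = "kept"),
    by = "condition")
  acc$kept[is.na(acc$kept)] <- 0
  expect_equal(acc$kept + acc$n_rejected, acc$n)
  expect_true(all(acc$pct_rejected >= 0 & acc$pct_rejected <= 100))
})

test_that("clean recordings stay within the false-positive budget", {
  # power-matched regular conditions: screening sees homogeneous epochs
  spec <- small_spec(40, regularities = c("angry", "neutral"))
  plan <- build_session_plan(spec, seed = 17)
  cfg <- simulation_config(15, effects = condition_effects(spec))
  pct <- sapply(1:6, function(r) {
    ep <- simulate_experiment(plan, fx_model, cfg, seed = 600 + r)
    preprocess(ep)$report$by_condition$pct_rejected
  })
  expect_true(all(rowMeans(pct) <= 5))
})
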