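test_that("expected CS follows the Bessel-ratio bridge", {
  expect_equal(expected_cs(0), 0)
  expect_gt(expected_cs(1e8), 1 - 1e-6)
  # oracle: E[cos(theta)] by numerical integration of the von Mises density
  vm_mean_cos <- function(kappa) {
    dens <- function(x) exp(kappa * cos(x))
    stats::integrate(function(x) cos(x) * dens(x), -pi, pi)$value /
      stats::integrate(dens, -pi, pi)$value
  }
  for (kappa in c(0.5, 2, 5)) {
    expect_equal(expected_cs(kappa), vm_mean_cos(kappa)^2, tolerance = 1e-8)
  }
  expect_equal(expected_cs(2), 0.4868, tolerance = 1e-3)
  expect_error(expected_cs(2, n = 1), class = "fpvs_domain_error")
  expect_equal(kappa_for_cs(expected_cs(1.7)), 1.7, tolerance = 1e-6)
})

test_that("the von Mises sampler matches the Bessel resultant", {
  set.seed(2)
  for (kappa in c(0.5, 4)) {
    th <- rvonmises(20000, 0.8, kappa)
    r_hat <- Mod(mean(exp(1i * th)))
    expect_lt(abs(r_hat - sqrt(expected_cs(kappa))), 0.01)
    expect_lt(abs(Arg(mean(exp(1i * th))) - 0.8), 0.05)
  }
  expect_true(all(abs(rvonmises(100, 0, 1e8)) < 1e-3))
})

test_that("a silent configuration simulates all-zero epochs", {
  spec <- small_spec(1, regularities = "irregular")
  cfg <- simulation_config(15, effects = condition_effects(spec),
                           amp_stim = 0, noise_sd = 0, alpha_amp = 0)
  sq <- build_sequence(pilot1_cond("irregular"), spec, seed = 1)
  x <- simulate_trial(sq, fx_model, cfg, seed = 2)
  expect_true(all(x == 0))
})

test_that("epoch length covers 0-3.8 s at 256 Hz (973 samples)", {
  spec <- small_spec(1, regularities = "neutral")
  cfg <- simulation_config(15, effects = condition_effects(spec))
  sq <- build_sequence(pilot1_cond("neutral"), spec, seed = 1)
  x <- simulate_trial(sq, fx_model, cfg, seed = 2)
  expect_equal(dim(x), c(68, 973))
})

test_that("infinite concentration locks the regularity phase across trials", {
  spec <- small_spec(6, regularities = "neutral")
  eff <- condition_effects(spec)
  eff$kappa <- 1e9
  cfg <- simulation_config(15, effects = eff, amp_stim = 0, noise_sd = 0,
                           alpha_amp = 0)
  plan <- build_session_plan(spec, seed = 4)
  ep <- simulate_experiment(plan, fx_model, cfg, seed = 5)
  ep <- truncate_detrend(ep)
  best <- which.max(abs(fx_model$topo_reg))
  spec_f <- spectrum_fft(ep$data[, best, ], 256)
  ph <- phase_at(spec_f, 5)
  expect_lt(diff(range(ph$angles)), 1e-3)
  expect_equal(as.numeric(cs_index_closed(ph)), 1, tolerance = 1e-6)
})

test_that("simulated sessions carry labels and reproduce by seed", {
  spec <- small_spec(3)
  plan <- build_session_plan(spec, seed = 6)
  cfg <- simulation_config(15, effects = condition_effects(spec))
  a <- simulate_experiment(plan, fx_model, cfg, seed = 7)
  b <- simulate_experiment(plan, fx_model, cfg, seed = 7)
  c <- simulate_experiment(plan, fx_model, cfg, seed = 8)
  expect_equal(dim(a), c(9, 68, 973))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  expect_equal(a$info$condition, plan$condition)

  empty <- simulate_experiment(plan[0, ], fx_model, cfg, seed = 1)
  expect_equal(dim(empty)[1], 0)
})

test_that("simulated regular epochs recover the planted concentration as CS", {
  # low measurement noise isolates the phase-concentration bridge; the
  # tolerance is three phase-sampling standard errors of a 3 x 60-trial
  # mean (~0.08); the tight +/-0.03 recovery check runs at full
  # replicate strength in the acceptance suite
  spec <- small_spec(60, regularities = "neutral")
  plan <- build_session_plan(spec, seed = 31)
  for (kappa in c(0.5, 4)) {
    eff <- condition_effects(spec)
    eff$kappa <- kappa
    cfg <- simulation_config(15, effects = eff, noise_sd = 1)
    cs <- sapply(1:3, function(r) {
      ep <- simulate_experiment(plan, fx_model, cfg, seed = 400 + r)
      ep <- truncate_detrend(rereference(ep, "average"))
      cs_by_condition(ep, 5)$cs
    })
    expect_lt(abs(mean(cs) - expected_cs(kappa)), 0.08)
  }
})

test_that("irregular simulations carry no regularity-rate phase locking", {
  spec <- small_spec(60, regularities = "irregular")
  plan <- build_session_plan(spec, seed = 32)
  cfg <- simulation_config(15, effects = condition_effects(spec))
  best <- which.max(abs(fx_model$topo_reg))
  # fixed sensor projection: no filter overfitting enters the estimate
  cs <- sapply(1:20, function(r) {
    ep <- simulate_experiment(plan, fx_model, cfg, seed = 500 + r)
    ep <- truncate_detrend(rereference(ep, "average"))
    sp <- spectrum_fft(ep$data[, best, ], 256)
    as.numeric(cs_index_closed(phase_at(sp, 5)))
  })
  expect_lt(abs(mean(cs)), 0.01)
})

test_that("background noise has the configured 1/f spectral slope", {
  beta <- 1
  spec <- small_spec(1, regularities = "irregular")
  cfg <- simulation_config(15, effects = condition_effects(spec),
                           amp_stim = 0, alpha_amp = 0, noise_sd = 10,
                           noise_exponent = beta)
  sq <- build_sequence(pilot1_cond("irregular"), spec, seed = 1)
  set.seed(9)
  pw <- 0
  n_rep <- 12
  for (r in 1:n_rep) {
    x <- simulate_trial(sq, fx_model, cfg)
    pw <- pw + Mod(mvfft(t(x)))^2 / n_rep
  }
  f <- (seq_len(ncol(x)) - 1) * 256 / ncol(x)
  band <- f >= 1 & f <= 40
  slope <- coef(lm(log(rowMeans(pw)[band]) ~ log(f[band])))[[2]]
  expect_equal(slope, -beta, tolerance = 0.15)
})

test_that("blinks appear on EOG channels with small scalp leakage", {
  spec <- small_spec(1, regularities = "irregular")
  cfg <- simulation_config(15, effects = condition_effects(spec),
                           amp_stim = 0, noise_sd = 0, alpha_amp = 0,
                           blink_rate = 60, blink_amp = 300)
  sq <- build_sequence(pilot1_cond("irregular"), spec, seed = 1)
  x <- simulate_trial(sq, fx_model, cfg, seed = 11)
  eog <- fx_montage$type == "eog"
  expect_gt(max(abs(x[eog, ])), 250)
  expect_equal(max(abs(x[!eog, ])), 0.1 * max(abs(x[eog, ])), tolerance = 1e-9)
})

test_that("irregular conditions refuse a regularity amplitude", {
  spec <- small_spec(1)
  eff <- condition_effects(spec)
  eff$amp_reg[eff$regularity == "irregular"] <- 2
  expect_error(simulation_config(15, effects = eff),
               class = "fpvs_config_error")
  expect_error(simulation_config(15, f_reg = 4),
               class = "fpvs_config_error")
})
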