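test_that("sequence length and triplet structure follow the design timing", {
  p1 <- preset_spec("pilot1")
  sq <- build_sequence(pilot1_cond("angry"), p1, seed = 1)
  expect_equal(nrow(sq), 57)           # 15 Hz x 3.8 s
  expect_equal(max(sq$triplet), 19)
  expect_true(all(sq$expression[sq$position == 1] == "angry"))
  expect_equal(mean(sq$expression == "angry"), 1 / 3)

  e1 <- preset_spec("exp1")
  sq6 <- build_sequence(list(orientation = "upright", regularity = "neutral",
                             variability = "high"), e1, seed = 1)
  expect_equal(nrow(sq6), 42)          # 6 Hz x 7 s
  expect_true(all(sq6$orientation == "upright"))
  expect_equal(length(unique(sq6$identity)), 1)  # one identity per trial
})

test_that("fillers are balanced and never occupy regular positions", {
  p1 <- preset_spec("pilot1")
  p2 <- preset_spec("pilot2")
  set.seed(42)
  n_rep <- 2500  # x4 condition types below: 10,000 sequences in total
  for (k in seq_len(n_rep)) {
    for (sq in list(
      build_sequence(pilot1_cond("angry"), p1),
      build_sequence(pilot1_cond("irregular"), p1),
      build_sequence(list(orientation = "upright", regularity = "neutral",
                          variability = "low"), p2),
      build_sequence(list(orientation = "inverted", regularity = "irregular",
                          variability = "high"), p2))) {
      first <- sq$expression[sq$position == 1]
      if (any(first %in% c("happy", "disgusted"))) {
        fail("filler expression found at a regular position")
      }
    }
  }
  succeed()
  # per-sequence filler balance in regular conditions
  sq <- build_sequence(pilot1_cond("angry"), p1, seed = 7)
  tb <- table(sq$expression[sq$position != 1])
  expect_equal(unname(diff(range(tb))), 0)
})

test_that("irregular triplets hold distinct categories", {
  p2 <- preset_spec("pilot2")
  for (s in 1:50) {
    sq <- build_sequence(list(orientation = "upright", regularity = "irregular",
                              variability = "high"), p2, seed = s)
    per_trip <- tapply(sq$expression, sq$triplet, function(x)
      length(unique(x)))
    expect_true(all(per_trip == 3))
  }
})

test_that("no face token of one triplet recurs in the next", {
  p1 <- preset_spec("pilot1")
  for (s in 1:50) {
    sq <- build_sequence(pilot1_cond("neutral"), p1, seed = s)
    tok <- paste(sq$identity, sq$expression)
    for (t in 2:max(sq$triplet)) {
      expect_length(intersect(tok[sq$triplet == t], tok[sq$triplet == t - 1]), 0)
    }
  }
})

test_that("session plans have the printed trial counts", {
  plan <- build_session_plan(preset_spec("pilot1"), seed = 3)
  expect_equal(nrow(plan), 576)
  expect_true(all(table(plan$condition) == 96))

  plan2 <- build_session_plan(preset_spec("exp2"), seed = 3)
  expect_equal(nrow(plan2), 360)
  expect_true(all(table(paste(plan2$orientation, plan2$regularity)) == 60))

  tiny <- experiment_spec(15, 3.8, orientations = "upright",
                          regularities = "neutral", trials_per_condition = 1,
                          identities = list(none = "id01"))
  expect_equal(nrow(build_session_plan(tiny, seed = 1)), 1)
})

test_that("plans are reproducible by seed and differ across seeds", {
  spec <- small_spec(4)
  a <- build_session_plan(spec, seed = 11)
  b <- build_session_plan(spec, seed = 11)
  c <- build_session_plan(spec, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$cycles, c$cycles))
  ta <- schedule_targets(a, spec, seed = 5)
  tb <- schedule_targets(b, spec, seed = 5)
  expect_identical(ta$targets, tb$targets)
})

test_that("target scheduling honors counts, intervals and the frame grid", {
  spec <- preset_spec("pilot1")
  plan <- schedule_targets(build_session_plan(spec, seed = 21), spec, seed = 22)
  expect_equal(sum(plan$target_trial), 216)
  expect_true(all(table(plan$condition[plan$target_trial]) == 36))
  n_t <- lengths(plan$targets[plan$target_trial])
  expect_true(all(n_t >= 1 & n_t <= 3))
  gaps <- fpvs:::target_gaps(plan)
  expect_true(all(gaps >= 600))
  frame_ms <- 1000 / 60
  on <- unlist(plan$targets)
  expect_true(all(abs(on / frame_ms - round(on / frame_ms)) < 1e-9))
  expect_true(all(on <= 3.8 * 1000 - 2 * frame_ms + 1e-9))

  e1 <- preset_spec("exp1")
  plan1 <- schedule_targets(build_session_plan(e1, seed = 1), e1, seed = 2)
  expect_true(all(fpvs:::target_gaps(plan1) >= 800))
})

test_that("scheduled gaps respect the minimum over many replicate sessions", {
  spec <- small_spec(10)
  spec$target_policy <- list(target_trials_per_condition = 8,
                             max_targets_per_trial = 3,
                             min_target_interval = 600,
                             target_duration_frames = 2)
  plan <- build_session_plan(spec, seed = 1)
  for (s in 1:300) {
    g <- fpvs:::target_gaps(schedule_targets(plan, spec, seed = s))
    if (length(g) && min(g) < 600) fail(sprintf("gap %.1f < 600 at seed %d", min(g), s))
  }
  succeed()
})

test_that("passive designs stay target-free", {
  spec <- preset_spec("exp2")
  plan <- build_session_plan(spec, seed = 1)
  out <- schedule_targets(plan, spec, seed = 2)
  expect_false(any(out$target_trial))
  expect_true(all(lengths(out$targets) == 0))
})

test_that("configuration errors are raised for invalid designs", {
  expect_error(experiment_spec(15, 3.75, identities = list(none = "a")),
               class = "fpvs_config_error")  # not a whole triplet count
  expect_error(experiment_spec(7, 3, identities = list(none = "a")),
               class = "fpvs_config_error")  # refresh not divisible
  spec <- small_spec(2)
  expect_error(build_sequence(list(orientation = "upright",
                                   regularity = "happy",
                                   variability = "none"), spec),
               class = "fpvs_config_error")
  tight <- experiment_spec(15, 0.2, orientations = "upright",
                           regularities = "neutral",
                           identities = list(none = "a"),
                           trials_per_condition = 1,
                           target_policy = list(
                             target_trials_per_condition = 1,
                             max_targets_per_trial = 1,
                             min_target_interval = 60000,
                             target_duration_frames = 13))
  plan <- build_session_plan(tight, seed = 1)
  expect_error(schedule_targets(plan, tight, seed = 1),
               class = "fpvs_scheduling_error")
})

test_that("NTSC luminance is the unrounded weighted sum", {
  expect_equal(rgb_to_luminance(0, 0, 0), 0)
  expect_equal(rgb_to_luminance(255, 0, 0), 76.2195)
  expect_equal(rgb_to_luminance(100, 100, 100), 99.99)
  expect_error(rgb_to_luminance(-1, 0, 0), class = "fpvs_validation_error")
  expect_error(rgb_to_luminance(0, 300, 0), class = "fpvs_validation_error")
})

test_that("plans flatten and serialize to TSV and JSON", {
  spec <- small_spec(2)
  plan <- schedule_targets(build_session_plan(spec, seed = 1), spec, seed = 2)
  flat <- plan_to_table(plan)
  expect_equal(nrow(flat), nrow(plan) * 57)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_session_plan(plan, tsv = tsv, json = js)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(flat))
  parsed <- jsonlite::read_json(js)
  expect_length(parsed, nrow(plan))
  expect_equal(parsed[[1]]$condition, plan$condition[1])
})
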