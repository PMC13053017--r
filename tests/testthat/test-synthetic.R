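test_that("synthetic utterances honor requested boundaries and are reproducible", {
  item <- default_item_table()[52, ]
  a1 <- synth_utterance_audio(item, produced = 3, base_f0 = 140, seed = 90)
  a2 <- synth_utterance_audio(item, produced = 3, base_f0 = 140, seed = 90)
  expect_identical(a1$wave, a2$wave)
  expect_identical(a1$syllables, a2$syllables)

  # boundaries are exactly the generated durations, after the lead-in
  expect_equal(a1$syllables$start[1], synth_config()$lead_in_s)
  expect_equal(a1$syllables$start[-1], a1$syllables$end[-nrow(a1$syllables)])
  expect_equal(a1$syllables$end - a1$syllables$start, a1$cue_truth$duration)
  expect_equal(a1$t_env_peak,
               mean(unlist(a1$syllables[3, c("start", "end")])))

  expect_error(synth_utterance_audio(item, produced = 9, base_f0 = 140),
               "parameter error")
})

test_that("pipeline nomination recovers the produced syllable at default boost", {
  set.seed(91)
  items <- default_item_table()
  n <- 200
  idx <- rep_len(which(items$n_syll >= 2), n)
  hit <- 0
  for (i in seq_len(n)) {
    item <- items[idx[i], ]
    produced <- sample.int(item$n_syll, 1)
    a <- synth_utterance_audio(item, produced = produced,
                               base_f0 = sample(c(115, 215), 1))
    env <- amplitude_envelope(a$wave, a$sr)
    pitch <- f0_track(a$wave, a$sr)
    hit <- hit + (analyze_prominence(env, pitch, a$syllables)$nominated == produced)
  }
  expect_gte(hit / n, 0.95)
})

test_that("synthetic pose tracks place the apex at anchor plus asynchrony", {
  tr1 <- synth_pose_track(1.2, 0, span = c(0, 3), noise_sd = 0, seed = 92)
  ev <- detect_max_extension(preprocess_track(tr1))
  expect_lt(abs(ev$t_ext - 1.2), 0.02 + 1e-9)

  expect_identical(synth_pose_track(1.2, -60, span = c(0, 3), seed = 93)$y,
                   synth_pose_track(1.2, -60, span = c(0, 3), seed = 93)$y)
  expect_error(synth_pose_track(1.2, 5000, span = c(0, 3)), "parameter error")

  # generated vs pipeline-measured asynchrony across 100 trials
  set.seed(94)
  gen <- runif(100, -300, 300)
  meas <- vapply(gen, function(a) {
    tr <- synth_pose_track(1.5, a, span = c(0, 3.5))
    detect_max_extension(preprocess_track(tr))$t_ext
  }, numeric(1))
  meas_ms <- (meas - 1.5) * 1000
  expect_gt(stats::cor(gen, meas_ms), 0.99)
})

test_that("study design: counts, two productions per word, alternating blocks", {
  cfg <- small_cfg()
  res <- simulate_extract(cfg)
  tr <- res$trials
  expect_equal(nrow(tr), 2 * nrow(small_items()) * 2)  # speakers x items x 2

  per <- dplyr::count(tr, speaker_id, item_id, movement)
  expect_true(all(per$n == 1))                          # once per condition

  for (sp in unique(tr$speaker_id)) {
    d <- res$truth[res$truth$speaker_id == sp, ]
    d <- d[order(d$trial), ]
    runs <- rle(d$movement)
    expect_true(all(runs$lengths == cfg$block_len))
  }
})

test_that("identical configs reproduce byte-identical datasets on disk", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  t1 <- synth_study(cfg, d1)
  t2 <- synth_study(cfg, d2)
  expect_identical(t1$asynchrony_true_ms, t2$asynchrony_true_ms)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  sample_files <- f1[c(1, round(length(f1) / 2), length(f1))]
  for (f in sample_files)
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6))
  unlink(d2, recursive = TRUE)

  # truth ledger and emitted files agree: re-read one movement trial
  mv <- t1[t1$movement, ][1, ]
  tier <- read_syllable_tier(file.path(d1, "tiers", paste0(mv$file_stem, ".TextGrid")))
  expect_equal(nrow(tier), mv$n_syll)
  pose <- read_pose_track(file.path(d1, "pose", paste0(mv$file_stem, ".csv")))
  ev <- detect_max_extension(preprocess_track(pose))
  expect_lt(abs(ev$t_ext - mv$t_apex_true), 0.025)
  unlink(d1, recursive = TRUE)
})

test_that("in-memory and on-disk pipelines agree up to PCM quantization", {
  cfg <- synth_config(n_speakers = 1, items = small_items()[c(1, 9, 17), ],
                      seed = 404)
  dir <- file.path(tempdir(), "study_rt")
  synth_study(cfg, dir)
  from_disk <- extract_trials(dir)
  in_mem <- simulate_extract(cfg)$trials
  expect_equal(nrow(from_disk), nrow(in_mem))
  expect_identical(from_disk$nominated, in_mem$nominated)
  expect_identical(from_disk$condition, in_mem$condition)
  expect_equal(from_disk$t_peak_env, in_mem$t_peak_env, tolerance = 0.011)
  expect_equal(from_disk$peak_intensity, in_mem$peak_intensity, tolerance = 0.01)
  ok <- !is.na(in_mem$asynchrony_ms)
  expect_equal(from_disk$asynchrony_ms[ok], in_mem$asynchrony_ms[ok],
               tolerance = 0.05)
  unlink(dir, recursive = TRUE)
})

test_that("realized production classes follow the accuracy presets", {
  cfg <- synth_config(n_speakers = 10, items = small_items(), seed = 95)
  set.seed(cfg$seed)
  plan <- promkin:::build_study_plan(cfg)
  mm <- plan[!plan$matching, ]
  p_hat <- mean(mm$class_true == "correct_L2")
  n <- nrow(mm)
  expect_lt(abs(p_hat - 0.53), stats::qnorm(0.995) * sqrt(0.53 * 0.47 / n))
  p_cmp <- mean(mm$class_true == "incorrect_L1")
  expect_lt(abs(p_cmp - 0.27), stats::qnorm(0.995) * sqrt(0.27 * 0.73 / n))
  mt <- plan[plan$matching, ]
  expect_lt(abs(mean(mt$class_true == "correct_L2") - 0.60),
            stats::qnorm(0.995) * sqrt(0.6 * 0.4 / nrow(mt)))
})

test_that("generated asynchronies have the configured condition means", {
  cfg <- synth_config(n_speakers = 40, items = small_items(),
                      noise_sd_ms = 50, speaker_sd_ms = 10, item_sd_ms = 10,
                      seed = 96)
  set.seed(cfg$seed)
  plan <- promkin:::build_study_plan(cfg)
  mv <- plan[plan$movement, ]
  for (cond in c("matching_correct", "precede_correct", "follow_correct")) {
    sel <- mv$condition_true == cond
    mc_err <- 3 * 55 / sqrt(sum(sel))
    expect_lt(abs(mean(mv$asynchrony_true_ms[sel]) - cfg$asynchrony_ms[[cond]]),
              mc_err)
  }
})
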