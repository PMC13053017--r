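sr <- 8000

test_that("envelope of a constant-amplitude tone is flat at the amplitude", {
  t <- (0:(sr - 1)) / sr
  x <- 0.5 * sin(2 * pi * 200 * t)
  env <- amplitude_envelope(x, sr)
  interior <- env$t > 0.1 & env$t < 0.9
  expect_true(all(abs(env$value[interior] - 0.5) / 0.5 < 0.05))

  env0 <- amplitude_envelope(numeric(sr), sr)
  expect_true(all(env0$value < 1e-9))
})

test_that("AM-tone envelope maxima align with the modulator maxima", {
  t <- (0:(sr - 1)) / sr
  x <- sin(2 * pi * 200 * t) * (1 + cos(2 * pi * 4 * t)) / 2  # maxima at k/4 s
  env <- amplitude_envelope(x, sr)
  v <- env$value
  peaks <- which(diff(sign(diff(v))) == -2) + 1L
  peaks <- peaks[env$t[peaks] > 0.1 & env$t[peaks] < 0.9]
  expect_gt(length(peaks), 1)
  truth <- c(0.25, 0.5, 0.75)
  for (p in peaks) {
    expect_lt(min(abs(env$t[p] - truth)), 1 / env$rate + 1e-9)
  }
})

test_that("envelope cutoff above the output Nyquist is rejected", {
  expect_error(amplitude_envelope(sin(1:8000), sr, cutoff_hz = 60, out_rate = 100),
               "Nyquist")
})

test_that("envelope is amplitude-equivariant and shift-covariant", {
  set.seed(21)
  item <- default_item_table()[52, ]
  a <- synth_utterance_audio(item, produced = 3, base_f0 = 130)
  env1 <- amplitude_envelope(a$wave, a$sr)
  env3 <- amplitude_envelope(3 * a$wave, a$sr)
  expect_equal(env3$value, 3 * env1$value, tolerance = 1e-8)
  iv <- a$syllables[3, ]
  expect_identical(envelope_peak_time(env1, iv), envelope_peak_time(env3, iv))

  # quarter-second shift moves the in-interval peak time by the same amount
  shift <- 0.25
  env_s <- amplitude_envelope(c(numeric(shift * a$sr), a$wave), a$sr)
  iv_s <- list(start = iv$start + shift, end = iv$end + shift)
  expect_equal(envelope_peak_time(env_s, iv_s),
               envelope_peak_time(env1, iv) + shift,
               tolerance = 1.5 / env1$rate)
})

test_that("f0 tracking recovers known fundamentals and rejects noise", {
  t <- (0:(sr - 1)) / sr
  pt <- f0_track(sin(2 * pi * 200 * t), sr)
  expect_lt(abs(stats::median(pt$f0, na.rm = TRUE) - 200), 1)
  expect_gt(mean(!is.na(pt$f0)), 0.9)

  set.seed(3)
  pn <- f0_track(rnorm(sr, 0, 0.3), sr)
  expect_gt(mean(is.na(pn$f0)), 0.5)

  expect_error(f0_track(numeric(0), sr), "insufficient|empty")
  expect_error(f0_track(sin(t), sr, fmin = 500, fmax = 100), "fmin")
})

test_that("f0 tracking follows a linear 150-250 Hz ramp", {
  n <- sr
  f0c <- seq(150, 250, length.out = n)
  x <- harmonic_complex(f0c, sr)
  pt <- f0_track(x, sr)
  head_sel <- pt$t < 0.1
  tail_sel <- pt$t > 0.9
  truth_head <- mean(f0c[seq_len(0.1 * sr)])
  truth_tail <- mean(f0c[(0.9 * sr):n])
  expect_lt(abs(mean(pt$f0[head_sel], na.rm = TRUE) - truth_head), 5)
  expect_lt(abs(mean(pt$f0[tail_sel], na.rm = TRUE) - truth_tail), 5)
})

test_that("syllable cues: durations from boundaries, peaks from tracks", {
  set.seed(10)
  item <- default_item_table()[52, ]   # 4 syllables, target 3
  a <- synth_utterance_audio(item, produced = 3, base_f0 = 130, cue_boost = 3)
  env <- amplitude_envelope(a$wave, a$sr)
  pitch <- f0_track(a$wave, a$sr)
  cues <- extract_syllable_cues(env, pitch, a$syllables)
  expect_equal(cues$duration, a$syllables$end - a$syllables$start)
  # the boosted syllable holds the maximum of every cue
  expect_equal(which.max(cues$duration), 3L)
  expect_equal(which.max(cues$f0_peak), 3L)
  expect_equal(which.max(cues$env_peak), 3L)
  expect_false(any(cues$f0_missing))

  out <- tibble::tibble(start = 90, end = 91, label = "zz")
  expect_error(extract_syllable_cues(env, pitch, out), "alignment")
})

test_that("a wholly unvoiced syllable is flagged with f0 missing", {
  t <- (0:(2.4 * sr - 1)) / sr
  seg <- function(f, lo, hi) ifelse(t >= lo & t < hi, sin(2 * pi * f * t), 0)
  set.seed(4)
  x <- 0.5 * seg(180, 0, 0.8) + 0.5 * seg(220, 1.6, 2.4)
  x[t >= 0.8 & t < 1.6] <- 0.4 * rnorm(sum(t >= 0.8 & t < 1.6))  # noise syllable
  syl <- tibble::tibble(start = c(0, 0.8, 1.6), end = c(0.8, 1.6, 2.4),
                        label = c("sa", "xx", "so"))
  env <- amplitude_envelope(x, sr)
  pitch <- f0_track(x, sr)
  cues <- extract_syllable_cues(env, pitch, syl)
  expect_true(cues$f0_missing[2])
  expect_true(is.na(cues$f0_peak[2]))
  expect_false(any(cues$f0_missing[c(1, 3)]))

  # missing-f0 policy: the unvoiced syllable gets the minimum voiced f0 z-score
  prom <- analyze_prominence(env, pitch, syl)
  expect_true("f0_missing" %in% prom$flags)
  expect_equal(prom$cues$z_f[2], min(prom$cues$z_f[c(1, 3)]))
})

test_that("envelope peak time is a local argmax within the interval", {
  t <- seq(0, 1, by = 0.01)
  parab <- env_track(t, pmax(0, 1 - 100 * (t - 0.35)^2))
  expect_equal(envelope_peak_time(parab, list(start = 0.2, end = 0.5)), 0.35)

  rising <- env_track(t, t)
  expect_equal(envelope_peak_time(rising, list(start = 0.2, end = 0.5)), 0.5)

  expect_error(envelope_peak_time(parab, list(start = 2, end = 3)), "alignment")

  # nominated-syllable peak recovered close to the generator's AM peak
  set.seed(11)
  item <- default_item_table()[52, ]
  for (rep in 1:5) {
    a <- synth_utterance_audio(item, produced = 3, base_f0 = 200)
    env <- amplitude_envelope(a$wave, a$sr)
    expect_lt(abs(envelope_peak_time(env, a$syllables[3, ]) - a$t_env_peak), 0.02)
  }
})
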