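#' Extraction parameters
#'
#' Bundles the signal-processing settings used by [extract_trial()].
#'
#' @param env_cutoff_hz,env_rate Envelope smoother cutoff and output rate.
#' @param f0_min,f0_max f0 search range (Hz).
#' @param pose_rate Kinematic resampling rate (Hz).
#' @param pose_smooth_hz Kinematic low-pass cutoff (Hz).
#' @param movement_threshold Displacement needed to call a movement present
#'   (track units).
#' @param window_margin_s Apex search window: speech extent widened by this
#'   margin on each side (s); `NULL` searches the full track.
#' @return A plain list of parameters.
#' @export
extract_params <- function(env_cutoff_hz = 12, env_rate = 100,
                           f0_min = 75, f0_max = 500,
                           pose_rate = 50, pose_smooth_hz = 10,
                           movement_threshold = 20,
                           window_margin_s = 0.5) {
  list(env_cutoff_hz = env_cutoff_hz, env_rate = env_rate,
       f0_min = f0_min, f0_max = f0_max, pose_rate = pose_rate,
       pose_smooth_hz = pose_smooth_hz,
       movement_threshold = movement_threshold,
       window_margin_s = window_margin_s)
}

#' Measure one trial: prominence, apex, asynchrony
#'
#' Runs the acoustic stage (envelope, f0, cue aggregation, z-scoring,
#' nomination, envelope-peak time) and, when a pose track is supplied, the
#' kinematic stage (preprocessing, apex detection) and joins them into one
#' trial record. Quality issues (unvoiced syllables, apex at the search
#' window edge, no movement detected on a movement trial) become flags, not
#' dropped rows.
#'
#' @param wave,sr Waveform and sampling rate.
#' @param syllables Syllable interval tibble.
#' @param pose A [pose_track()] or `NULL` (no-movement trial).
#' @param item One item-table row (`item_id`, `n_syll`, `target_syll`,
#'   `competitor_syll`, `matching`, `distance`).
#' @param speaker_id Speaker identifier.
#' @param movement Logical movement-condition flag.
#' @param block Block index (optional).
#' @param weights [prominence_weights()].
#' @param params [extract_params()].
#' @return One-row tibble in the [trial_table] schema.
#' @export
extract_trial <- function(wave, sr, syllables, pose = NULL, item,
                          speaker_id, movement = !is.null(pose), block = NA_integer_,
                          weights = prominence_weights(),
                          params = extract_params()) {
  env <- amplitude_envelope(wave, sr, cutoff_hz = params$env_cutoff_hz,
                            out_rate = params$env_rate)
  pitch <- f0_track(wave, sr, fmin = params$f0_min, fmax = params$f0_max)
  prom <- analyze_prominence(env, pitch, syllables, weights)
  flags <- prom$flags

  t_peak_target <- envelope_peak_time(env, syllables[item$target_syll, ])

  t_ext <- NA_real_
  if (!is.null(pose)) {
    track <- preprocess_track(pose, out_rate = params$pose_rate,
                              smooth_cutoff_hz = params$pose_smooth_hz)
    window <- if (is.null(params$window_margin_s)) NULL else
      c(min(syllables$start) - params$window_margin_s - 1e-9,
        max(syllables$end) + params$window_margin_s + 1e-9)
    if (!is.null(window)) {
      window[1] <- max(window[1], track$t[1])
      window[2] <- min(window[2], track$t[length(track$t)])
    }
    ev <- detect_max_extension(track, window)
    if (ev$at_edge) flags <- c(flags, "apex_at_edge")
    if (!movement_present(track, threshold = params$movement_threshold, window = window)) {
      flags <- c(flags, "no_movement_detected")
    } else {
      t_ext <- ev$t_ext
    }
  } else if (movement) {
    flags <- c(flags, "missing_pose_track")
  }

  cls <- classify_production(prom$nominated, item$target_syll, item$competitor_syll)
  cond <- label_condition(item$matching, item$target_syll, item$competitor_syll, cls)
  quick_tbl(
    speaker_id = speaker_id,
    item_id = item$item_id,
    movement = movement,
    block = block,
    n_syll = item$n_syll,
    nominated = prom$nominated,
    production_class = cls,
    condition = cond,
    distance = item$distance,
    t_peak_env = prom$peak_env_time,
    t_peak_env_target = t_peak_target,
    t_ext = t_ext,
    asynchrony_ms = compute_asynchrony(t_ext, prom$peak_env_time),
    asynchrony_anchor_ms = compute_asynchrony(t_ext, t_peak_target),
    peak_intensity = prom$cues$env_peak[prom$nominated],
    flags = paste(flags, collapse = ";")
  )
}

#' Extract a trial table from a dataset directory
#'
#' Consumes a dataset laid out as written by [synth_study()] (or any dataset
#' following that layout): `audio/<stem>.wav`, `tiers/<stem>.TextGrid`,
#' `pose/<stem>.csv` for movement trials, `items.csv`, and a design table
#' with columns `speaker_id`, `item_id`, `movement`, `file_stem` (and
#' optionally `block`).
#'
#' @param dir Dataset directory.
#' @param design Design tibble; defaults to reading `truth.csv` under `dir`.
#' @param tier_name Syllable tier name in the TextGrids.
#' @param weights,params See [extract_trial()].
#' @return Trial-table tibble, one row per trial.
#' @export
extract_trials <- function(dir, design = NULL, tier_name = "syllables",
                           weights = prominence_weights(),
                           params = extract_params()) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  items <- read_item_table(file.path(dir, "items.csv"))
  if (is.null(design)) {
    tf <- file.path(dir, "truth.csv")
    if (!file.exists(tf)) stop("no design supplied and no truth.csv under ", dir)
    design <- tibble::as_tibble(utils::read.csv(tf, stringsAsFactors = FALSE))
  }
  recs <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    stem <- row$file_stem
    wav <- read_wav(file.path(dir, "audio", paste0(stem, ".wav")))
    syl <- read_syllable_tier(file.path(dir, "tiers", paste0(stem, ".TextGrid")),
                              tier_name = tier_name)
    pose_path <- file.path(dir, "pose", paste0(stem, ".csv"))
    pose <- if (isTRUE(as.logical(row$movement)) && file.exists(pose_path))
      read_pose_track(pose_path) else NULL
    recs[[i]] <- extract_trial(
      wave = wav$samples, sr = wav$sample_rate, syllables = syl, pose = pose,
      item = items[items$item_id == row$item_id, ],
      speaker_id = row$speaker_id, movement = as.logical(row$movement),
      block = if ("block" %in% names(row)) row$block else NA_integer_,
      weights = weights, params = params)
  }
  dplyr::bind_rows(recs)
}
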