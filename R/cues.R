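#' Per-syllable acoustic prominence cues
#'
#' Aggregates the three cue measurements the prominence score consumes, one
#' row per syllable interval: duration (`end - start`, exactly), peak f0
#' (maximum voiced f0 of frames whose centers fall in the interval) and peak
#' envelope amplitude (maximum envelope sample in the interval).
#'
#' @param env An `envelope_track` from [amplitude_envelope()].
#' @param pitch A `pitch_track` from [f0_track()].
#' @param syllables Tibble of syllable intervals (`start`, `end`, `label`),
#'   as returned by [read_syllable_tier()].
#' @return Tibble with columns `syll` (1-based index), `label`, `duration`
#'   (s), `f0_peak` (Hz, `NA` when the syllable has no voiced frame),
#'   `env_peak` (arbitrary units) and `f0_missing`.
#' @export
extract_syllable_cues <- function(env, pitch, syllables) {
  stopifnot(inherits(env, "envelope_track"), inherits(pitch, "pitch_track"))
  validate_intervals(syllables)
  n <- nrow(syllables)
  if (n < 1) stop("no syllable intervals supplied")
  env_max <- env$t[length(env$t)]
  out <- quick_tbl(
    syll = seq_len(n),
    label = syllables$label,
    duration = syllables$end - syllables$start,
    f0_peak = rep(NA_real_, n),
    env_peak = rep(NA_real_, n),
    f0_missing = rep(FALSE, n)
  )
  for (j in seq_len(n)) {
    s <- syllables$start[j]; e <- syllables$end[j]
    if (s < env$t[1] - 1e-6 || e > env_max + 1e-6)
      stop("alignment error: syllable interval (", s, ", ", e,
           ") lies outside the envelope extent (0, ", round(env_max, 3), ")")
    sel_e <- which(env$t >= s - 1e-9 & env$t <= e + 1e-9)
    if (!length(sel_e)) stop("alignment error: interval contains no envelope sample")
    out$env_peak[j] <- max(env$value[sel_e])
    sel_p <- which(pitch$t >= s - 1e-9 & pitch$t <= e + 1e-9 & !is.na(pitch$f0))
    if (length(sel_p)) {
      out$f0_peak[j] <- max(pitch$f0[sel_p])
    } else {
      out$f0_missing[j] <- TRUE
    }
  }
  out
}
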