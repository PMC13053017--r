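# Shared fixture builders (everything is generated in code at test time).

# a small balanced item subset: 8 matching, 8 competitor-preceding,
# 8 competitor-following
small_items <- function() {
  items <- default_item_table()
  rbind(items[1:8, ], items[49:56, ], items[73:80, ])
}

small_cfg <- function(...) {
  synth_config(n_speakers = 2, items = small_items(), seed = 301, ...)
}

# simple envelope track built directly (for argmax-style oracle tests)
env_track <- function(t, value, rate = 1 / diff(t[1:2])) {
  structure(list(t = t, value = value, rate = rate), class = "envelope_track")
}

pitch_track_direct <- function(t, f0, rate = 1 / diff(t[1:2])) {
  structure(list(t = t, f0 = f0, rate = rate), class = "pitch_track")
}

# harmonic complex with a prescribed f0 contour, for pitch-tracker oracles
harmonic_complex <- function(f0_contour, sr, n_harm = 3) {
  phase <- 2 * pi * cumsum(f0_contour) / sr
  x <- numeric(length(phase))
  for (h in seq_len(n_harm)) x <- x + sin(h * phase) / h
  x / max(abs(x))
}
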