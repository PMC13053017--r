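#' Fundamental-frequency track by short-time autocorrelation
#'
#' Frames the waveform, computes the normalized autocorrelation of each
#' frame via FFT, and reads f0 off the highest autocorrelation peak in the
#' candidate lag range, refined by parabolic interpolation. A frame is
#' voiced when its normalized autocorrelation peak exceeds
#' `voicing_threshold` and its energy is not negligible relative to the
#' utterance maximum.
#'
#' @param wave Numeric waveform, or a list with `wave`/`samples` and
#'   `sr`/`sample_rate`.
#' @param sr Sampling rate (Hz).
#' @param fmin,fmax Candidate f0 range in Hz; the default 75-500 Hz covers
#'   mixed-sex adult speech. `fmax` must stay below the Nyquist frequency.
#' @param hop_s Frame hop in seconds (default 10 ms).
#' @param win_s Analysis window in seconds (default 40 ms, >= 3 periods at
#'   `fmin`).
#' @param voicing_threshold Normalized autocorrelation needed to call a
#'   frame voiced.
#' @return A `pitch_track`: list with `t` (frame centers, s), `f0` (Hz, `NA`
#'   when unvoiced) and `rate` (frames per second).
#' @export
f0_track <- function(wave, sr = NULL, fmin = 75, fmax = 500,
                     hop_s = 0.010, win_s = 0.040, voicing_threshold = 0.45) {
  if (is.list(wave)) {
    sr <- wave$sr %||% wave$sample_rate
    wave <- wave$wave %||% wave$samples
  }
  if (is.null(sr)) stop("sample rate required")
  if (!length(wave)) stop("insufficient data: empty waveform")
  if (!(fmin < fmax && fmax < sr / 2))
    stop("require fmin < fmax < Nyquist (", sr / 2, " Hz)")
  wlen <- round(win_s * sr)
  hop <- round(hop_s * sr)
  if (length(wave) < wlen) stop("insufficient data: waveform shorter than one analysis window")

  starts <- seq(1L, length(wave) - wlen + 1L, by = hop)
  centers <- (starts - 1L + wlen / 2) / sr
  frames <- vapply(starts, function(s) wave[s:(s + wlen - 1L)], numeric(wlen))
  frames <- sweep(frames, 2L, colMeans(frames))
  rms <- sqrt(colMeans(frames^2))

  nfft <- 2^ceiling(log2(2L * wlen))
  padded <- rbind(frames, matrix(0, nfft - wlen, ncol(frames)))
  spec <- stats::mvfft(padded)
  acf_full <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft

  lag_min <- max(2L, floor(sr / fmax))
  lag_max <- min(wlen - 2L, ceiling(sr / fmin))
  if (lag_min >= lag_max) stop("f0 search range empty at this sample rate")

  n_frames <- ncol(frames)
  f0 <- rep(NA_real_, n_frames)
  r0 <- acf_full[1L, ]
  energy_floor <- 0.02 * max(rms, 1e-12)
  for (j in seq_len(n_frames)) {
    if (r0[j] <= 0 || rms[j] < energy_floor) next
    r <- acf_full[(lag_min:lag_max) + 1L, j] / r0[j]
    k <- which.max(r)
    if (r[k] < voicing_threshold) next
    lag <- lag_min + k - 1L
    # parabolic refinement around the peak
    if (k > 1L && k < length(r)) {
      denom <- r[k - 1L] - 2 * r[k] + r[k + 1L]
      if (abs(denom) > 1e-12) {
        delta <- 0.5 * (r[k - 1L] - r[k + 1L]) / denom
        lag <- lag + max(-0.5, min(0.5, delta))
      }
    }
    cand <- sr / lag
    if (cand >= fmin && cand <= fmax) f0[j] <- cand
  }
  structure(list(t = centers, f0 = f0, rate = 1 / hop_s), class = "pitch_track")
}

#' @export
print.pitch_track <- function(x, ...) {
  cat(sprintf("<pitch_track> %d frames at %g Hz hop rate, %.0f%% voiced\n",
              length(x$t), x$rate, 100 * mean(!is.na(x$f0))))
  invisible(x)
}
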