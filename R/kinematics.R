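#' Preprocess a raw pose track into an extension-displacement signal
#'
#' Resamples to a uniform grid (cubic spline), normalizes orientation so
#' that extension (downward motion of the hand) is positive displacement
#' from the trial's starting baseline, smooths with a zero-phase 4th-order
#' Butterworth low-pass, and optionally divides by a per-speaker reference
#' length to give body-scaled units.
#'
#' @param track A [pose_track()].
#' @param out_rate Target sampling rate (Hz); 50 Hz matches common
#'   video-based pose extraction.
#' @param smooth_cutoff_hz Low-pass cutoff (Hz); biphasic beat energy lies
#'   well below the default 10 Hz. `NULL` disables smoothing.
#' @param baseline_s Initial span (s) averaged to define the resting
#'   baseline.
#' @param ref_length Optional reference length (same units as `y`, e.g. the
#'   speaker's shoulder-hip distance in pixels) dividing the displacement;
#'   timing is unaffected, only amplitude reporting.
#' @return A `pose_track` whose `y` is extension displacement (positive =
#'   extended), `y_down = FALSE`, sampled uniformly at `out_rate`.
#' @export
preprocess_track <- function(track, out_rate = 50, smooth_cutoff_hz = 10,
                             baseline_s = 0.2, ref_length = NULL) {
  stopifnot(inherits(track, "pose_track"))
  if (length(track$t) < 12)
    stop("insufficient data: pose track too short for filtering (need >= 12 samples)")
  t_out <- seq(track$t[1], track$t[length(track$t)], by = 1 / out_rate)
  y <- if (isTRUE(all.equal(track$t, t_out, tolerance = 1e-9)) &&
           length(track$t) == length(t_out)) {
    t_out <- track$t
    track$y
  } else {
    stats::spline(track$t, track$y, xout = t_out)$y
  }
  disp <- if (track$y_down) y else -y
  if (!is.null(smooth_cutoff_hz)) {
    if (smooth_cutoff_hz >= out_rate / 2)
      stop("smooth_cutoff_hz must be below the output Nyquist rate")
    if (length(disp) < 12)
      stop("insufficient data: pose track too short for filtering")
    bf <- signal::butter(4, smooth_cutoff_hz / (out_rate / 2), type = "low")
    mu <- mean(disp)          # demean so filter edge transients stay negligible
    disp <- signal::filtfilt(bf, disp - mu) + mu
  }
  n_base <- max(3L, min(length(disp), round(baseline_s * out_rate)))
  disp <- disp - mean(disp[seq_len(n_base)])
  if (!is.null(ref_length)) {
    stopifnot(ref_length > 0)
    disp <- disp / ref_length
  }
  out <- pose_track(t_out, disp, y_down = TRUE, nominal_rate = out_rate)
  out$y_down <- FALSE                     # orientation already normalized
  attr(out, "preprocessed") <- TRUE
  out
}

#' Detect the maximum-extension apex of a hand movement
#'
#' The apex is the time of the global maximum of extension displacement
#' within the search window. An apex falling on the first or last sample of
#' the window is flagged (`at_edge`), not rejected: truncated recordings
#' should be inspectable rather than silently dropped.
#'
#' @param track A preprocessed [pose_track()] (see [preprocess_track()]).
#' @param window Optional `c(t0, t1)` limiting the search (s); default is
#'   the full track.
#' @return A `movement_event`: list with `t_ext` (s), `extension_peak`
#'   (displacement units), `present = TRUE` and `at_edge`.
#' @export
detect_max_extension <- function(track, window = NULL) {
  stopifnot(inherits(track, "pose_track"))
  if (is.null(window)) window <- range(track$t)
  sel <- which(track$t >= window[1] - 1e-9 & track$t <= window[2] + 1e-9)
  if (!length(sel)) stop("alignment error: search window does not overlap the pose track")
  k <- sel[which.max(track$y[sel])]
  structure(list(
    t_ext = track$t[k],
    extension_peak = track$y[k],
    present = TRUE,
    at_edge = k == sel[1] || k == sel[length(sel)]
  ), class = "movement_event")
}

#' Was a hand movement actually produced?
#'
#' Quality check for no-movement blocks: a movement is present when the peak
#' extension displacement reaches `threshold`.
#'
#' @param track A preprocessed [pose_track()].
#' @param threshold Displacement threshold in the track's units (pixels
#'   unless body-scaled).
#' @param window Optional search window, as in [detect_max_extension()].
#' @return Logical.
#' @export
movement_present <- function(track, threshold = 20, window = NULL) {
  ev <- detect_max_extension(track, window)
  ev$extension_peak >= threshold
}

#' @export
print.movement_event <- function(x, ...) {
  cat(sprintf("<movement_event> apex at %.3f s, peak extension %.2f%s\n",
              x$t_ext, x$extension_peak, if (x$at_edge) " (at window edge)" else ""))
  invisible(x)
}
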