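#' Construct a pose track
#'
#' A pose track is the vertical position of one tracked landmark (here the
#' index finger) over time, plus its orientation convention.
#'
#' @param t Time stamps in seconds, strictly increasing.
#' @param y Vertical position (pixels or body-scaled units).
#' @param y_down `TRUE` if larger `y` means lower on screen (image
#'   coordinates, the MediaPipe convention), so that a downward extension
#'   movement increases `y`.
#' @param nominal_rate Nominal sampling rate in Hz; inferred from the median
#'   time step when `NULL`.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(t, y, y_down = TRUE, nominal_rate = NULL) {
  stopifnot(length(t) == length(y))
  if (length(t) < 2) stop("insufficient data: pose track needs at least 2 samples")
  if (any(diff(t) <= 0)) stop("malformed pose track: time must be strictly increasing")
  if (is.null(nominal_rate)) nominal_rate <- 1 / stats::median(diff(t))
  structure(list(t = as.numeric(t), y = as.numeric(y),
                 y_down = isTRUE(y_down), nominal_rate = nominal_rate),
            class = "pose_track")
}

#' Read a pose track from a delimited text table
#'
#' The table must have a header; the time column is in seconds. Extra
#' columns (other landmarks) are ignored.
#'
#' @param path Path to a comma-delimited file.
#' @param y_down Orientation flag, see [pose_track()].
#' @param time_col,y_col Column names of the time stamps and of the vertical
#'   index-finger coordinate.
#' @return A [pose_track()].
#' @export
read_pose_track <- function(path, y_down = TRUE, time_col = "time_s", y_col = "y") {
  if (!file.exists(path)) stop("pose file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  for (col in c(time_col, y_col))
    if (!col %in% names(d)) stop("pose table is missing column '", col, "': ", path)
  pose_track(d[[time_col]], d[[y_col]], y_down = y_down)
}

#' Write a pose track to a comma-delimited file
#'
#' @param track A [pose_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_track <- function(track, path) {
  stopifnot(inherits(track, "pose_track"))
  utils::write.csv(data.frame(time_s = track$t, y = track$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d samples, %.3f-%.3f s, nominal rate %.1f Hz, y_down=%s\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$nominal_rate, x$y_down))
  invisible(x)
}
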