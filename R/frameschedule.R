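#' PET frame schedule
#'
#' A frame schedule holds the timing grid shared by every curve of a PET
#' measurement: frame onsets, frame durations and derived frame midpoints,
#' all in minutes. Frames are closed-open intervals `[start, start + duration)`
#' and must be non-overlapping with non-decreasing onsets.
#'
#' @param frame_start Numeric vector of frame onsets (minutes, first >= 0).
#' @param frame_duration Numeric vector of frame durations (minutes, > 0).
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `frame_start`, `frame_duration` and `frame_mid`.
#' @examples
#' fs <- frame_schedule(c(0, 1, 2), c(1, 1, 2))
#' fs$frame_mid
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  if (length(frame_start) != length(frame_duration)) {
    stop("`frame_start` and `frame_duration` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_duration))) {
    stop("frame times must be finite", call. = FALSE)
  }
  if (frame_start[1] < 0) stop("first frame onset must be >= 0", call. = FALSE)
  if (any(frame_duration <= 0)) stop("frame durations must be > 0", call. = FALSE)
  if (is.unsorted(frame_start)) stop("frame onsets must be non-decreasing", call. = FALSE)
  ends <- frame_start + frame_duration
  if (length(frame_start) > 1 &&
      any(frame_start[-1] < ends[-length(ends)] - 1e-9)) {
    stop("frames must not overlap", call. = FALSE)
  }
  out <- data.frame(
    frame_start = frame_start,
    frame_duration = frame_duration,
    frame_mid = frame_start + frame_duration / 2
  )
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, %.1f min total>\n",
              nrow(x), x$frame_start[nrow(x)] + x$frame_duration[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Default 93-minute, 38-frame acquisition schedule
#'
#' A standard HRRT-style schedule used as the package default: 4 x 15 s,
#' 4 x 30 s, 6 x 1 min, 6 x 2 min, 6 x 3 min and 12 x 4.5 min frames,
#' totalling 93 minutes in 38 frames.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(0.25, 4), rep(0.5, 4), rep(1, 6), rep(2, 6), rep(3, 6), rep(4.5, 12))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Short 20-frame schedule for compact examples and simulations
#'
#' A coarser 60-minute schedule (4 x 30 s, 4 x 1 min, 6 x 3 min, 6 x 6 min)
#' retaining the early fast sampling that reference-tissue models need.
#'
#' @return A [frame_schedule()].
#' @export
short_frame_schedule <- function() {
  dur <- c(rep(0.5, 4), rep(1, 4), rep(3, 6), rep(6, 6))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

.assert_frame_schedule <- function(frames) {
  if (!inherits(frames, "frame_schedule")) {
    if (is.data.frame(frames) &&
        all(c("frame_start", "frame_duration") %in% names(frames))) {
      return(frame_schedule(frames$frame_start, frames$frame_duration))
    }
    stop("`frames` must be a frame_schedule", call. = FALSE)
  }
  frames
}
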