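# Width measurement and temporal interpolation: valid frames -> dense
# per-frame pupil and limbus width signals aligned with the video timeline.

#' Measure pupil and limbus widths on valid frames
#'
#' The pupil width is the x-extent of the pupil bounding box; the limbus
#' width is the x-extent of the iris bounding box (the outer iris border is
#' the limbus). Widths, not heights, are used because the eye moves
#' vertically far more than horizontally during surgery, making the
#' horizontal extent the stabler measurement. Only frames whose validity
#' report is `ok` contribute.
#'
#' @param segments A list of `frame_segment` records.
#' @param reports Validity data.frame from [validate_frames()] (computed if
#'   omitted); must correspond one-to-one to `segments`.
#' @return A data.frame with columns `frame`, `pupil_width`, `limbus_width`,
#'   one row per valid frame, sorted by frame.
#' @export
measure_widths <- function(segments, reports = validate_frames(segments)) {
  if (nrow(reports) != length(segments)) {
    stop("reports must correspond one-to-one to segments")
  }
  keep <- which(reports$valid)
  out <- data.frame(
    frame = reports$frame_index[keep],
    pupil_width = vapply(segments[keep], function(s) s$pupil_box[3L] - s$pupil_box[1L], numeric(1L)),
    limbus_width = vapply(segments[keep], function(s) s$iris_box[3L] - s$iris_box[1L], numeric(1L))
  )
  out[order(out$frame), , drop = FALSE]
}

#' Dense width signal from sparse measurements
#'
#' Fills unmeasured frames so that the widths align with the full video
#' timeline: each missing frame takes the widths of the most recent measured
#' frame (pupil and limbus jointly, from the same donor frame); a leading run
#' of missing frames takes the first following measured widths.
#'
#' @param widths data.frame with columns `frame` (0-based), `pupil_width`,
#'   `limbus_width`, as from [measure_widths()].
#' @param total_frames Total number of frames in the video; defaults to
#'   `max(frame) + 1`.
#' @param fps Frame rate in frames per second.
#' @return A `width_signal` object: list with `fps`, numeric vectors
#'   `pupil_width` and `limbus_width` of length `total_frames`, and a logical
#'   vector `measured` flagging frames that were measured rather than filled.
#' @export
interpolate_widths <- function(widths, total_frames = NULL, fps = 25) {
  if (is.null(widths) || nrow(widths) == 0L) {
    stop("no valid frames: cannot build a width signal")
  }
  if (fps <= 0) stop("fps must be positive")
  widths <- widths[order(widths$frame), , drop = FALSE]
  if (anyDuplicated(widths$frame)) stop("duplicate frame in width measurements")
  if (is.null(total_frames)) total_frames <- max(widths$frame) + 1L
  total_frames <- as.integer(total_frames)
  if (total_frames < max(widths$frame) + 1L) {
    stop("total_frames smaller than the largest measured frame index")
  }
  # donor index per frame: last measured frame at or before it, else first
  # measured frame (leading backfill)
  pos <- findInterval(seq_len(total_frames) - 1L, widths$frame)
  pos[pos == 0L] <- 1L
  measured <- logical(total_frames)
  measured[widths$frame + 1L] <- TRUE
  structure(
    list(
      fps = fps,
      pupil_width = widths$pupil_width[pos],
      limbus_width = widths$limbus_width[pos],
      measured = measured
    ),
    class = "width_signal"
  )
}

#' @export
print.width_signal <- function(x, ...) {
  n <- length(x$pupil_width)
  cat(sprintf(
    "Width signal: %d frames at %g fps (%.1f s), %d measured (%.1f%%)\n",
    n, x$fps, n / x$fps, sum(x$measured), 100 * mean(x$measured)
  ))
  cat(sprintf("  pupil width : median %.1f px\n", stats::median(x$pupil_width)))
  cat(sprintf("  limbus width: median %.1f px\n", stats::median(x$limbus_width)))
  invisible(x)
}

#' @export
as.data.frame.width_signal <- function(x, ...) {
  data.frame(
    frame = seq_along(x$pupil_width) - 1L,
    pupil_width = x$pupil_width,
    limbus_width = x$limbus_width,
    measured = x$measured
  )
}

#' Export a width signal as CSV
#'
#' Columns `frame`, `pupil_width`, `limbus_width`, `measured`.
#'
#' @param signal A `width_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_width_signal_csv <- function(signal, path) {
  utils::write.csv(as.data.frame(signal), path, row.names = FALSE)
  invisible(path)
}
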