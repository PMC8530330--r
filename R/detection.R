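# Core detector: segment the smoothed width signal at its extrema and keep
# candidate segments whose size change passes the relevance threshold.

#' Detector configuration
#'
#' @param cutoff_hz Low-pass cutoff frequency in Hz (see [filter_spec()]).
#' @param delta Relevance threshold as a fraction of DM (the median
#'   limbus-pupil width difference, [compute_dm()]); a candidate segment is
#'   emitted only if its absolute size change is at least `delta * DM`. Must
#'   lie in `[0, 1]`; 0 emits every candidate.
#' @param mode `"pupil"` analyzes the smoothed pupil width; `"difference"`
#'   analyzes the smoothed limbus-minus-pupil width, which exploits the
#'   limbus staying essentially constant while the pupil reacts.
#' @param order Butterworth filter order.
#' @return A `detection_config` object.
#' @export
detection_config <- function(cutoff_hz = 0.1, delta = 0.12,
                             mode = c("pupil", "difference"), order = 5L) {
  mode <- match.arg(mode)
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  structure(
    list(cutoff_hz = cutoff_hz, delta = delta, mode = mode,
         order = as.integer(order)),
    class = "detection_config"
  )
}

#' Median limbus-pupil width difference (DM)
#'
#' DM is the reference scale for reaction sizes: the difference between the
#' median limbus width and the median pupil width over the whole video,
#' computed on the interpolated but unfiltered signals (medians are robust
#' to the segmentation noise that filtering removes).
#'
#' @param signal A `width_signal`.
#' @return A positive number (pixels).
#' @export
compute_dm <- function(signal) {
  stopifnot(inherits(signal, "width_signal"))
  dm <- stats::median(signal$limbus_width) - stats::median(signal$pupil_width)
  if (!is.finite(dm) || dm <= 0) {
    stop("degenerate signal: median limbus width must exceed median pupil width")
  }
  dm
}

#' Extrema of a filtered signal
#'
#' Returns the 0-based indices of strict local minima and maxima (sign
#' changes of the first difference), plus the first and last index as
#' boundary extrema so the leading and trailing monotone runs form candidate
#' segments. A plateau contributes only its first frame, a deterministic
#' tie-break (plateaus are rare after real-valued filtering).
#'
#' @param x Numeric vector of length >= 2.
#' @return Strictly increasing integer vector of 0-based indices, starting
#'   at 0 and ending at `length(x) - 1`.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  # collapse runs of equal values to their first index
  keep <- c(TRUE, x[-1L] != x[-n])
  idx <- which(keep)        # 1-based indices of run starts
  xs <- x[idx]
  m <- length(xs)
  interior <- integer(0)
  if (m >= 3L) {
    d <- diff(xs)
    turn <- which(d[-length(d)] * d[-1L] < 0) + 1L
    interior <- idx[turn]
  }
  sort(unique(c(1L, interior, n))) - 1L
}

#' Pupil-to-limbus ratio change over a segment
#'
#' The pupil/limbus width ratio at the segment's end minus the ratio at its
#' start, evaluated on the smoothed signals. The ratio is camera-zoom
#' invariant, so its change expresses a reaction size as a fraction of the
#' (constant) limbus: a value of -0.12 is a 12-percentage-point
#' constriction.
#'
#' @param signal A `width_signal`.
#' @param seg A list or one-row data.frame with `start_frame` and
#'   `end_frame` (0-based; `end_frame` is the closing extremum index).
#' @param config A [detection_config()] providing the smoothing parameters.
#' @return Signed ratio change.
#' @export
reaction_ratio_change <- function(signal, seg, config = detection_config()) {
  spec <- filter_spec(config$cutoff_hz, config$order, signal$fps)
  p <- lowpass(signal$pupil_width, spec)
  l <- lowpass(signal$limbus_width, spec)
  ratio_change_at(p, l, seg$start_frame, seg$end_frame)
}

ratio_change_at <- function(pupil_f, limbus_f, start_frame, end_frame) {
  i0 <- start_frame + 1L
  i1 <- end_frame + 1L
  if (any(limbus_f[c(i0, i1)] <= 0)) {
    stop("degenerate signal: non-positive limbus width")
  }
  pupil_f[i1] / limbus_f[i1] - pupil_f[i0] / limbus_f[i0]
}

#' Detect pupil reactions in a width signal
#'
#' The analyzed signal (smoothed pupil width, or smoothed limbus-minus-pupil
#' width in difference mode) is segmented at its extrema; every span between
#' two neighboring extrema is a candidate reaction. A candidate is emitted
#' when the absolute difference of the signal values at its bounding extrema
#' is at least `delta * DM`. In both modes the threshold scale DM comes from
#' the original (unfiltered) signals.
#'
#' @param signal A `width_signal`.
#' @param config A [detection_config()].
#' @return A data.frame of class `reaction_set`, one row per reaction, in
#'   temporal order, with columns `start_frame`, `end_frame` (0-based,
#'   half-open; `end_frame` is the closing extremum), `start_s`, `end_s`,
#'   `size_px` (analyzed-signal value at the closing extremum minus at the
#'   opening one), `relative_size` (`|size_px| / DM`), `direction`
#'   (`"constriction"` or `"dilation"`, from the pupil-width sign
#'   convention) and `ratio_change` (see [reaction_ratio_change()]).
#'   Attributes `dm`, `fps` and `config` record the context.
#' @export
detect_reactions <- function(signal, config = detection_config()) {
  stopifnot(inherits(signal, "width_signal"), inherits(config, "detection_config"))
  dm <- compute_dm(signal)
  spec <- filter_spec(config$cutoff_hz, config$order, signal$fps)
  pupil_f <- lowpass(signal$pupil_width, spec)
  limbus_f <- lowpass(signal$limbus_width, spec)
  analyzed <- switch(config$mode,
    pupil = pupil_f,
    difference = limbus_f - pupil_f
  )
  ex <- find_extrema(analyzed)
  start <- ex[-length(ex)]
  end <- ex[-1L]
  size <- analyzed[end + 1L] - analyzed[start + 1L]
  keep <- abs(size) >= config$delta * dm
  start <- start[keep]; end <- end[keep]; size <- size[keep]
  # on the pupil signal a negative change is a constriction; the difference
  # signal moves opposite to the pupil, so invert before assigning direction
  pupil_sign <- if (config$mode == "difference") -size else size
  out <- data.frame(
    start_frame = start,
    end_frame = end,
    start_s = start / signal$fps,
    end_s = end / signal$fps,
    size_px = size,
    relative_size = abs(size) / dm,
    direction = ifelse(pupil_sign < 0, "constriction", "dilation"),
    ratio_change = vapply(seq_along(start), function(i) {
      ratio_change_at(pupil_f, limbus_f, start[i], end[i])
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )
  structure(out, dm = dm, fps = signal$fps, config = config,
            class = c("reaction_set", "data.frame"))
}

#' Write detected reactions as JSON
#'
#' `{"reactions": [...], "dm": float, "config": {...}, "fps": float}`.
#'
#' @param reactions A `reaction_set` from [detect_reactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(reactions, path) {
  cfg <- attr(reactions, "config")
  obj <- list(
    reactions = as.data.frame(reactions),
    dm = attr(reactions, "dm"),
    fps = attr(reactions, "fps"),
    config = list(cutoff_hz = cfg$cutoff_hz, delta = cfg$delta,
                  mode = cfg$mode, order = cfg$order)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 6, dataframe = "rows")
  invisible(path)
}

#' Read a reactions JSON file
#'
#' @param path Path written by [write_reactions()].
#' @return A data.frame with at least `start_frame` and `end_frame`;
#'   attributes `dm`, `fps` and `config` when present in the file.
#' @export
read_reactions <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  df <- if (length(obj$reactions) == 0L) {
    data.frame(start_frame = integer(0), end_frame = integer(0))
  } else {
    as.data.frame(obj$reactions)
  }
  attr(df, "dm") <- obj$dm
  attr(df, "fps") <- obj$fps
  attr(df, "config") <- obj$config
  df
}
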