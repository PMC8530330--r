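# Per-frame segmentation records: reading, writing, bounding boxes, validity.
#
# Box convention throughout the package: 0-based, half-open [min, max) in both
# axes, so the x-extent (width) of a box is x_max - x_min with no +/-1
# ambiguity.

#' Tight bounding box of a binary mask
#'
#' Computes the minimal axis-aligned box containing every foreground pixel of
#' a binary raster, in the package's 0-based half-open convention: a single
#' foreground pixel at column 7, row 3 yields `c(7, 3, 8, 4)`.
#'
#' @param mask A logical or 0/1 matrix, rows = image rows, columns = image
#'   columns (row-major raster).
#' @return Named numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @examples
#' m <- matrix(FALSE, 20, 80)
#' m[6:15, 11:60] <- TRUE
#' tight_box(m)  # 10 5 60 15
#' @export
tight_box <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.logical(mask)) mask <- mask != 0
  cols <- which(colSums(mask) > 0L)
  rows <- which(rowSums(mask) > 0L)
  if (length(cols) == 0L) stop("empty mask: no foreground pixels")
  c(
    x_min = cols[1L] - 1,
    y_min = rows[1L] - 1,
    x_max = cols[length(cols)],
    y_max = rows[length(rows)]
  )
}

# Decode {"size": [nrow, ncol], "counts": [...]} run-length encoding.
# Counts alternate background/foreground in row-major order, starting with
# a (possibly zero) background run.
rle_decode <- function(rle) {
  size <- as.integer(rle$size)
  counts <- as.integer(rle$counts)
  if (length(size) != 2L || any(size <= 0L)) stop("rle size must be two positive integers")
  if (sum(counts) != prod(size)) stop("rle counts do not sum to raster size")
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  # row-major stream -> fill by row
  matrix(vals, nrow = size[1L], ncol = size[2L], byrow = TRUE) != 0L
}

rle_encode <- function(mask) {
  v <- as.integer(t(mask != 0))  # row-major
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1L] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

check_box <- function(box, where) {
  box <- as.numeric(box)
  if (length(box) != 4L || anyNA(box)) {
    stop(sprintf("%s: box must be four numbers [x_min, y_min, x_max, y_max]", where))
  }
  if (box[1L] >= box[3L] || box[2L] >= box[4L]) {
    stop(sprintf("%s: degenerate box (need x_min < x_max and y_min < y_max)", where))
  }
  names(box) <- c("x_min", "y_min", "x_max", "y_max")
  box
}

# One region entry from the JSON dialect: {"box": [...], "rle": {...}}.
parse_region <- function(obj, where) {
  box <- if (!is.null(obj$box)) check_box(obj$box, where) else NULL
  mask <- NULL
  if (!is.null(obj$rle)) {
    mask <- rle_decode(obj$rle)
    mbox <- tight_box(mask)
    if (is.null(box)) {
      box <- mbox
    } else if (any(abs(box - mbox) > 1e-9)) {
      stop(sprintf("%s: stored box does not match the mask's tight box", where))
    }
  }
  if (is.null(box)) stop(sprintf("%s: region has neither box nor rle", where))
  list(box = box, mask = mask)
}

# A class entry may be one region or an array of regions (the upstream
# network can emit several candidates per class; validity handles > 1).
parse_class <- function(obj, where) {
  if (is.null(obj)) return(list())
  if (!is.null(obj$box) || !is.null(obj$rle)) return(list(parse_region(obj, where)))
  lapply(seq_along(obj), function(i) parse_region(obj[[i]], where))
}

new_frame_segment <- function(frame_index, pupil, iris) {
  structure(
    list(
      frame_index = frame_index,
      pupil = pupil,
      iris = iris,
      pupil_box = if (length(pupil) == 1L) pupil[[1L]]$box else NULL,
      iris_box = if (length(iris) == 1L) iris[[1L]]$box else NULL,
      pupil_mask = if (length(pupil) == 1L) pupil[[1L]]$mask else NULL,
      iris_mask = if (length(iris) == 1L) iris[[1L]]$mask else NULL,
      source = if (length(pupil) == 1L && !is.null(pupil[[1L]]$mask) ||
                   length(iris) == 1L && !is.null(iris[[1L]]$mask)) "mask" else "box"
    ),
    class = "frame_segment"
  )
}

#' Construct a frame segmentation record
#'
#' @param frame_index 0-based frame number.
#' @param pupil_box,iris_box Optional boxes `c(x_min, y_min, x_max, y_max)`
#'   (0-based, half-open). `NULL` means the class was not detected.
#' @param pupil_mask,iris_mask Optional binary matrices; when given, the box
#'   is derived from (or checked against) the mask's tight box.
#' @return A `frame_segment` object.
#' @export
frame_segment <- function(frame_index, pupil_box = NULL, iris_box = NULL,
                          pupil_mask = NULL, iris_mask = NULL) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) stop("frame_index must be a non-negative integer")
  mk <- function(box, mask, what) {
    if (is.null(box) && is.null(mask)) return(list())
    where <- sprintf("frame %d %s", frame_index, what)
    if (!is.null(box)) box <- check_box(box, where)
    if (!is.null(mask)) {
      mbox <- tight_box(mask)
      if (is.null(box)) box <- mbox
      else if (any(abs(box - mbox) > 1e-9)) {
        stop(where, ": stored box does not match the mask's tight box")
      }
    }
    list(list(box = box, mask = mask))
  }
  new_frame_segment(frame_index,
                    mk(pupil_box, pupil_mask, "pupil"),
                    mk(iris_box, iris_mask, "iris"))
}

#' Read per-frame segmentation records from a JSON-Lines file
#'
#' One JSON object per line:
#' `{"frame": int, "pupil": {"box": [x0,y0,x1,y1], "rle": {...}}, "iris": {...}}`.
#' An absent class key means the class was not detected in that frame. The
#' optional `rle` carries the binary mask as `{"size": [nrow, ncol],
#' "counts": [...]}`: run lengths in row-major order alternating
#' background/foreground, starting with a (possibly zero) background run.
#'
#' @param path Path to the JSON-Lines file.
#' @return A list of [frame_segment()] records sorted by frame index, class
#'   `frame_segments`.
#' @seealso [write_frame_segments()], [validate_frames()]
#' @export
read_frame_segments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  segs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE, simplifyDataFrame = FALSE),
      error = function(e) stop(sprintf("line %d: malformed JSON (%s)", i, conditionMessage(e)))
    )
    if (is.null(obj$frame) || obj$frame < 0 || obj$frame != floor(obj$frame)) {
      stop(sprintf("line %d: missing or invalid 'frame'", i))
    }
    where <- sprintf("line %d", i)
    segs[[i]] <- new_frame_segment(
      as.integer(obj$frame),
      parse_class(obj$pupil, paste(where, "pupil")),
      parse_class(obj$iris, paste(where, "iris"))
    )
  }
  idx <- vapply(segs, `[[`, integer(1L), "frame_index")
  if (anyDuplicated(idx)) {
    stop("duplicate frame_index: ", paste(unique(idx[duplicated(idx)]), collapse = ", "))
  }
  structure(segs[order(idx)], class = "frame_segments")
}

region_json <- function(region) {
  obj <- list(box = as.numeric(region$box))
  if (!is.null(region$mask)) obj$rle <- rle_encode(region$mask)
  obj
}

#' Write per-frame segmentation records as JSON-Lines
#'
#' Inverse of [read_frame_segments()]: writing then reading reproduces the
#' records field-for-field.
#'
#' @param segments A list of `frame_segment` records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_segments <- function(segments, path) {
  lines <- vapply(segments, function(s) {
    obj <- list(frame = s$frame_index)
    if (length(s$pupil) == 1L) obj$pupil <- region_json(s$pupil[[1L]])
    else if (length(s$pupil) > 1L) obj$pupil <- lapply(s$pupil, region_json)
    if (length(s$iris) == 1L) obj$iris <- region_json(s$iris[[1L]])
    else if (length(s$iris) > 1L) obj$iris <- lapply(s$iris, region_json)
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

box_inside <- function(inner, outer) {
  inner[1L] >= outer[1L] && inner[3L] <= outer[3L] &&
    inner[2L] >= outer[2L] && inner[4L] <= outer[4L]
}

#' Frame validity for width measurement
#'
#' A frame is usable only when both pupil and iris were detected exactly once
#' and the pupil's bounding box lies fully inside the iris's bounding box
#' (containment checked at box level). Frames failing these rules carry a
#' reason code and are skipped by [measure_widths()].
#'
#' @param seg A `frame_segment`.
#' @return A list with `frame_index`, `valid` (logical) and `reason`, one of
#'   `"ok"`, `"missing_class"`, `"pupil_not_inside_iris"`,
#'   `"too_many_segments"`.
#' @export
validate_frame <- function(seg) {
  reason <- if (length(seg$pupil) > 1L || length(seg$iris) > 1L) {
    "too_many_segments"
  } else if (length(seg$pupil) == 0L || length(seg$iris) == 0L) {
    "missing_class"
  } else if (!box_inside(seg$pupil_box, seg$iris_box)) {
    "pupil_not_inside_iris"
  } else {
    "ok"
  }
  list(frame_index = seg$frame_index, valid = reason == "ok", reason = reason)
}

#' Validity reports for a sequence of frames
#'
#' @param segments A list of `frame_segment` records.
#' @return A data.frame with columns `frame_index`, `valid`, `reason`.
#' @export
validate_frames <- function(segments) {
  reps <- lapply(segments, validate_frame)
  data.frame(
    frame_index = vapply(reps, `[[`, integer(1L), "frame_index"),
    valid = vapply(reps, `[[`, logical(1L), "valid"),
    reason = vapply(reps, `[[`, character(1L), "reason"),
    stringsAsFactors = FALSE
  )
}
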