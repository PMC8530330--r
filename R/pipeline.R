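# Orchestration: segments -> widths -> interpolation -> filtering ->
# detection -> report, over one or many videos, plus thin wrappers backing
# the command-line interface.

log_msg <- function(...) message(sprintf(...))

#' Read a run manifest
#'
#' JSON listing the videos of a run:
#' `{"videos": [{"id", "segments", "gt" (optional), "fps",
#' "total_frames" (optional)}]}`. Paths are resolved relative to the
#' manifest's directory.
#'
#' @param path Manifest path.
#' @return List with a `videos` list; each video has `id`, `segments`,
#'   optional `gt`, `fps`, optional `total_frames`.
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  vids <- lapply(obj$videos, function(v) {
    if (is.null(v$id) || is.null(v$segments) || is.null(v$fps)) {
      stop("manifest video needs id, segments and fps")
    }
    v$segments <- file.path(base, v$segments)
    if (!is.null(v$gt)) v$gt <- file.path(base, v$gt)
    v
  })
  ids <- vapply(vids, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate video ids in manifest")
  list(videos = vids)
}

#' Detect reactions for one segments file
#'
#' The full single-video pipeline: read records, validate, measure widths,
#' interpolate, detect. Per-stage counts are logged to the message stream.
#'
#' @param segments_path JSON-Lines segmentation records.
#' @param fps Frame rate.
#' @param total_frames Total video frames; defaults to the largest frame
#'   index + 1.
#' @param config A [detection_config()].
#' @return A `reaction_set` (see [detect_reactions()]).
#' @export
detect_from_file <- function(segments_path, fps, total_frames = NULL,
                             config = detection_config()) {
  segs <- read_frame_segments(segments_path)
  reports <- validate_frames(segs)
  widths <- measure_widths(segs, reports)
  log_msg("%s: %d frames read, %d valid", segments_path, length(segs), nrow(widths))
  signal <- interpolate_widths(widths, total_frames, fps)
  det <- detect_reactions(signal, config)
  log_msg("%s: %d frames interpolated, %d reactions emitted",
          segments_path, sum(!signal$measured), nrow(det))
  det
}

#' Run detection over a manifest of videos
#'
#' Processes each video independently; a failing video is logged and skipped
#' while the others continue. Per-video reaction JSON files are written to
#' `output_dir` when given.
#'
#' @param manifest A manifest list (see [read_manifest()]) or a path to one.
#' @param config A [detection_config()].
#' @param output_dir Optional directory for `<id>_reactions.json` files.
#' @return A summary data.frame with one row per processed video: `id`,
#'   `n_reactions` and `strongest_ratio_change` (largest absolute
#'   pupil/limbus ratio change among its reactions, in percentage points);
#'   attribute `failures` names the videos that errored, and attribute
#'   `reactions` holds the per-video `reaction_set`s.
#' @export
run_detect <- function(manifest, config = detection_config(), output_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  rows <- list()
  dets <- list()
  failures <- character(0)
  for (v in manifest$videos) {
    det <- tryCatch(
      detect_from_file(v$segments, v$fps, v$total_frames, config),
      error = function(e) {
        log_msg("video %s failed: %s", v$id, conditionMessage(e))
        NULL
      }
    )
    if (is.null(det)) {
      failures <- c(failures, v$id)
      next
    }
    if (!is.null(output_dir)) {
      write_reactions(det, file.path(output_dir, paste0(v$id, "_reactions.json")))
    }
    dets[[v$id]] <- det
    rows[[v$id]] <- data.frame(
      id = v$id,
      n_reactions = nrow(det),
      strongest_ratio_change = if (nrow(det) > 0L) {
        100 * max(abs(det$ratio_change))
      } else 0,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(id = character(0), n_reactions = integer(0),
               strongest_ratio_change = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  attr(out, "reactions") <- dets
  out
}

#' Evaluate a predictions file against a ground-truth file
#'
#' @param pred_path Reactions JSON (see [write_reactions()]).
#' @param gt_path Ground-truth JSON (see [read_ground_truth()]).
#' @param cfg A [match_config()].
#' @param groups Optional subset of intensities to restrict the ground truth
#'   to (see [evaluate_by_intensity()]).
#' @return An `evaluation_result`.
#' @export
run_evaluate <- function(pred_path, gt_path, cfg = match_config(), groups = NULL) {
  pred <- read_reactions(pred_path)
  gt <- read_ground_truth(gt_path)
  fps <- attr(gt, "fps")
  if (is.null(fps)) fps <- 25
  if (is.null(groups)) {
    evaluate_detections(pred, gt, cfg, fps)
  } else {
    evaluate_by_intensity(pred, gt, groups, cfg, fps)
  }
}

#' Simulate a video and write its artifacts
#'
#' Writes `segments.jsonl` (rendered per-frame records), `gt.json` and
#' `spec.json` into `out_dir`.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [render_eye_frames()] (frame size, `masks`, ...).
#' @return The `synthetic_video`, invisibly.
#' @export
run_simulate <- function(spec = simulation_spec(), out_dir, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  video <- simulate_video(spec)
  render_eye_frames(video, file.path(out_dir, "segments.jsonl"), ...)
  write_ground_truth(video$gt, file.path(out_dir, "gt.json"), fps = video$fps)
  jsonlite::write_json(video$spec[setdiff(names(video$spec), "relative_size_ranges")],
                       file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = 6)
  invisible(video)
}

#' Run a hyperparameter sweep from a manifest
#'
#' Builds each video's width signal from its segments file and sweeps the
#' grid (see [run_sweep()]); every video in the manifest must carry a `gt`
#' path.
#'
#' @param manifest A manifest list or path (see [read_manifest()]).
#' @param grid A [sweep_grid()].
#' @param cfg A [match_config()].
#' @return A `sweep_result`.
#' @export
run_sweep_manifest <- function(manifest, grid = sweep_grid(), cfg = match_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  signals <- list()
  gts <- list()
  for (v in manifest$videos) {
    if (is.null(v$gt)) stop("video ", v$id, " has no ground-truth path")
    segs <- read_frame_segments(v$segments)
    widths <- measure_widths(segs)
    signals[[v$id]] <- interpolate_widths(widths, v$total_frames, v$fps)
    gts[[v$id]] <- read_ground_truth(v$gt)
  }
  run_sweep(signals, gts, grid, cfg)
}
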