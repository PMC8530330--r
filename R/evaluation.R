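# Interval-matching evaluation: Recall, Precision, Ground Truth Coverage
# Rate (GTCR), their harmonic mean H, and the adaptive IoU pre-filter.
#
# Count definitions (with Pc = number of correct predictions):
#   tp  ground-truth reactions detected by some retained prediction
#   fn  ground-truth reactions left undetected
#   Pc  retained predictions that detect at least one ground truth
#   fp  retained predictions that detect none
#   Recall = tp / (tp + fn);  GTCR = Pc / tp;  Precision = Pc / (Pc + fp).
# Note on Precision: the printed formula in the source method is
# tp / (tp + fp), but its own worked example (precision 33% with three
# detected ground truths, three predictions of which two are wrong) is only
# consistent with correct-predictions / all-predictions; this package
# implements the operational definition Pc / (Pc + fp).

#' Read a ground-truth annotation file
#'
#' JSON of the form `{"fps": float, "reactions": [{"start_frame",
#' "end_frame", "intensity", "clarity"}]}` with intensity in
#' weak/medium/strong and clarity in obvious/unclear.
#'
#' @param path Path to the JSON file.
#' @return A data.frame with columns `start_frame`, `end_frame`,
#'   `intensity`, `clarity`, sorted, with attribute `fps`.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  gt <- as.data.frame(obj$reactions)
  if (nrow(gt) > 0L) gt <- gt[order(gt$start_frame), , drop = FALSE]
  rownames(gt) <- NULL
  check_gt(gt)
  attr(gt, "fps") <- obj$fps
  gt
}

#' Write a ground-truth annotation file
#'
#' @param gt Ground-truth data.frame (see [read_ground_truth()]).
#' @param path Output path.
#' @param fps Frame rate stored in the file; defaults to the data.frame's
#'   `fps` attribute.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path, fps = attr(gt, "fps")) {
  jsonlite::write_json(list(fps = fps, reactions = as.data.frame(gt)),
                       path, auto_unbox = TRUE, digits = 6, dataframe = "rows")
  invisible(path)
}

check_gt <- function(gt) {
  if (nrow(gt) == 0L) return(invisible(gt))
  if (any(gt$end_frame <= gt$start_frame)) stop("ground truth interval with end <= start")
  o <- order(gt$start_frame)
  if (any(gt$end_frame[o][-nrow(gt)] > gt$start_frame[o][-1L])) {
    stop("overlapping ground truth intervals")
  }
  invisible(gt)
}

#' Matching configuration
#'
#' @param apply_iou_filter Drop predictions whose temporal IoU with every
#'   ground-truth interval is at most the adaptive threshold
#'   [iou_threshold()] before counting. Default `TRUE`; turn off to
#'   reproduce the schematic worked examples ([fig7_fixture()]), which are
#'   defined without the filter.
#' @param containment_fraction Fraction of a ground-truth interval a
#'   prediction must cover for the ground truth to count as detected.
#'   Default 1 (full containment).
#' @return A `match_config` object.
#' @export
match_config <- function(apply_iou_filter = TRUE, containment_fraction = 1) {
  if (containment_fraction <= 0 || containment_fraction > 1) {
    stop("containment_fraction must lie in (0, 1]")
  }
  structure(list(apply_iou_filter = isTRUE(apply_iou_filter),
                 containment_fraction = containment_fraction),
            class = "match_config")
}

#' Adaptive IoU threshold
#'
#' The ratio `min(GTL, PL) / max(GTL, PL)` of the average ground-truth
#' segment length and the average predicted segment length: predictions much
#' longer than a typical annotation must overlap a ground truth
#' substantially to be kept.
#'
#' @param gtl_seconds Average ground-truth segment duration (s), positive.
#' @param pl_seconds Average predicted segment duration (s), positive.
#' @return A value in (0, 1].
#' @export
iou_threshold <- function(gtl_seconds, pl_seconds) {
  if (gtl_seconds <= 0 || pl_seconds <= 0) stop("durations must be positive")
  min(gtl_seconds, pl_seconds) / max(gtl_seconds, pl_seconds)
}

# pairwise temporal IoU and overlap between interval sets (half-open frames)
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

#' Match predictions against ground truth
#'
#' Optionally applies the adaptive IoU pre-filter (computed once from the
#' current prediction and ground-truth sets), then counts: a ground truth is
#' detected when some retained prediction covers at least
#' `containment_fraction` of it; a retained prediction is correct when it
#' detects at least one ground truth.
#'
#' @param predictions data.frame with `start_frame`, `end_frame`.
#' @param gt Ground-truth data.frame with `start_frame`, `end_frame`.
#' @param cfg A [match_config()].
#' @param fps Frame rate used to express durations in seconds.
#' @return A list with counts `tp`, `fn`, `fp`, `pc`, the per-ground-truth
#'   logical `detected`, the per-prediction logical `retained` and
#'   `correct`, and `gtl_seconds`, `pl_seconds`, `iou_tr` (the latter `NA`
#'   when the filter is off or either set is empty).
#' @export
match_segments <- function(predictions, gt, cfg = match_config(), fps = 25) {
  check_gt(gt)
  np <- nrow(predictions)
  ng <- nrow(gt)
  gtl <- if (ng > 0L) mean(gt$end_frame - gt$start_frame) / fps else NA_real_
  pl_all <- if (np > 0L) mean(predictions$end_frame - predictions$start_frame) / fps else NA_real_
  retained <- rep(TRUE, np)
  iou_tr <- NA_real_
  if (cfg$apply_iou_filter && np > 0L && ng > 0L) {
    iou_tr <- iou_threshold(gtl, pl_all)
    best_iou <- vapply(seq_len(np), function(i) {
      inter <- interval_overlap(predictions$start_frame[i], predictions$end_frame[i],
                                gt$start_frame, gt$end_frame)
      union <- (predictions$end_frame[i] - predictions$start_frame[i]) +
        (gt$end_frame - gt$start_frame) - inter
      max(inter / union)
    }, numeric(1L))
    retained <- best_iou > iou_tr
  }
  ret_idx <- which(retained)
  detected <- logical(ng)
  correct <- logical(np)
  for (i in ret_idx) {
    if (ng == 0L) break
    cov <- interval_overlap(predictions$start_frame[i], predictions$end_frame[i],
                            gt$start_frame, gt$end_frame) /
      (gt$end_frame - gt$start_frame)
    hits <- cov >= cfg$containment_fraction - 1e-12
    if (any(hits)) {
      correct[i] <- TRUE
      detected <- detected | hits
    }
  }
  pl_ret <- if (length(ret_idx) > 0L) {
    mean(predictions$end_frame[ret_idx] - predictions$start_frame[ret_idx]) / fps
  } else 0
  list(
    tp = sum(detected), fn = ng - sum(detected),
    pc = sum(correct), fp = length(ret_idx) - sum(correct),
    detected = detected, retained = retained, correct = correct,
    gtl_seconds = gtl, pl_seconds = pl_ret, iou_tr = iou_tr
  )
}

#' Harmonic mean of positive components
#'
#' `k / sum(1 / x)` for `k` components; 0 when any component is zero or
#' negative (the harmonic-mean limit), which avoids division by zero for
#' degenerate evaluations.
#'
#' @param x Numeric vector of components on a common scale.
#' @return The harmonic mean.
#' @export
harmonic_mean <- function(x) {
  if (any(x <= 0)) return(0)
  length(x) / sum(1 / x)
}

metrics_from_counts <- function(tp, fn, fp, pc) {
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  precision <- if (pc + fp > 0L) pc / (pc + fp) else 0
  gtcr <- if (tp > 0L) pc / tp else 0
  list(recall = recall, precision = precision, gtcr = gtcr,
       h = harmonic_mean(c(recall, precision, gtcr)))
}

#' Evaluate predicted reactions against ground truth
#'
#' Runs [match_segments()] and derives Recall, Precision, GTCR and their
#' harmonic mean H, plus the average retained-prediction duration PL.
#'
#' @inheritParams match_segments
#' @return An `evaluation_result`: list with counts `tp`, `fn`, `fp`, `pc`
#'   and metrics `recall`, `precision`, `gtcr`, `h` (fractions in `[0, 1]`),
#'   `pl_seconds`, `gtl_seconds`, `iou_tr`. Any metric with a zero
#'   denominator is 0, and H is then 0.
#' @examples
#' fx <- fig7_fixture("pred1")
#' evaluate_detections(fx$predictions, fx$gt,
#'                     match_config(apply_iou_filter = FALSE), fps = fx$fps)
#' @export
evaluate_detections <- function(predictions, gt, cfg = match_config(), fps = 25) {
  m <- match_segments(predictions, gt, cfg, fps)
  met <- metrics_from_counts(m$tp, m$fn, m$fp, m$pc)
  structure(
    c(m[c("tp", "fn", "fp", "pc")], met,
      m[c("pl_seconds", "gtl_seconds", "iou_tr")]),
    class = "evaluation_result"
  )
}

#' Evaluate against ground truth restricted to chosen intensities
#'
#' Keeps only ground-truth reactions of the named intensities before
#' matching, leaving the prediction set unrestricted — so precision
#' naturally drops as the ground truth shrinks while recall shows how well
#' the chosen intensities are retrieved.
#'
#' @inheritParams evaluate_detections
#' @param groups Non-empty subset of `c("weak", "medium", "strong")`.
#' @return An `evaluation_result`.
#' @export
evaluate_by_intensity <- function(predictions, gt, groups,
                                  cfg = match_config(), fps = 25) {
  groups <- match.arg(groups, c("weak", "medium", "strong"), several.ok = TRUE)
  sub <- gt[gt$intensity %in% groups, , drop = FALSE]
  evaluate_detections(predictions, sub, cfg, fps)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("tp %d  fn %d  fp %d  Pc %d\n", x$tp, x$fn, x$fp, x$pc))
  cat(sprintf("Recall    %6.2f%%\n", 100 * x$recall))
  cat(sprintf("Precision %6.2f%%\n", 100 * x$precision))
  cat(sprintf("GTCR      %6.2f%%\n", 100 * x$gtcr))
  cat(sprintf("H         %6.2f%%\n", 100 * x$h))
  cat(sprintf("PL %.2f s  GTL %.2f s", x$pl_seconds, x$gtl_seconds))
  if (!is.na(x$iou_tr)) cat(sprintf("  IoU_tr %.3f", x$iou_tr))
  cat("\n")
  invisible(x)
}
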