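# Grid search over cutoff frequency and Delta (and analysis mode): the
# detector's two hyperparameters are dataset-dependent, so the sweep reports
# H and PL per configuration and selects the best H subject to a cap on the
# average predicted-segment duration.

#' Hyperparameter sweep grid
#'
#' @param cutoffs_hz Cutoff frequencies in Hz. The default grid is
#'   `c(0.01, 0.05, 0.1, 0.15, 0.2)`.
#' @param deltas Relevance thresholds as fractions of DM; default
#'   `seq(0, 0.2, by = 0.02)`.
#' @param modes Subset of `c("pupil", "difference")`.
#' @param max_pl_seconds Configurations whose average predicted-segment
#'   duration exceeds this bound are never selected as best, however good
#'   their H: a prediction much longer than a one-second reaction is useless
#'   to a clinician. Default 60 s; `Inf` disables the bound.
#' @return A `sweep_grid` object.
#' @export
sweep_grid <- function(cutoffs_hz = c(0.01, 0.05, 0.1, 0.15, 0.2),
                       deltas = seq(0, 0.2, by = 0.02),
                       modes = "pupil",
                       max_pl_seconds = 60) {
  if (length(cutoffs_hz) == 0L || length(deltas) == 0L || length(modes) == 0L) {
    stop("empty sweep grid")
  }
  if (any(deltas < 0 | deltas > 1)) stop("deltas must lie in [0, 1]")
  modes <- match.arg(modes, c("pupil", "difference"), several.ok = TRUE)
  structure(list(cutoffs_hz = cutoffs_hz, deltas = deltas, modes = modes,
                 max_pl_seconds = max_pl_seconds),
            class = "sweep_grid")
}

#' Grid search over detector hyperparameters
#'
#' For every (cutoff, delta, mode) cell, detects reactions on each video,
#' pools the match counts (tp, fn, fp, Pc) across videos, and computes the
#' evaluation metrics from the pooled counts; PL pools all retained
#' predictions' durations. The best row maximizes H among rows whose PL does
#' not exceed the grid's `max_pl_seconds`.
#'
#' @param signals Named list of `width_signal` objects, one per video.
#' @param gts Named list of ground-truth data.frames aligned with `signals`
#'   by name.
#' @param grid A [sweep_grid()].
#' @param cfg A [match_config()] used for every cell.
#' @param order Butterworth filter order passed to the detector.
#' @return A `sweep_result`: list with `rows` (data.frame of cutoff, delta,
#'   mode, counts, metrics, `pl_seconds`, `n_predictions`) and `best` (the
#'   selected row, or `NULL` when every row violates the PL bound).
#' @export
run_sweep <- function(signals, gts, grid = sweep_grid(), cfg = match_config(),
                      order = 5L) {
  stopifnot(inherits(grid, "sweep_grid"))
  ids <- names(signals)
  if (is.null(ids) || !setequal(ids, names(gts))) {
    stop("signals and gts must be named lists with matching names")
  }
  cells <- expand.grid(cutoff_hz = grid$cutoffs_hz, delta = grid$deltas,
                       mode = grid$modes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    cc <- detection_config(cells$cutoff_hz[k], cells$delta[k], cells$mode[k], order)
    tp <- fn <- fp <- pc <- n_pred <- 0L
    dur_sum <- 0
    n_ret <- 0L
    for (id in ids) {
      det <- detect_reactions(signals[[id]], cc)
      m <- match_segments(det, gts[[id]], cfg, signals[[id]]$fps)
      tp <- tp + m$tp; fn <- fn + m$fn; fp <- fp + m$fp; pc <- pc + m$pc
      n_pred <- n_pred + nrow(det)
      ret <- which(m$retained)
      n_ret <- n_ret + length(ret)
      dur_sum <- dur_sum + sum((det$end_frame[ret] - det$start_frame[ret]) /
                                 signals[[id]]$fps)
    }
    met <- metrics_from_counts(tp, fn, fp, pc)
    data.frame(cutoff_hz = cells$cutoff_hz[k], delta = cells$delta[k],
               mode = cells$mode[k], tp = tp, fn = fn, fp = fp, pc = pc,
               recall = met$recall, precision = met$precision,
               gtcr = met$gtcr, h = met$h,
               pl_seconds = if (n_ret > 0L) dur_sum / n_ret else 0,
               n_predictions = n_pred,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  eligible <- rows$pl_seconds <= grid$max_pl_seconds
  best <- if (any(eligible)) {
    cand <- rows[eligible, , drop = FALSE]
    cand[which.max(cand$h), , drop = FALSE]
  } else NULL
  structure(list(rows = rows, best = best, grid = grid), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %d configurations\n", nrow(x$rows)))
  if (!is.null(x$best)) {
    b <- x$best
    cat(sprintf(
      "best: mode %s, cutoff %.3g Hz, delta %.3g -> H %.1f%% (PL %.1f s)\n",
      b$mode, b$cutoff_hz, b$delta, 100 * b$h, b$pl_seconds
    ))
  } else {
    cat("no configuration satisfies the PL bound\n")
  }
  invisible(x)
}

#' Write sweep rows as CSV
#'
#' @param result A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  utils::write.csv(result$rows, path, row.names = FALSE)
  invisible(path)
}
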