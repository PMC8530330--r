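# Independent brute-force oracles and small fixture builders shared across
# the test files. Each oracle deliberately uses a different algorithm than
# the implementation it checks.

# exhaustive pixel scan (no colSums/rowSums shortcut)
oracle_tight_box <- function(mask) {
  xmin <- Inf; xmax <- -Inf; ymin <- Inf; ymax <- -Inf
  for (r in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      if (mask[r, cc]) {
        xmin <- min(xmin, cc - 1); xmax <- max(xmax, cc)
        ymin <- min(ymin, r - 1); ymax <- max(ymax, r)
      }
    }
  }
  c(x_min = xmin, y_min = ymin, x_max = xmax, y_max = ymax)
}

random_mask <- function(h, w) {
  m <- matrix(runif(h * w) < 0.2, h, w)
  r0 <- sample(h, 1); r1 <- sample(r0:h, 1)
  c0 <- sample(w, 1); c1 <- sample(c0:w, 1)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# neighbor comparison with plateau collapsing, O(n) scan
oracle_extrema <- function(x) {
  n <- length(x)
  out <- 0L
  i <- 1L
  prev_slope <- 0
  while (i < n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # skip plateau
    if (j == n) break
    slope <- sign(x[j + 1L] - x[i])
    if (prev_slope != 0 && slope != prev_slope) out <- c(out, i - 1L)
    prev_slope <- slope
    i <- j + 1L
  }
  sort(unique(c(out, n - 1L)))
}

# explicit two-pass fill: forward fill, then backfill the leading run
oracle_fill <- function(frames, pupil, limbus, total) {
  pw <- rep(NA_real_, total); lw <- rep(NA_real_, total)
  pw[frames + 1L] <- pupil; lw[frames + 1L] <- limbus
  for (i in seq_len(total)[-1L]) {
    if (is.na(pw[i])) { pw[i] <- pw[i - 1L]; lw[i] <- lw[i - 1L] }
  }
  for (i in rev(seq_len(total - 1L))) {
    if (is.na(pw[i])) { pw[i] <- pw[i + 1L]; lw[i] <- lw[i + 1L] }
  }
  list(pupil = pw, limbus = lw)
}

# O(n*m) interval scan (IoU filter off)
oracle_match_counts <- function(pred, gt, frac = 1) {
  detected <- rep(FALSE, nrow(gt))
  correct <- rep(FALSE, nrow(pred))
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(gt))) {
      inter <- max(0, min(pred$end_frame[i], gt$end_frame[j]) -
                     max(pred$start_frame[i], gt$start_frame[j]))
      if (inter / (gt$end_frame[j] - gt$start_frame[j]) >= frac - 1e-12) {
        detected[j] <- TRUE
        correct[i] <- TRUE
      }
    }
  }
  list(tp = sum(detected), fn = sum(!detected),
       pc = sum(correct), fp = sum(!correct))
}

# random non-overlapping sorted ground truth over [0, horizon)
random_gt <- function(n, horizon) {
  cuts <- sort(sample(horizon, 2L * n))
  data.frame(start_frame = cuts[seq(1, 2 * n, 2)],
             end_frame = cuts[seq(2, 2 * n, 2)],
             intensity = sample(c("weak", "medium", "strong"), n, replace = TRUE),
             clarity = "obvious", stringsAsFactors = FALSE)
}

random_predictions <- function(n, horizon) {
  s <- sample(horizon - 1L, n, replace = TRUE)
  data.frame(start_frame = s, end_frame = s + sample(50L, n, replace = TRUE))
}

# width_signal built directly from arrays
make_signal <- function(pupil, limbus, fps = 25, measured = rep(TRUE, length(pupil))) {
  structure(list(fps = fps, pupil_width = pupil, limbus_width = limbus,
                 measured = measured),
            class = "width_signal")
}

fig7_eval <- function(variant) {
  fx <- fig7_fixture(variant)
  evaluate_detections(fx$predictions, fx$gt,
                      match_config(apply_iou_filter = FALSE), fx$fps)
}
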