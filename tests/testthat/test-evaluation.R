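test_that("the adaptive IoU threshold is min/max of the average durations", {
  expect_equal(iou_threshold(1.5, 1.5), 1.0)
  expect_equal(iou_threshold(1.0, 10.2), 1.0 / 10.2)
  expect_equal(iou_threshold(2, 4), 0.5)
  expect_equal(iou_threshold(4, 2), 0.5)
  expect_error(iou_threshold(0, 1), "positive")
})

test_that("the three schematic prediction sets reproduce their metrics", {
  r1 <- fig7_eval("pred1")
  expect_equal(c(r1$tp, r1$fn, r1$fp, r1$pc), c(3, 1, 0, 3))
  expect_equal(r1$recall, 0.75)
  expect_equal(r1$precision, 1.0)
  expect_equal(r1$gtcr, 1.0)
  expect_equal(r1$h, 0.90)

  r2 <- fig7_eval("pred2")
  expect_equal(c(r2$tp, r2$fn, r2$fp, r2$pc), c(3, 1, 2, 1))
  expect_equal(r2$recall, 0.75)
  expect_equal(r2$precision, 1 / 3)
  expect_equal(r2$gtcr, 1 / 3)
  expect_equal(r2$h, 9 / 22)  # exact fraction, 40.9%
  # with components first rounded to whole percents, H is 40.6%
  h_rounded <- harmonic_mean(round(100 * c(r2$recall, r2$precision, r2$gtcr)))
  expect_equal(round(h_rounded, 1), 40.6)

  r3 <- fig7_eval("pred3")
  expect_equal(c(r3$tp, r3$fn, r3$fp, r3$pc), c(4, 0, 0, 1))
  expect_equal(r3$recall, 1.0)
  expect_equal(r3$precision, 1.0)
  expect_equal(r3$gtcr, 0.25)
  expect_equal(r3$h, 0.50)
})

test_that("degenerate evaluations report zeros instead of dividing by zero", {
  gt <- fig7_fixture("pred1")$gt
  none <- data.frame(start_frame = integer(0), end_frame = integer(0))
  r <- evaluate_detections(none, gt, match_config(FALSE), 25)
  expect_equal(c(r$recall, r$precision, r$gtcr, r$h), c(0, 0, 0, 0))
  expect_equal(r$fn, 4)

  perfect <- evaluate_detections(gt[, 1:2], gt, match_config(FALSE), 25)
  expect_equal(c(perfect$recall, perfect$precision, perfect$gtcr, perfect$h),
               c(1, 1, 1, 1))
})

test_that("match counts equal the exhaustive interval-intersection oracle", {
  set.seed(61)
  cfg <- match_config(apply_iou_filter = FALSE)
  for (i in 1:100) {
    gt <- random_gt(sample(1:8, 1), 2000L)
    pred <- random_predictions(sample(0:10, 1), 2000L)
    m <- match_segments(pred, gt, cfg, 25)
    o <- oracle_match_counts(pred, gt)
    expect_equal(m[c("tp", "fn", "pc", "fp")], o)
    # conservation
    expect_equal(m$tp + m$fn, nrow(gt))
    expect_equal(m$pc + m$fp, nrow(pred))
    if (m$tp > 0) expect_lte(m$pc, m$tp)   # GTCR <= 1 by construction
  }
})

test_that("a spurious non-overlapping prediction only lowers precision", {
  fx <- fig7_fixture("pred1")
  cfg <- match_config(FALSE)
  base <- evaluate_detections(fx$predictions, fx$gt, cfg, fx$fps)
  noisy <- rbind(fx$predictions, data.frame(start_frame = 950L, end_frame = 980L))
  r <- evaluate_detections(noisy, fx$gt, cfg, fx$fps)
  expect_equal(r$recall, base$recall)
  expect_equal(r$gtcr, base$gtcr)
  expect_lt(r$precision, base$precision)
})

test_that("the IoU pre-filter drops overlong predictions before counting", {
  gt <- data.frame(start_frame = c(100L, 600L), end_frame = c(125L, 625L),
                   intensity = "medium", clarity = "obvious")
  pred <- data.frame(start_frame = c(100L, 0L), end_frame = c(125L, 2000L))
  m <- match_segments(pred, gt, match_config(apply_iou_filter = TRUE), 25)
  expect_equal(m$retained, c(TRUE, FALSE))
  expect_equal(m$tp, 1)            # only the exact prediction counts
  expect_equal(m$pl_seconds, 1.0)  # PL over retained predictions
  expect_equal(m$iou_tr, 1 / 40.5) # GTL 1 s vs mean PL (25+2000)/2 frames

  off <- match_segments(pred, gt, match_config(apply_iou_filter = FALSE), 25)
  expect_equal(off$tp, 2)
})

test_that("partial-coverage detection follows containment_fraction", {
  gt <- data.frame(start_frame = 100L, end_frame = 200L,
                   intensity = "strong", clarity = "obvious")
  pred <- data.frame(start_frame = 100L, end_frame = 160L)  # covers 60%
  full <- match_segments(pred, gt, match_config(FALSE, 1.0), 25)
  expect_equal(full$tp, 0)
  half <- match_segments(pred, gt, match_config(FALSE, 0.5), 25)
  expect_equal(half$tp, 1)
})

test_that("harmonic mean matches the closed form and zero limit", {
  set.seed(62)
  for (i in 1:20) {
    x <- runif(3, 0.01, 1)
    expect_equal(harmonic_mean(x), 3 * prod(x) / sum(prod(x) / x),
                 tolerance = 1e-12)
  }
  expect_equal(harmonic_mean(c(0.5, 0, 0.9)), 0)
})

test_that("intensity-restricted evaluation prefilters only the ground truth", {
  gt <- data.frame(start_frame = c(100L, 300L), end_frame = c(125L, 325L),
                   intensity = c("weak", "strong"), clarity = "obvious")
  pred <- data.frame(start_frame = 300L, end_frame = 325L)
  cfg <- match_config(FALSE)
  strong <- evaluate_by_intensity(pred, gt, "strong", cfg, 25)
  expect_equal(strong$recall, 1.0)
  all3 <- evaluate_by_intensity(pred, gt, c("weak", "medium", "strong"), cfg, 25)
  expect_equal(unclass(all3), unclass(evaluate_detections(pred, gt, cfg, 25)))

  set.seed(63)
  gt2 <- random_gt(8, 2000L)
  pred2 <- random_predictions(6, 2000L)
  manual <- evaluate_detections(pred2, gt2[gt2$intensity %in% c("medium", "strong"), ],
                                cfg, 25)
  auto <- evaluate_by_intensity(pred2, gt2, c("medium", "strong"), cfg, 25)
  expect_equal(unclass(auto), unclass(manual))
})

test_that("overlapping ground-truth annotations are rejected", {
  gt <- data.frame(start_frame = c(100L, 110L), end_frame = c(125L, 130L),
                   intensity = "weak", clarity = "obvious")
  pred <- data.frame(start_frame = 1L, end_frame = 2L)
  expect_error(match_segments(pred, gt, match_config(FALSE), 25), "overlapping")
})

test_that("ground-truth JSON round-trips", {
  gt <- fig7_fixture("pred1")$gt
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, path, fps = 25)
  back <- read_ground_truth(path)
  expect_equal(back$start_frame, gt$start_frame)
  expect_equal(back$intensity, gt$intensity)
  expect_equal(attr(back, "fps"), 25)
})
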