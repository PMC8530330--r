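test_that("DM is the difference of the unfiltered medians", {
  expect_equal(compute_dm(make_signal(rep(60, 10), rep(100, 10))), 40)
  expect_equal(compute_dm(make_signal(c(60, 58, 62), c(100, 100, 102))), 40)

  set.seed(51)
  pw <- runif(10000, 50, 90); lw <- runif(10000, 95, 130)
  sort_median <- function(v) {  # sort-based middle-element/midpoint oracle
    s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  expect_equal(compute_dm(make_signal(pw, lw)),
               sort_median(lw) - sort_median(pw))

  expect_error(compute_dm(make_signal(rep(100, 5), rep(60, 5))), "degenerate")
})

test_that("extrema include boundaries, turning points and plateau heads", {
  expect_equal(find_extrema(1:10), c(0L, 9L))
  tri <- c(0:50, 49:0)
  expect_equal(find_extrema(tri), c(0L, 50L, 100L))
  # plateau at the top contributes its first frame only
  expect_equal(find_extrema(c(0, 1, 2, 2, 2, 1, 0)), c(0L, 2L, 6L))
  expect_error(find_extrema(5), "at least 2")
})

test_that("extrema agree with the neighbor-scan oracle on random signals", {
  set.seed(52)
  spec <- filter_spec(0.5, 3, 25)
  for (i in 1:100) {
    x <- lowpass(cumsum(rnorm(300)), spec)
    expect_equal(find_extrema(x), oracle_extrema(x))
  }
})

test_that("an injected step is detected iff it clears the Delta threshold", {
  # limbus 100, pupil baseline 60 -> DM = 40; smooth step of 8 px = 0.2 DM
  n <- 3000
  t <- (0:(n - 1)) / 25
  pupil <- 60 - 8 * plogis((t - 80) / 0.15)
  sig <- make_signal(pupil, rep(100, n))
  cfg <- detection_config(cutoff_hz = 0.1, delta = 0.1, mode = "pupil")
  det <- detect_reactions(sig, cfg)
  big <- det[det$relative_size >= 0.1, ]
  expect_equal(nrow(big), 1L)
  expect_lt(big$start_frame, 80 * 25)
  expect_gt(big$end_frame, 80 * 25)
  expect_equal(big$direction, "constriction")
  # zero-phase Butterworth step response over/undershoots, inflating the
  # extremum-to-extremum size somewhat beyond the injected 0.2 DM
  expect_gte(big$relative_size, 0.18)
  expect_lte(big$relative_size, 0.26)

  none <- detect_reactions(sig, detection_config(0.1, 0.3, "pupil"))
  expect_equal(nrow(none), 0L)

  flat <- detect_reactions(make_signal(rep(60, n), rep(100, n)),
                           detection_config(0.1, 0.05, "pupil"))
  expect_equal(nrow(flat), 0L)
})

test_that("raising Delta only removes reactions (subset monotonicity)", {
  for (seed in 1:5) {
    sig <- synthetic_signal(simulate_video(simulation_spec(seed = seed, duration_s = 120,
                                                           n_reactions = 4)))
    prev <- NULL
    for (delta in seq(0, 0.2, by = 0.02)) {
      det <- detect_reactions(sig, detection_config(0.1, delta, "pupil"))
      key <- paste(det$start_frame, det$end_frame)
      if (!is.null(prev)) expect_true(all(key %in% prev))
      prev <- key
      # segments are sorted and non-overlapping (shared endpoints allowed)
      expect_true(all(diff(det$start_frame) > 0))
      expect_true(all(det$end_frame > det$start_frame))
      if (nrow(det) > 1) {
        expect_true(all(det$start_frame[-1] >= det$end_frame[-nrow(det)]))
      }
    }
  }
})

test_that("pupil and difference modes coincide when the limbus is constant", {
  sig <- synthetic_signal(simulate_video(
    simulation_spec(seed = 53, duration_s = 120, n_reactions = 4,
                    noise_sd_px = 0, dropout_rate = 0)
  ))
  sig$limbus_width[] <- 400
  a <- detect_reactions(sig, detection_config(0.1, 0.08, "pupil"))
  b <- detect_reactions(sig, detection_config(0.1, 0.08, "difference"))
  expect_equal(a$start_frame, b$start_frame)
  expect_equal(a$end_frame, b$end_frame)
  expect_equal(abs(a$size_px), abs(b$size_px))
  expect_equal(a$direction, b$direction)
})

test_that("ratio change is the two-point pupil/limbus difference", {
  n <- 3000  # long settled spans so the smoothed endpoints sit at 60 and 48
  pupil <- c(rep(60, 1400), seq(60, 48, length.out = 200), rep(48, 1400))
  sig <- make_signal(pupil, rep(100, n))
  cfg <- detection_config(0.1, 0.05, "pupil")
  seg <- list(start_frame = 0L, end_frame = n - 1L)
  expect_equal(reaction_ratio_change(sig, seg, cfg), -0.12, tolerance = 1e-3)

  flat <- make_signal(rep(60, n), rep(100, n))
  expect_equal(reaction_ratio_change(flat, seg, cfg), 0)

  # recompute from the filtered arrays directly
  det <- detect_reactions(sig, cfg)
  spec <- filter_spec(0.1, 5, 25)
  pf <- lowpass(sig$pupil_width, spec); lf <- lowpass(sig$limbus_width, spec)
  for (k in seq_len(nrow(det))) {
    expect_equal(det$ratio_change[k],
                 pf[det$end_frame[k] + 1] / lf[det$end_frame[k] + 1] -
                   pf[det$start_frame[k] + 1] / lf[det$start_frame[k] + 1])
  }
})

test_that("reactions JSON round-trips with its context", {
  sig <- synthetic_signal(simulate_video(simulation_spec(seed = 54, duration_s = 60,
                                                         n_reactions = 2)))
  det <- detect_reactions(sig, detection_config(0.1, 0.1, "pupil"))
  path <- withr::local_tempfile(fileext = ".json")
  write_reactions(det, path)
  back <- read_reactions(path)
  expect_equal(back$start_frame, det$start_frame)
  expect_equal(back$end_frame, det$end_frame)
  expect_equal(attr(back, "dm"), attr(det, "dm"), tolerance = 1e-5)
  expect_equal(attr(back, "config")$delta, 0.1)
})
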