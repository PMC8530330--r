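# Zero-phase Butterworth low-pass smoothing of width signals.
#
# The filter is applied forward and then backward ("two-fold" processing) so
# the smoothed signal has no temporal shift relative to the original; a
# detected extremum therefore sits at the true time of the size change.
#
# The Butterworth filter is realized as a cascade of second-order sections
# (biquads) designed analytically via the bilinear transform. At this
# detector's operating cutoffs (0.01-0.2 Hz against a 12.5 Hz Nyquist) the
# poles sit so close to the unit circle that a single transfer-function
# recursion accumulates roundoff of ~1e-8 relative; the cascade keeps each
# section well conditioned.

#' Low-pass filter specification
#'
#' @param cutoff_hz Cutoff frequency in Hz; must lie below the Nyquist
#'   frequency `fps / 2`. The detector's usual operating range is
#'   0.01-0.2 Hz: a pupil reaction lasts about a second, but the surrounding
#'   segmentation jitter is much faster, so a sub-Hz cutoff separates the
#'   two.
#' @param order Butterworth filter order (>= 1). Default 5, a common choice
#'   giving a sharp transition band; results should not hinge on the exact
#'   order, which is why it stays configurable.
#' @param fps Sampling rate of the signal in frames per second. The digital
#'   cutoff is `cutoff_hz / (fps / 2)`, so the same `cutoff_hz` means the
#'   same physical smoothing at any frame rate.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(cutoff_hz = 0.1, order = 5L, fps = 25) {
  if (fps <= 0) stop("fps must be positive")
  if (cutoff_hz <= 0 || cutoff_hz >= fps / 2) {
    stop("cutoff_hz must lie in (0, fps/2)")
  }
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("order must be a positive integer")
  structure(list(cutoff_hz = cutoff_hz, order = order, fps = fps),
            class = "filter_spec")
}

# Digital Butterworth low-pass as second-order sections. wn is the cutoff as
# a fraction of Nyquist. Analog prototype poles wc*exp(i*pi*(2k+n-1)/(2n))
# are mapped by the bilinear transform (T = 2, cutoff prewarped); zeros land
# at z = -1. Each section is normalized to unit DC gain.
butter_sos <- function(order, wn) {
  wc <- tan(pi * wn / 2)
  k <- seq_len(order)
  sp <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  zp <- (1 + sp) / (1 - sp)
  secs <- list()
  i <- 1L
  while (i <= order) {
    if (abs(Im(zp[i])) > 1e-12) {
      a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2)
      b <- c(1, 2, 1)
      i <- i + 2L
    } else {
      a <- c(1, -Re(zp[i]), 0)
      b <- c(1, 1, 0)
      i <- i + 1L
    }
    secs[[length(secs) + 1L]] <- list(b = b * sum(a) / sum(b), a = a)
  }
  list(sections = secs, rmax = max(Mod(zp)))
}

# One causal pass through the cascade, each section started in the steady
# state of a constant input equal to its first sample (every section has
# unit DC gain, so the consistent state is inputs = outputs = x[1]).
sos_pass <- function(sections, x) {
  for (s in sections) {
    x <- as.numeric(signal::filter(s$b, s$a, x,
                                   init.x = rep(x[1L], 2L),
                                   init.y = rep(x[1L], 2L)))
  }
  x
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies a Butterworth low-pass filter forward and then backward over the
#' signal, eliminating the phase shift a single pass would introduce. The
#' effective amplitude response is the squared Butterworth magnitude. Edges
#' are handled by odd-extension padding with steady-state initial
#' conditions, so constants pass through unchanged (unit DC gain). The
#' padding length is sized from the filter's slowest pole so its start-up
#' transient decays below 1e-13 within the padding (floored at `3 * order`,
#' capped at the signal length minus one): at sub-Hz cutoffs transients
#' persist for hundreds to thousands of samples, and a short fixed padding
#' would leak edge artifacts several seconds into the signal.
#'
#' @param x Numeric vector, one sample per frame.
#' @param spec A [filter_spec()].
#' @return Filtered numeric vector of the same length.
#' @examples
#' spec <- filter_spec(cutoff_hz = 0.1, order = 5, fps = 25)
#' lowpass(rep(42, 200), spec)[1:5]  # constant in, constant out
#' @export
lowpass <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n <= 3L * spec$order) {
    stop(sprintf("signal too short: need more than %d samples for order %d",
                 3L * spec$order, spec$order))
  }
  d <- butter_sos(spec$order, spec$cutoff_hz / (spec$fps / 2))
  np <- min(n - 1L, max(3L * spec$order, ceiling(log(1e-13) / log(d$rmax))))
  # centre for numerical conditioning (filter is linear with unit DC gain)
  m <- mean(x)
  xc <- x - m
  ext <- c(2 * xc[1L] - xc[(np + 1L):2L], xc, 2 * xc[n] - xc[(n - 1L):(n - np)])
  y <- sos_pass(d$sections, ext)
  y <- rev(sos_pass(d$sections, rev(y)))
  y[(np + 1L):(np + n)] + m
}

#' Analytic amplitude gain of the two-fold Butterworth filter
#'
#' Closed-form squared Butterworth magnitude response at a probe frequency,
#' with bilinear-transform prewarping, i.e. the amplitude ratio a pure
#' sinusoid experiences under [lowpass()]. Exposed mainly for verification.
#'
#' @param freq_hz Probe frequency in Hz.
#' @param spec A [filter_spec()].
#' @return Gain in (0, 1].
#' @export
butterworth_gain <- function(freq_hz, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- tan(pi * freq_hz / spec$fps)
  wc <- tan(pi * spec$cutoff_hz / spec$fps)
  single <- 1 / sqrt(1 + (w / wc)^(2 * spec$order))
  single^2  # forward + backward pass
}
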