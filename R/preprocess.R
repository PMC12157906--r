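#' @include AllClasses.R
NULL

#' Acceleration magnitude from tri-axial components
#'
#' `sqrt(ax^2 + ay^2 + az^2)`, vectorized over samples.
#'
#' @param ax,ay,az numeric vectors of equal length; all values finite.
#' @return non-negative numeric vector of magnitudes.
#' @examples
#' magnitude(3, 4, 0)  # 5
#' @export
magnitude <- function(ax, ay, az) {
  if (!all(is.finite(ax), is.finite(ay), is.finite(az)))
    stop("magnitude() requires finite inputs")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Split a trace into equal contiguous segments
#'
#' The default splits a 180-sample trace into the half-open index windows
#' [0,60), [60,120), [120,180): the start, mid-activity and finishing phases
#' of the instance.
#'
#' @param samples numeric vector.
#' @param n_segments number of equal windows; must divide `length(samples)`.
#' @return list of `n_segments` numeric vectors in temporal order.
#' @examples
#' length(segmentTrace(rnorm(180))[[1]])  # 60
#' @export
segmentTrace <- function(samples, n_segments = 3L) {
  n <- length(samples)
  if (n %% n_segments != 0L)
    stop("trace length ", n, " is not divisible by n_segments = ", n_segments)
  w <- n %/% n_segments
  lapply(seq_len(n_segments), function(k) samples[((k - 1L) * w + 1L):(k * w)])
}

# steady-state initial filter conditions (direct-form II transposed state
# for unit step input), solved from the companion system of `a`
lfilterZi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  solve(diag(n - 1L) - t(comp), b[-1L] - a[-1L] * b[1L])
}

# direct-form II transposed IIR filter with initial state zi
iirFilter <- function(b, a, x, zi) {
  n <- max(length(b), length(a))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  z <- c(zi, 0)
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1] * xm + z[1]
    for (i in seq_len(n - 1L)) {
      z[i] <- b[i + 1L] * xm + z[i + 1L] - a[i + 1L] * ym
    }
    y[m] <- ym
  }
  y
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Forward-backward application of a Butterworth low-pass filter
#' (coefficients from [signal::butter()]). The signal is extended at both
#' ends by odd reflection over `3 * (2 * order + 1)` samples and the filter
#' is started from its steady-state initial conditions, so a constant input
#' is reproduced exactly (DC gain 1) and the output has no phase shift.
#'
#' @param samples numeric vector; must be longer than the reflection pad
#'   (28 samples at the default order 4).
#' @param spec a [FilterSpec-class].
#' @return filtered numeric vector, same length as the input.
#' @examples
#' all.equal(lowpassFilter(rep(2, 60), filterSpec()), rep(2, 60))
#' @export
lowpassFilter <- function(samples, spec = filterSpec()) {
  validObject(spec)
  padlen <- 3L * (2L * spec@order + 1L)
  n <- length(samples)
  if (n <= padlen)
    stop("input of length ", n, " is too short for zero-phase filtering; ",
         "need at least ", padlen + 1L, " samples")
  ba <- signal::butter(spec@order, spec@cutoff_hz / (spec@fs / 2), "low")
  b <- ba$b
  a <- ba$a
  zi <- lfilterZi(b, a)
  ext <- c(2 * samples[1] - samples[(padlen + 1L):2L],
           samples,
           2 * samples[n] - samples[(n - 1L):(n - padlen)])
  y <- iirFilter(b, a, ext, zi * ext[1])
  y <- rev(iirFilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Min-max normalization to [0, 1]
#'
#' Affine map sending the segment minimum to 0 and maximum to 1. A constant
#' segment carries no shape information and maps to all zeros.
#'
#' @param samples non-empty numeric vector.
#' @return numeric vector in [0, 1], same length.
#' @examples
#' minmaxNormalize(c(2, 4, 6))  # 0.0 0.5 1.0
#' @export
minmaxNormalize <- function(samples) {
  if (!length(samples)) stop("cannot normalize an empty segment")
  r <- range(samples)
  if (r[1] == r[2]) return(rep(0, length(samples)))
  (samples - r[1]) / (r[2] - r[1])
}

#' Time- and frequency-domain features of one segment
#'
#' Computes the 10 per-segment features in canonical order: mean,
#' (population) standard deviation, min, max, peak-to-peak, RMS, skewness
#' (biased g1), excess kurtosis (biased g2), dominant frequency and
#' low-frequency energy. Spectral features use the one-sided DFT magnitude
#' with a rectangular window; the dominant frequency is the non-DC bin with
#' the largest magnitude (ties go to the lower frequency) and the
#' low-frequency energy is the fraction of non-DC spectral energy at or
#' below `low_band_hz`.
#'
#' @param samples numeric vector (a normalized segment), length >= 4.
#' @param fs sampling frequency in Hz.
#' @param low_band_hz upper edge of the low-frequency band (default 10 Hz).
#' @param unbiased use sample (n-1) standard deviation and adjusted
#'   skewness/kurtosis instead of the biased population conventions.
#' @return named numeric vector of the 10 features.
#' @examples
#' extractSegmentFeatures(minmaxNormalize(sin(1:60)), fs = 256)
#' @export
extractSegmentFeatures <- function(samples, fs, low_band_hz = 10,
                                   unbiased = FALSE) {
  n <- length(samples)
  if (n < 4L) stop("segment too short for feature extraction (need >= 4)")
  m <- mean(samples)
  dev <- samples - m
  if (unbiased) {
    s <- sd(samples)
    g1 <- if (s > 0) (n^2 / ((n - 1) * (n - 2))) * mean(dev^3) / s^3 else 0
    g2 <- if (s > 0) {
      ((n + 1) * n / ((n - 1) * (n - 2) * (n - 3))) * sum(dev^4) / s^4 -
        3 * (n - 1)^2 / ((n - 2) * (n - 3))
    } else 0
  } else {
    s <- sqrt(mean(dev^2))
    g1 <- if (s > 0) mean(dev^3) / s^3 else 0
    g2 <- if (s > 0) mean(dev^4) / s^4 - 3 else 0
  }
  spec <- fft(samples)
  side <- 2:(n %/% 2 + 1L)              # non-DC one-sided bins
  freqs <- (side - 1) * fs / n
  mag <- Mod(spec[side])
  energy <- mag^2
  tot <- sum(energy)
  c(mean = m,
    std = s,
    min = min(samples),
    max = max(samples),
    peak_to_peak = max(samples) - min(samples),
    rms = sqrt(mean(samples^2)),
    skewness = g1,
    kurtosis = g2,
    dominant_freq = freqs[which.max(mag)],
    low_freq_energy = if (tot > 0) sum(energy[freqs <= low_band_hz]) / tot else 0)
}

#' Full preprocessing of one magnitude trace
#'
#' Segment -> zero-phase low-pass filter -> per-segment min-max
#' normalization -> feature extraction, concatenated in segment order into a
#' 30-dimensional feature vector. With `filter_whole = TRUE` the low-pass
#' filter is instead applied to the whole trace before segmentation (less
#' edge influence, at the cost of mixing information across segment
#' boundaries).
#'
#' @param samples numeric trace (length divisible by `n_segments`).
#' @param spec a [FilterSpec-class]; its `fs` is the trace sampling rate.
#' @param n_segments number of equal windows (default 3).
#' @param low_band_hz low-frequency band edge passed to
#'   [extractSegmentFeatures()].
#' @param filter_whole filter before segmenting instead of per segment.
#' @param unbiased see [extractSegmentFeatures()].
#' @return named numeric vector of length `10 * n_segments`
#'   (see [featureNames()]).
#' @examples
#' length(featurizeTrace(9.8 + rnorm(180)))  # 30
#' @export
featurizeTrace <- function(samples, spec = filterSpec(), n_segments = 3L,
                           low_band_hz = 10, filter_whole = FALSE,
                           unbiased = FALSE) {
  if (!all(is.finite(samples))) stop("trace contains non-finite samples")
  if (filter_whole) samples <- lowpassFilter(samples, spec)
  segs <- segmentTrace(samples, n_segments)
  out <- unlist(lapply(segs, function(seg) {
    if (!filter_whole) seg <- lowpassFilter(seg, spec)
    extractSegmentFeatures(minmaxNormalize(seg), fs = spec@fs,
                           low_band_hz = low_band_hz, unbiased = unbiased)
  }))
  names(out) <- featureNames(n_segments)
  out
}

#' Featurize every trace of a TraceSet
#'
#' @param traces a [TraceSet-class].
#' @param spec,n_segments,low_band_hz,filter_whole,unbiased
#'   see [featurizeTrace()]; the filter's `fs` is taken from the traces.
#' @return a [FeatureSet-class] with one 30-dimensional column per trace.
#' @examples
#' fs <- featurize(generateDataset(syntheticSpec(n_users = 1,
#'                                               instances_per_user = 4)))
#' dim(fs)  # 30 x 4
#' @export
featurize <- function(traces, spec = NULL, n_segments = 3L, low_band_hz = 10,
                      filter_whole = FALSE, unbiased = FALSE) {
  stopifnot(is(traces, "TraceSet"))
  if (is.null(spec)) spec <- filterSpec(fs = metadata(traces)$fs)
  m <- assay(traces, "magnitude")
  vals <- vapply(seq_len(ncol(m)), function(j) {
    featurizeTrace(m[, j], spec = spec, n_segments = n_segments,
                   low_band_hz = low_band_hz, filter_whole = filter_whole,
                   unbiased = unbiased)
  }, numeric(10L * n_segments))
  featureSetFromMatrix(vals, colData(traces), filter = spec,
                       low_band_hz = low_band_hz)
}
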