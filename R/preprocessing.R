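# --- Butterworth low-pass design (bilinear transform) --------------------
#
# No signal-processing package ships with the supported stack, so the design
# is done from first principles: analog Butterworth prototype poles, cutoff
# prewarping, bilinear transform, zeros at z = -1, unity DC gain.

# Polynomial coefficients (descending powers) from complex roots.
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0) - c(0, rt * p)
  p
}

#' Design a digital Butterworth low-pass filter
#'
#' @param order filter order (>= 1).
#' @param cutoff cutoff as a fraction of the Nyquist frequency, in (0, 1).
#' @return list with numerator `b` and denominator `a` coefficients
#'   (direct form, `a[1] == 1`).
#' @export
butter_lowpass <- function(order = 2, cutoff) {
  if (!(cutoff > 0 && cutoff < 1))
    stopf("parameter error: cutoff must lie in (0, 1), got %g", cutoff)
  if (order < 1) stopf("parameter error: order must be >= 1")
  k <- seq_len(order)
  # left-half-plane prototype poles, prewarped cutoff
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) * tan(pi * cutoff / 2)
  zp <- (1 + p) / (1 - p)                 # bilinear transform
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)                # H(1) = 1
  list(b = b, a = a / a[1])
}

# Steady-state initial filter state for a unit-step input (direct form II
# transposed), so a constant input produces a constant output from sample one.
lfilter_zi <- function(b, a) {
  m <- length(a) - 1
  Ac <- matrix(0, m, m)
  Ac[1, ] <- -a[-1] / a[1]
  if (m > 1) Ac[cbind(2:m, 1:(m - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - t(Ac), B)
}

# Causal IIR filter via stats::filter, with initial state zi * x[1] (the
# scipy lfilter(..., zi = zi * x[0]) convention): the zero-state response is
# computed vectorized, then the homogeneous transient implied by the initial
# state is added through a second recursive pass on an impulse sequence.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- length(x)
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb + n - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
    if (!is.null(zi)) {
      e <- numeric(n)
      m <- min(length(zi), n)
      e[seq_len(m)] <- zi[seq_len(m)] * x[1]
      v <- v + as.numeric(stats::filter(e, -a[-1], method = "recursive"))
    }
  }
  v
}

#' Analytic magnitude response of the digital Butterworth low-pass
#'
#' Closed form in terms of the prewarped design: |H| at normalized frequency
#' `w` (fraction of Nyquist) is `1/sqrt(1 + (tan(pi w/2)/tan(pi wc/2))^(2 n))`.
#' Useful as an independent oracle for the filter implementation.
#'
#' @param w normalized frequency (fraction of Nyquist).
#' @param cutoff design cutoff (fraction of Nyquist).
#' @param order filter order.
#' @return `|H(w)|` for a single (causal) pass.
#' @export
butter_gain <- function(w, cutoff, order = 2) {
  1 / sqrt(1 + (tan(pi * w / 2) / tan(pi * cutoff / 2))^(2 * order))
}

#' Zero-phase Butterworth denoising
#'
#' Low-pass filters a sequence forward and backward (zero-phase, so step and
#' heading timing are not lagged), with odd reflection padding at both ends to
#' suppress edge transients. The effective amplitude response is the squared
#' single-pass Butterworth magnitude.
#'
#' @param x numeric sequence (length >= 3 * order).
#' @param order filter order; the denoiser is second-order by default.
#' @param cutoff cutoff frequency. With `cutoff_units = "normalized"` it is a
#'   fraction of Nyquist in (0, 1) (default 0.001); with `"hz"` it is in Hz
#'   and `fs` must be supplied.
#' @param cutoff_units `"normalized"` or `"hz"`.
#' @param fs sampling rate in Hz, required when `cutoff_units = "hz"`.
#' @return Filtered sequence, same length as `x`.
#' @export
#' @examples
#' butterworth_denoise(rep(2, 50), cutoff = 0.1)  # DC passes untouched
butterworth_denoise <- function(x, order = 2, cutoff = 0.001,
                                cutoff_units = c("normalized", "hz"), fs = NULL) {
  cutoff_units <- match.arg(cutoff_units)
  if (cutoff_units == "hz") {
    if (is.null(fs)) stopf("parameter error: fs required for cutoff in Hz")
    cutoff <- cutoff / (fs / 2)
  }
  if (!(cutoff > 0 && cutoff < 1))
    stopf("parameter error: cutoff must lie in (0, 1), got %g", cutoff)
  n <- length(x)
  if (n < 3 * order) stopf("input too short: need at least %d samples", 3 * order)
  co <- butter_lowpass(order, cutoff)
  zi <- lfilter_zi(co$b, co$a)
  pad <- min(3 * max(length(co$a), length(co$b)), n - 1)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter(co$b, co$a, ext, zi = zi)
  y <- rev(iir_filter(co$b, co$a, rev(y), zi = zi))
  y[(pad + 1):(pad + n)]
}

# --- Hamming windowing and stacking --------------------------------------

#' Hamming window weight
#'
#' `w(n) = 0.54 - 0.46 cos(2 pi n / (N - 1))` for 0-based index `n` in a
#' window of length `N`; 0.08 at the endpoints, 1 at the midpoint of an
#' odd-length window, symmetric.
#'
#' @param n 0-based index (vectorized), `0 <= n < N`.
#' @param N window length, `>= 2`.
#' @return Window weight(s) in `[0.08, 1]`.
#' @export
hamming_weight <- function(n, N) {
  if (N < 2) stopf("parameter error: N must be >= 2")
  if (any(n < 0 | n >= N)) stopf("index error: n out of [0, N)")
  0.54 - 0.46 * cos(2 * pi * n / (N - 1))
}

#' Cut a recording into fixed-length windows
#'
#' Cuts `floor(duration / window_s)` non-overlapping windows from an aligned
#' recording. Each window carries the raw samples per channel plus
#' Hamming-weighted copies of the inertial channels (used by spectral
#' features; time-domain step/heading extraction consumes the raw samples so
#' tapering cannot distort peak amplitudes).
#'
#' @param rec an aligned [sensor_recording] (see [align_and_resample()]).
#' @param window_s window length in seconds (default 5).
#' @return List of `"sensor_window"` objects (empty, with a warning, when the
#'   recording is shorter than one window).
#' @export
segment_windows <- function(rec, window_s = 5) {
  if (is.na(rec$fs)) stopf("recording must be aligned before windowing")
  fs <- rec$fs
  N <- round(window_s * fs)
  imu <- intersect(names(rec$channels), c("acc", "gyr", "mag"))
  n_imu <- nrow(rec$channels[[imu[1]]]$data)
  n_win <- n_imu %/% N
  if (n_win < 1) {
    warnf("recording shorter than one %g-s window; no windows produced", window_s)
    return(list())
  }
  w <- hamming_weight(0:(N - 1), N)
  lapply(seq_len(n_win), function(k) {
    idx <- ((k - 1) * N + 1):(k * N)
    t0 <- (k - 1) * window_s
    samples <- list(); weighted <- list()
    for (nm in imu) {
      m <- rec$channels[[nm]]$data[idx, , drop = FALSE]
      samples[[nm]] <- m
      weighted[[nm]] <- m * w
    }
    for (nm in setdiff(names(rec$channels), imu)) {
      ch <- rec$channels[[nm]]
      keep <- ch$timestamps >= t0 & ch$timestamps < t0 + window_s
      samples[[nm]] <- ch$data[keep, , drop = FALSE]
    }
    structure(list(start_s = t0, fs = fs, window_s = window_s, samples = samples,
                   weighted = weighted, weights = w, weights_applied = TRUE,
                   rates = lapply(rec$channels, function(ch) ch$rate_hz)),
              class = "sensor_window")
  })
}

#' Stack consecutive windows
#'
#' Slides a stack of `size` time-contiguous windows along the window list at
#' the given stride; each stack is the unit of feature extraction and carries
#' the parent recording's labels.
#'
#' @param windows list of windows from one recording, time-ordered.
#' @param size windows per stack (default 3).
#' @param stride stride between stack starts, in windows (default 1).
#' @param activity_label,location_label labels inherited by every stack.
#' @return List of `"window_stack"` objects (empty, with a warning, when
#'   fewer than `size` windows are supplied).
#' @export
stack_windows <- function(windows, size = 3, stride = 1,
                          activity_label = NA_character_,
                          location_label = NA_character_) {
  n <- length(windows)
  if (n < size) {
    warnf("fewer than %d windows; no stacks produced", size)
    return(list())
  }
  starts <- seq(1, n - size + 1, by = stride)
  lapply(starts, function(s) {
    structure(list(windows = windows[s:(s + size - 1)],
                   activity_label = activity_label,
                   location_label = location_label),
              class = "window_stack")
  })
}

#' Denoise every channel of a recording in place
#'
#' Applies [butterworth_denoise()] column-wise to each channel.
#'
#' @inheritParams butterworth_denoise
#' @param rec a [sensor_recording].
#' @param channels channels to filter (default: all but GPS).
#' @return The filtered recording.
#' @export
denoise_recording <- function(rec, order = 2, cutoff = 0.001,
                              cutoff_units = "normalized",
                              channels = setdiff(names(rec$channels), "gps")) {
  for (nm in intersect(channels, names(rec$channels))) {
    ch <- rec$channels[[nm]]
    if (nrow(ch$data) < 3 * order) next
    rec$channels[[nm]]$data <- apply(ch$data, 2, butterworth_denoise,
                                     order = order, cutoff = cutoff,
                                     cutoff_units = cutoff_units, fs = ch$rate_hz)
  }
  rec
}
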