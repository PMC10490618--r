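# --- delay embedding helpers ---------------------------------------------

# Time-delay embedding: rows are (x_i, x_{i+tau}, ..., x_{i+(m-1) tau}).
delay_embed <- function(x, m, tau) {
  n <- length(x) - (m - 1) * tau
  if (n < 2) stopf("length error: series too short to embed (m=%d, tau=%d)", m, tau)
  idx <- outer(seq_len(n), (0:(m - 1)) * tau, `+`)
  matrix(x[idx], nrow = n)
}

# Delay choice: first zero crossing of the autocorrelation, capped at 1/20 of
# the series length so high-order embeddings of slow signals stay populated
# (fallback 1).
acf_zero_delay <- function(x, max_lag = min(length(x) %/% 4, 100)) {
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  z <- which(ac <= 0)
  d <- if (length(z)) z[1] else 1L
  max(1L, min(d, length(x) %/% 20))
}

# Full pairwise Euclidean distance matrix for an embedding (n kept modest by
# the 5-s window sizes; the chaos oracles use up to ~2000 points). Squared
# distances via the Gram identity, clipped at 0 before the square root.
embed_dist <- function(Y) {
  rn <- rowSums(Y^2)
  D2 <- -2 * tcrossprod(Y)
  D2 <- D2 + rn            # adds rn down columns
  D2 <- t(D2) + rn
  D2[D2 < 0] <- 0
  sqrt(D2)
}

# set D[i,j] <- Inf for |i - j| <= w (temporal exclusion band)
ban_band <- function(D, w) {
  n <- nrow(D)
  for (k in 0:min(w, n - 1)) {
    i <- seq_len(n - k)
    D[cbind(i, i + k)] <- Inf
    D[cbind(i + k, i)] <- Inf
  }
  D
}

# --- maximum Lyapunov exponent (Rosenstein) ------------------------------

#' Maximum Lyapunov exponent of a scalar series
#'
#' Rosenstein's small-data estimator of the dominant Lyapunov exponent: the
#' series is delay-embedded, each point is paired with its nearest neighbour
#' outside a temporal exclusion window, the mean log-divergence curve
#' `y(k) = <log ||X_{i+k} - X_{j+k}||>` is tracked, and the exponent is the
#' least-squares slope of the initial (pre-saturation) region, in units of
#' 1/sample.
#'
#' @param x numeric series, length >= 100.
#' @param emb_dim embedding dimension; `NULL` (default) picks it with
#'   [embedding_dimension()].
#' @param delay embedding delay in samples; `NULL` picks the first zero
#'   crossing of the autocorrelation.
#' @param max_steps divergence horizon in samples.
#' @param min_tsep temporal exclusion window for neighbour search.
#' @return Estimated exponent (per sample); 0 with attribute
#'   `degenerate = TRUE` for a constant input.
#' @export
#' @examples
#' x <- numeric(500); x[1] <- 0.3
#' for (i in 2:500) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
#' max_lyapunov_exponent(x, emb_dim = 2, delay = 1)  # about log(2)
max_lyapunov_exponent <- function(x, emb_dim = NULL, delay = NULL,
                                  max_steps = 30, min_tsep = NULL) {
  if (length(x) < 100) stopf("length error: need >= 100 samples, got %d", length(x))
  if (stats::var(x) == 0) return(structure(0, degenerate = TRUE))
  if (is.null(delay)) delay <- acf_zero_delay(x)
  if (is.null(emb_dim)) emb_dim <- embedding_dimension(x, delay = delay)
  Y <- delay_embed(x, emb_dim, delay)
  n <- nrow(Y)
  min_tsep <- min_tsep %||% max(10L, delay)
  D <- ban_band(embed_dist(Y), min_tsep)
  D[D == 0] <- Inf            # exact duplicates (periodic sampling) are no pairs
  nb <- max.col(-D, ties.method = "first")
  max_steps <- min(max_steps, n - 1)
  # mean log separation after k steps over pairs still inside the series
  ycurve <- vapply(0:max_steps, function(k) {
    i <- seq_len(n - k)
    j <- nb[i]
    ok <- j + k <= n & is.finite(D[cbind(i, j)])
    if (!any(ok)) return(NA_real_)
    d <- sqrt(rowSums((Y[i[ok] + k, , drop = FALSE] -
                         Y[j[ok] + k, , drop = FALSE])^2))
    mean(log(pmax(d, 1e-12)))
  }, 0)
  ks <- 0:max_steps
  ok <- !is.na(ycurve)
  ycurve <- ycurve[ok]; ks <- ks[ok]
  if (length(ycurve) < 4) return(structure(0, degenerate = TRUE))
  # fit only the pre-saturation region: stop where the curve comes within
  # 0.25 nats of its tail plateau (at least 4 points are always used)
  y_sat <- mean(utils::tail(ycurve, max(2, length(ycurve) %/% 4)))
  i_end <- which(ycurve > y_sat - 0.25)[1]
  if (is.na(i_end)) i_end <- length(ycurve)
  i_end <- max(i_end, 4L)
  fit <- stats::lm.fit(cbind(1, ks[1:i_end]), ycurve[1:i_end])
  unname(fit$coefficients[2])
}

# --- Higuchi fractal dimension -------------------------------------------

#' Higuchi fractal dimension of a scalar series
#'
#' Estimates the exponent `D` of the scaling law between curve length and
#' scale: mean curve length `L(k)` is computed for `k = 1..k_max` over the
#' `k` decimated sub-series, and `D` is the slope of `log L(k)` against
#' `log(1/k)`. A smooth curve gives ~1, Gaussian white noise ~2.
#'
#' @param x numeric series, length >= 10 * k_max.
#' @param k_max largest decimation scale (default 10).
#' @return Fractal dimension estimate in `[1, 2]` territory; 1 with
#'   attribute `degenerate = TRUE` for a constant input.
#' @export
fractal_dimension <- function(x, k_max = 10) {
  n <- length(x)
  if (n < 10 * k_max) stopf("length error: need >= %d samples, got %d", 10 * k_max, n)
  if (stats::var(x) == 0) return(structure(1, degenerate = TRUE))
  Lk <- vapply(seq_len(k_max), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      ni <- (n - m) %/% k
      if (ni < 1) return(NA_real_)
      d <- abs(diff(x[seq(m, m + ni * k, by = k)]))
      (sum(d) * (n - 1) / (ni * k)) / k
    }, 0)
    mean(Lm, na.rm = TRUE)
  }, 0)
  ks <- seq_len(k_max)
  fit <- stats::lm.fit(cbind(1, log(1 / ks)), log(Lk))
  unname(fit$coefficients[2])
}

# --- false nearest neighbours embedding dimension ------------------------

#' Embedding dimension by false nearest neighbours
#'
#' Kennel's false-nearest-neighbour criterion: at each candidate dimension
#' `d`, every embedded point's nearest neighbour is re-examined in dimension
#' `d + 1`; a neighbour is false when the extra coordinate either inflates
#' the distance by more than `rtol` relative or moves the pair beyond
#' `atol` standard deviations. The embedding dimension is the smallest `d`
#' at which the false fraction drops below 1% (or `max_dim` if it never does,
#' as for stochastic data).
#'
#' @param x numeric series, length >= 100.
#' @param max_dim largest dimension tried (default 10).
#' @param delay embedding delay; `NULL` picks the autocorrelation zero
#'   crossing.
#' @param rtol relative distance-inflation threshold (default 15).
#' @param atol absolute threshold in units of the series SD (default 2).
#' @return Integer embedding dimension; 1 with attribute
#'   `degenerate = TRUE` for a constant input.
#' @export
embedding_dimension <- function(x, max_dim = 10, delay = NULL, rtol = 15, atol = 2) {
  if (length(x) < 100) stopf("length error: need >= 100 samples, got %d", length(x))
  if (stats::var(x) == 0) return(structure(1L, degenerate = TRUE))
  if (is.null(delay)) delay <- acf_zero_delay(x)
  sdx <- stats::sd(x)
  for (d in seq_len(max_dim)) {
    if (length(x) - d * delay < 10) return(as.integer(max_dim))
    Y <- delay_embed(x, d, delay)
    n_use <- length(x) - d * delay          # points whose (d+1)-th coord exists
    Y <- Y[seq_len(n_use), , drop = FALSE]
    D <- ban_band(embed_dist(Y), delay)
    nb <- max.col(-D, ties.method = "first")
    Rd <- D[cbind(seq_len(n_use), nb)]
    extra <- abs(x[seq_len(n_use) + d * delay] - x[nb + d * delay])
    ok <- is.finite(Rd)
    if (!any(ok)) return(as.integer(max_dim))   # no usable pairs: no unfolding
    # pairs closer than numerical resolution are true neighbours by fiat
    thr <- 1e-9 * sdx
    false_nn <- (Rd[ok] > thr & extra[ok] / pmax(Rd[ok], thr) > rtol) |
      (sqrt(Rd[ok]^2 + extra[ok]^2) / sdx > atol)
    if (mean(false_nn) < 0.01) return(as.integer(d))
  }
  as.integer(max_dim)
}

# --- Mel-frequency cepstral coefficients ---------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank (n_filters x n_bins) over [0, fs/2].
mel_filterbank <- function(n_filters, n_fft, fs) {
  n_bins <- n_fft %/% 2 + 1
  freqs <- (0:(n_bins - 1)) * fs / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fs / 2), length.out = n_filters + 2))
  fb <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; ce <- edges[i + 1]; hi <- edges[i + 2]
    up <- (freqs - lo) / max(ce - lo, 1e-12)
    down <- (hi - freqs) / max(hi - ce, 1e-12)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct2_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1); m <- 0:(n_in - 1)
  C <- sqrt(2 / n_in) * cos(pi * outer(k, 2 * m + 1) / (2 * n_in))
  C[1, ] <- sqrt(1 / n_in)
  C
}

#' Mel-frequency cepstral coefficients
#'
#' Frames the signal, applies a Hamming taper per frame, takes the magnitude
#' spectrum, pools it through a triangular Mel filterbank, logs the energies
#' (floored at `eps`, so an all-zero frame yields finite coefficients), and
#' applies an orthonormal DCT-II. The per-window feature used by the pipeline
#' is the mean coefficient vector over frames.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param n_coeffs number of cepstral coefficients kept (default 13).
#' @param n_filters number of Mel filters (default 26).
#' @param frame_s,hop_s frame length and hop in seconds (defaults 25 ms /
#'   10 ms, the standard audio choice; the activity bank uses longer frames
#'   suited to 40 Hz inertial data).
#' @param eps log floor.
#' @return List with `coefficients` (frames x n_coeffs matrix) and `mean`
#'   (length-`n_coeffs` frame mean).
#' @export
mfcc <- function(x, fs, n_coeffs = 13, n_filters = 26, frame_s = 0.025,
                 hop_s = 0.010, eps = 1e-12) {
  L <- max(2L, round(frame_s * fs))
  hop <- max(1L, round(hop_s * fs))
  if (length(x) < L) stopf("length error: signal shorter than one frame")
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  n_fft <- max(256L, 2^ceiling(log2(L)))
  fb <- mel_filterbank(n_filters, n_fft, fs)
  C <- dct2_matrix(n_coeffs, n_filters)
  w <- hamming_weight(0:(L - 1), L)
  n_bins <- n_fft %/% 2 + 1
  frames <- vapply(starts, function(s) x[s:(s + L - 1)] * w, numeric(L))
  spec <- stats::mvfft(rbind(frames, matrix(0, n_fft - L, length(starts))))
  mag <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  energies <- fb %*% mag                     # n_filters x n_frames
  coef <- C %*% log(pmax(energies, eps))     # n_coeffs x n_frames
  list(coefficients = t(coef), mean = rowMeans(coef))
}

# --- moments -------------------------------------------------------------

#' Skewness (standardized third moment)
#'
#' Population form, `m3 / m2^(3/2)`; returns 0 with a `degenerate` attribute
#' for constant input.
#'
#' @param x numeric vector, length >= 3.
#' @return Skewness.
#' @export
skewness <- function(x) {
  if (length(x) < 3) stopf("length error: need >= 3 samples")
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 == 0) return(structure(0, degenerate = TRUE))
  mean((x - m)^3) / m2^1.5
}

#' Excess kurtosis (fourth standardized moment minus 3)
#'
#' Population form; a Gaussian gives 0. Returns 0 with a `degenerate`
#' attribute for constant input.
#'
#' @param x numeric vector, length >= 3.
#' @return Excess kurtosis.
#' @export
kurtosis <- function(x) {
  if (length(x) < 3) stopf("length error: need >= 3 samples")
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 == 0) return(structure(0, degenerate = TRUE))
  mean((x - m)^4) / m2^2 - 3
}

# --- activity feature bank ------------------------------------------------

#' Default configuration of the activity feature bank
#'
#' @return Named list of tunables: chaos-estimator settings and the
#'   MFCC framing used on 40 Hz inertial channels (2 s frames, 1 s hop,
#'   16 mel filters, 13 coefficients).
#' @export
har_feature_config <- function() {
  list(emb_max_dim = 10, fnn_rtol = 15, fnn_atol = 2, fd_kmax = 10,
       mle_max_steps = 30,
       mfcc = list(n_coeffs = 13, n_filters = 16, frame_s = 2.0, hop_s = 1.0),
       per_window = TRUE)
}

# Feature slots per axis signal: values + layout rows.
axis_features <- function(x, fs, cfg, weighted = NULL) {
  n <- length(x)
  constant <- stats::var(x) == 0
  if (constant) {
    mle <- 0; fd <- 1; ed <- 1L
  } else {
    delay <- acf_zero_delay(x)
    ed <- embedding_dimension(x, max_dim = cfg$emb_max_dim, delay = delay,
                              rtol = cfg$fnn_rtol, atol = cfg$fnn_atol)
    mle <- max_lyapunov_exponent(x, emb_dim = as.integer(ed), delay = delay,
                                 max_steps = cfg$mle_max_steps)
    fd <- fractal_dimension(x, k_max = cfg$fd_kmax)
  }
  mf <- mfcc(weighted %||% x, fs, n_coeffs = cfg$mfcc$n_coeffs,
             n_filters = cfg$mfcc$n_filters, frame_s = cfg$mfcc$frame_s,
             hop_s = cfg$mfcc$hop_s)
  vals <- c(as.numeric(mle), mf$mean, as.numeric(fd), as.numeric(ed),
            as.numeric(skewness(x)), as.numeric(kurtosis(x)))
  names(vals) <- NULL
  feats <- c("mle", paste0("mfcc", 0:(cfg$mfcc$n_coeffs - 1)), "fd", "ed",
             "skewness", "kurtosis")
  list(values = vals, features = feats)
}

#' Extract the activity (HAR) feature bank from a window stack
#'
#' For every window in the stack, every inertial channel (acc, gyr, mag) and
#' every axis, computes the six activity descriptors — maximum Lyapunov
#' exponent, 13 MFCC frame-means, Higuchi fractal dimension,
#' false-nearest-neighbour embedding dimension, skewness and excess
#' kurtosis — and concatenates them per the layout manifest
#' (3 windows x 3 channels x 3 axes x 18 slots = 486 by default). MFCCs are
#' computed on the Hamming-weighted copies; the time-domain descriptors use
#' the raw samples. Degenerate (constant) inputs map to finite defaults; no
#' NaN/Inf ever leaves this function.
#'
#' @param stack a `"window_stack"` from [stack_windows()].
#' @param cfg configuration, see [har_feature_config()].
#' @return An object of class `"feature_vector"`: `values` plus a `layout`
#'   data frame naming each slot (feature, channel, axis, window).
#' @export
extract_har_features <- function(stack, cfg = har_feature_config()) {
  need <- c("acc", "gyr", "mag")
  have <- names(stack$windows[[1]]$samples)
  if (!all(need %in% have))
    stopf("precondition error: inertial channel(s) missing: %s",
          paste(setdiff(need, have), collapse = ", "))
  values <- numeric(0)
  layout <- list()
  for (wi in seq_along(stack$windows)) {
    win <- stack$windows[[wi]]
    for (ch in need) {
      m <- win$samples[[ch]]
      mw <- win$weighted[[ch]]
      for (ax in seq_len(ncol(m))) {
        af <- axis_features(m[, ax], win$fs, cfg, weighted = mw[, ax])
        values <- c(values, af$values)
        layout[[length(layout) + 1L]] <- data.frame(
          feature = af$features, channel = ch,
          axis = c("x", "y", "z")[ax], window = wi)
      }
    }
  }
  layout <- do.call(rbind, layout)
  stopifnot(all(is.finite(values)), nrow(layout) == length(values))
  structure(list(values = values, layout = layout, bank = "har"),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector [%s]> %d slots\n", x$bank, length(x$values)))
  invisible(x)
}
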