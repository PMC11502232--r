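# LFP band filtering, envelope event detection, nonrhythmic epochs,
# multitaper PSD and wide-band downsampling.

.lh_cache <- new.env(parent = emptyenv())

# Zero-phase FIR filtering: linear-phase fir1 design, FFT convolution,
# group-delay compensation. Chosen over IIR + filtfilt because the
# screening bands reach down to 2 Hz at fs = 1250 Hz, where a Butterworth
# bandpass is numerically fragile.
.fir_apply <- function(x, h) {
  n <- length(x)
  m <- length(h)  # odd, linear phase, delay (m-1)/2
  full <- conv_open(x, h)
  d <- (m - 1L) %/% 2L
  full[(d + 1L):(d + n)]
}

.fir_bandpass <- function(x, fs, lo, hi) {
  taps <- ceiling(3.5 * fs / min(lo, hi - lo))
  taps <- min(taps, max(32L, floor(length(x) / 3) * 2L), 8192L)
  if (taps %% 2L == 1L) taps <- taps + 1L
  h <- signal::fir1(taps, c(lo, hi) / (fs / 2), type = "pass")
  .fir_apply(x, as.numeric(h))
}

.fir_lowpass <- function(x, fs, cutoff, taps) {
  if (taps %% 2L == 1L) taps <- taps + 1L
  h <- signal::fir1(taps, cutoff / (fs / 2), type = "low")
  .fir_apply(x, as.numeric(h))
}

#' Downsample a wide-band signal
#'
#' Anti-alias FIR low-pass at `0.4 * fs_out` followed by resampling to
#' `fs_out` (stride decimation for integer ratios, linear interpolation
#' otherwise).
#'
#' @param signal an [lfp_signal()] or numeric vector.
#' @param fs_in input rate (required when `signal` is a bare vector).
#' @param fs_out output rate, default 1250 Hz.
#' @return An [lfp_signal()] at `fs_out`.
#' @export
downsample_wideband <- function(signal, fs_in = NULL, fs_out = 1250) {
  if (inherits(signal, "lfp_signal")) {
    fs_in <- signal$fs_hz
    sid <- signal$session_id
    x <- signal$samples
  } else {
    if (is.null(fs_in)) stop("fs_in required")
    sid <- "s1"
    x <- as.numeric(signal)
  }
  if (fs_in < fs_out) stop("fs_in must be >= fs_out")
  if (fs_in == fs_out) return(lfp_signal(x, fs_out, sid))
  taps <- ceiling(3.5 * fs_in / (0.1 * fs_out))
  y <- .fir_lowpass(x, fs_in, 0.4 * fs_out, min(taps, 8192L))
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    out <- y[seq(1L, length(y), by = round(ratio))]
  } else {
    t_in <- (seq_along(y) - 1L) / fs_in
    n_out <- floor(length(y) / ratio)
    out <- approx(t_in, y, xout = (seq_len(n_out) - 1L) / fs_out)$y
  }
  lfp_signal(out, fs_out, sid)
}

#' Band-passed, rectified, smoothed amplitude envelope
#'
#' Zero-phase band-pass, absolute value, Gaussian smoothing (SD
#' `smooth_sd_ms`). Noise statistics (mean, SD) are taken over the whole
#' envelope.
#'
#' @param lfp an [lfp_signal()].
#' @param band_hz `c(lo, hi)` band in Hz, within `(0, fs/2)`.
#' @param smooth_sd_ms Gaussian smoothing SD in ms.
#' @return `list(envelope, mean, sd, fs_hz, band_hz)` of class
#'   `band_envelope`.
#' @export
band_envelope <- function(lfp, band_hz, smooth_sd_ms = 10) {
  fs <- lfp$fs_hz
  if (band_hz[1L] <= 0 || band_hz[2L] >= fs / 2 || band_hz[2L] <= band_hz[1L]) {
    stop("band must satisfy 0 < lo < hi < fs/2")
  }
  bp <- .fir_bandpass(lfp$samples, fs, band_hz[1L], band_hz[2L])
  env <- abs(bp)
  sd_n <- smooth_sd_ms / 1000 * fs
  half <- max(1L, ceiling(4 * sd_n))
  kern <- dnorm(seq(-half, half), sd = sd_n)
  kern <- kern / sum(kern)
  env <- .fir_apply(env, kern)
  mu <- mean(env); s <- sd(env)
  if (s == 0) stop("degenerate envelope statistics: zero variance signal")
  structure(list(envelope = env, mean = mu, sd = s, fs_hz = fs,
                 band_hz = band_hz),
            class = "band_envelope")
}

#' Detect supra-threshold envelope events
#'
#' Candidate events are maximal runs with the envelope above
#' `mean + detect_sd * SD` lasting at least `min_event_ms`; each candidate
#' is extended outward to where the envelope falls below
#' `mean + edge_sd * SD`, and overlapping extended events are merged.
#'
#' @param env a [band_envelope()] (its own noise statistics are used).
#' @param detect_sd detection threshold in SD above the mean (default 2).
#' @param edge_sd boundary threshold in SD (default 1).
#' @param min_event_ms minimum supra-threshold duration in ms (default 25).
#' @param label epoch label.
#' @param session_id session identifier.
#' @return An [epoch_set()].
#' @export
detect_events <- function(env, detect_sd = 2, edge_sd = 1, min_event_ms = 25,
                          label = "event", session_id = "s1") {
  stopifnot(inherits(env, "band_envelope"))
  e <- env$envelope
  fs <- env$fs_hz
  hi <- env$mean + detect_sd * env$sd
  lo <- env$mean + edge_sd * env$sd
  above <- e > hi
  if (!any(above)) {
    return(epoch_set(label, NULL, session_id,
                     params = list(detect_sd = detect_sd, edge_sd = edge_sd,
                                   min_event_ms = min_event_ms,
                                   band_hz = env$band_hz)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_n <- min_event_ms / 1000 * fs
  keep <- r$values & r$lengths >= min_n
  s_idx <- starts[keep]; e_idx <- ends[keep]
  # extend to the nearest samples below the edge threshold
  ib <- which(e < lo)
  if (length(ib) == 0L) {
    s_ext <- rep(1L, length(s_idx))
    e_ext <- rep(length(e), length(e_idx))
  } else {
    pos_l <- findInterval(s_idx - 1L, ib)
    s_ext <- ifelse(pos_l >= 1L, ib[pmax(pos_l, 1L)] + 1L, 1L)
    pos_r <- findInterval(e_idx, ib) + 1L
    e_ext <- ifelse(pos_r <= length(ib), ib[pmin(pos_r, length(ib))] - 1L,
                    length(e))
  }
  iv <- merge_intervals(cbind((s_ext - 1L) / fs, e_ext / fs))
  epoch_set(label, iv, session_id,
            params = list(detect_sd = detect_sd, edge_sd = edge_sd,
                          min_event_ms = min_event_ms, band_hz = env$band_hz))
}

#' Detect nonrhythmic epochs
#'
#' Times at which every screening band's envelope stays below its own
#' `mean + thresh_sd * SD`, kept when at least `min_epoch_ms` long.
#' Intervals overlapping `exclude` (e.g. detected oscillation events) are
#' removed: by definition epochs with detected oscillations are rhythmic.
#'
#' @param lfp an [lfp_signal()].
#' @param bands named list of screening bands in Hz (defaults: delta 2-4,
#'   theta 5-10, beta 15-30, gamma 30-120, fast 120-200).
#' @param thresh_sd threshold in SD (default 0.5).
#' @param min_epoch_ms minimum epoch duration (default 100 ms).
#' @param exclude optional [epoch_set()] or list of epoch sets to subtract.
#' @param smooth_sd_ms envelope smoothing SD (ms).
#' @return An [epoch_set()] labeled `nonrhythmic`.
#' @export
detect_nonrhythmic <- function(lfp, bands = list(delta = c(2, 4),
                                                 theta = c(5, 10),
                                                 beta = c(15, 30),
                                                 gamma = c(30, 120),
                                                 fast = c(120, 200)),
                               thresh_sd = 0.5, min_epoch_ms = 100,
                               exclude = NULL, smooth_sd_ms = 10) {
  fs <- lfp$fs_hz
  for (b in bands) if (b[2L] >= fs / 2) stop("band above Nyquist: ", b[2L], " Hz")
  mask <- rep(TRUE, length(lfp$samples))
  for (b in bands) {
    env <- band_envelope(lfp, b, smooth_sd_ms)
    mask <- mask & (env$envelope < env$mean + thresh_sd * env$sd)
  }
  iv <- mask_to_intervals(mask, fs)
  if (!is.null(exclude)) {
    if (inherits(exclude, "epoch_set")) exclude <- list(exclude)
    for (es in exclude) iv <- subtract_intervals(iv, es$intervals)
  }
  if (nrow(iv)) iv <- iv[iv[, 2L] - iv[, 1L] >= min_epoch_ms / 1000, , drop = FALSE]
  epoch_set("nonrhythmic", iv, lfp$session_id,
            params = list(thresh_sd = thresh_sd, min_epoch_ms = min_epoch_ms,
                          bands = bands))
}

# Discrete prolate spheroidal (Slepian) tapers via the standard symmetric
# tridiagonal eigenproblem; cached per (n, nw, k).
.dpss <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.lh_cache[[key]])) return(.lh_cache[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t[-1L]) * (n - t[-1L]) / 2
  M <- matrix(0, n, n)
  M[cbind(t + 1, t + 1)] <- diag_main
  M[cbind(2:n, 1:(n - 1))] <- diag_off
  M[cbind(1:(n - 1), 2:n)] <- diag_off
  e <- eigen(M, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  .lh_cache[[key]] <- V
  V
}

#' Multitaper power spectral density
#'
#' Slepian-tapered periodograms (time-bandwidth `nw`, `2 nw - 1` tapers)
#' averaged over tapers and half-overlapping sliding windows; one-sided
#' density per Hz, so the integral over frequency approximates the signal
#' variance.
#'
#' @param signal an [lfp_signal()] or numeric vector.
#' @param fs_hz sampling rate (needed for bare vectors).
#' @param nw time-bandwidth product (default 3).
#' @param window window length in samples (default 1024).
#' @param overlap fractional window overlap (default 0.5).
#' @return `list(freqs, power)` (Hz, units^2/Hz).
#' @export
multitaper_psd <- function(signal, fs_hz = NULL, nw = 3, window = 1024L,
                           overlap = 0.5) {
  if (inherits(signal, "lfp_signal")) {
    fs_hz <- signal$fs_hz
    x <- signal$samples
  } else {
    if (is.null(fs_hz)) stop("fs_hz required")
    x <- as.numeric(signal)
  }
  n <- length(x)
  if (n < window) stop("signal shorter than the window length")
  k <- 2 * nw - 1
  V <- .dpss(window, nw, k)
  step <- max(1L, round(window * (1 - overlap)))
  starts <- seq(1L, n - window + 1L, by = step)
  nf <- window %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + window - 1L)]
    seg <- seg - mean(seg)
    for (j in seq_len(k)) {
      X <- fft(seg * V[, j])[seq_len(nf)]
      acc <- acc + (Mod(X)^2) / fs_hz
    }
  }
  p <- acc / (length(starts) * k)
  p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]  # one-sided
  list(freqs = (seq_len(nf) - 1L) * fs_hz / window, power = p)
}
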