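#' Feature extraction configuration
#'
#' All knobs of the mixed-MFCC front end in one place. Defaults give the
#' canonical 16 kHz / 20 ms / 128-frame configuration whose output is a
#' 128 x 120 matrix (40 static cepstra, 40 first-order and 40 second-order
#' differentials).
#'
#' @param sample_rate Internal sampling rate in Hz.
#' @param n_frames Number of analysis frames every clip is standardized to.
#' @param frame_len Frame length in samples (20 ms at `sample_rate`).
#' @param hop Frame shift in samples; half the frame length (overlap
#'   segmentation).
#' @param alpha Pre-emphasis coefficient in `[0, 1]`.
#' @param window Window kind: `"hamming"` (default), `"hanning"` or
#'   `"rectangular"`.
#' @param n_fft DFT length (frames are zero-padded up to it).
#' @param n_mels Number of triangular Mel filters `M`.
#' @param n_cepstra Number of cepstral coefficients `L` kept per frame.
#' @param delta_k Half-window of the differential regression (so the
#'   denominator is `sum(i^2)` over `-k..k`).
#' @param f_min,f_max Filterbank edges in Hz.
#' @param log_floor Floor applied inside the log to keep silent frames finite.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(sample_rate = 16000L, n_frames = 128L,
                           frame_len = round(0.020 * sample_rate),
                           hop = frame_len %/% 2L,
                           alpha = 0.97, window = "hamming", n_fft = 512L,
                           n_mels = 40L, n_cepstra = 40L, delta_k = 2L,
                           f_min = 20, f_max = 8000, log_floor = 1e-10) {
  if (alpha < 0 || alpha > 1) stop("feature_config: alpha must be in [0, 1]")
  if (delta_k < 1) stop("feature_config: delta_k must be >= 1")
  if (f_max > sample_rate / 2) stop("feature_config: f_max above Nyquist")
  window <- match.arg(window, c("hamming", "hanning", "rectangular"))
  structure(list(sample_rate = as.integer(sample_rate),
                 n_frames = as.integer(n_frames),
                 frame_len = as.integer(frame_len), hop = as.integer(hop),
                 alpha = alpha, window = window, n_fft = as.integer(n_fft),
                 n_mels = as.integer(n_mels), n_cepstra = as.integer(n_cepstra),
                 delta_k = as.integer(delta_k), f_min = f_min, f_max = f_max,
                 log_floor = log_floor),
            class = "feature_config")
}

#' Save / load a feature configuration as JSON
#'
#' The JSON sidecar records every front-end parameter so that extracted
#' features can be reproduced exactly.
#'
#' @param config A [feature_config()].
#' @param path JSON file path.
#' @return `save_feature_config`: `path`, invisibly. `load_feature_config`:
#'   a [feature_config()].
#' @export
save_feature_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_feature_config
#' @export
load_feature_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(feature_config, vals)
}

#' Pre-emphasis filter
#'
#' First-order high-pass `y[n] = x[n] - alpha * x[n-1]` (with `y[1] = x[1]`),
#' boosting the high-frequency components that decay fastest in vocal signals.
#'
#' @param clip An [audio_clip()].
#' @param alpha Filter coefficient in `[0, 1]`; 0.97 by default.
#' @return An [audio_clip()] of the same length.
#' @export
pre_emphasis <- function(clip, alpha = 0.97) {
  stopifnot(inherits(clip, "audio_clip"))
  if (alpha < 0 || alpha > 1) stop("pre_emphasis: alpha must be in [0, 1]")
  x <- clip$samples
  y <- x - alpha * c(0, x[-length(x)])
  clip$samples <- y
  clip
}

#' Slice a clip into overlapping frames
#'
#' Frame `i` (1-based) holds samples `[(i-1)*hop + 1, (i-1)*hop + frame_len]`;
#' the number of frames is `floor((n - frame_len)/hop) + 1`.
#'
#' @param clip An [audio_clip()].
#' @param frame_len Frame length in samples.
#' @param hop Frame shift in samples.
#' @return An `n_frames x frame_len` numeric matrix.
#' @export
frame_signal <- function(clip, frame_len, hop) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (frame_len > length(x))
    stop("frame_signal: frame_len (", frame_len, ") exceeds clip length (",
         length(x), ")")
  if (hop < 1) stop("frame_signal: hop must be >= 1")
  n_frames <- (length(x) - frame_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(starts, seq_len(frame_len), `+`)
  matrix(x[idx], nrow = n_frames, ncol = frame_len)
}

#' Analysis windows
#'
#' Symmetric windows of length `n`: rectangular (all ones), Hanning
#' `0.5 * (1 - cos(2*pi*k/(n-1)))` and Hamming `0.54 - 0.46*cos(2*pi*k/(n-1))`
#' for `k = 0..n-1`.
#'
#' @param kind One of `"rectangular"`, `"hanning"`, `"hamming"`.
#' @param n Window length (>= 2).
#' @return Numeric vector of length `n` with values in `[0, 1]`.
#' @export
make_window <- function(kind, n) {
  if (n < 2) stop("make_window: n must be >= 2")
  kind <- match.arg(kind, c("rectangular", "hanning", "hamming"))
  k <- seq(0, n - 1)
  switch(kind,
         rectangular = rep(1, n),
         hanning = 0.5 * (1 - cos(2 * pi * k / (n - 1))),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)))
}

#' Apply a window to every frame
#'
#' @param frames An `n_frames x frame_len` matrix from [frame_signal()].
#' @param window Numeric vector of length `frame_len`.
#' @return The windowed frame matrix.
#' @export
apply_window <- function(frames, window) {
  if (ncol(frames) != length(window))
    stop("apply_window: window length ", length(window),
         " != frame length ", ncol(frames))
  frames * rep(window, each = nrow(frames))
}

#' One-sided power spectrum per frame
#'
#' Frames are zero-padded to `n_fft` and transformed; the power spectrum is
#' `P(k) = |X(k)|^2 / n_fft`, retained for the one-sided bins
#' `k = 0 .. n_fft/2` (real-input symmetry).
#'
#' @param frames An `n_frames x frame_len` matrix.
#' @param n_fft DFT length, at least `frame_len`.
#' @return An `n_frames x (n_fft/2 + 1)` non-negative matrix.
#' @export
power_spectrum <- function(frames, n_fft = 512L) {
  if (n_fft < ncol(frames))
    stop("power_spectrum: n_fft must be >= frame length")
  padded <- cbind(frames, matrix(0, nrow(frames), n_fft - ncol(frames)))
  X <- mvfft(t(padded))                      # n_fft x n_frames
  keep <- seq_len(n_fft %/% 2 + 1L)
  t(Mod(X[keep, , drop = FALSE])^2) / n_fft
}

#' Hz to Mel and back
#'
#' The Mel scale `Mel(f) = 2595 * log10(1 + f/700)` and its inverse.
#'
#' @param f Frequency in Hz (non-negative).
#' @param mel Frequency in Mel.
#' @return `hz_to_mel`: Mel value(s); `mel_to_hz`: Hz value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("hz_to_mel: negative frequency")
  2595 * log10(1 + f / 700)
}

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(mel) {
  if (any(mel < 0)) stop("mel_to_hz: negative Mel value")
  700 * (10^(mel / 2595) - 1)
}

#' Triangular Mel filterbank
#'
#' `n_mels + 2` boundary points are spaced equally on the Mel axis between
#' `f_min` and `f_max`, mapped back to Hz and snapped to the DFT bin grid.
#' Filter `m` rises linearly from boundary `m-1` to a peak of 1 at boundary
#' `m` and falls to zero at boundary `m+1`; each triangle starts at the peak
#' of its predecessor, so at every bin strictly between the first and last
#' centers the filter responses sum to exactly 1 (a partition of unity).
#'
#' @param n_mels Number of filters `M`.
#' @param n_fft DFT length the filters are laid over.
#' @param sample_rate Sampling rate in Hz.
#' @param f_min,f_max Filterbank edge frequencies in Hz
#'   (`f_min < f_max <= sample_rate/2`).
#' @return A list of class `mel_filterbank` with `weights`
#'   (`n_mels x (n_fft/2 + 1)`), `center_bins` (the `n_mels + 2` boundary
#'   bins, 0-based), `center_freqs` (Hz of those bins) and the construction
#'   parameters.
#' @export
mel_filterbank <- function(n_mels = 40L, n_fft = 512L, sample_rate = 16000L,
                           f_min = 20, f_max = 8000) {
  if (n_mels < 1) stop("mel_filterbank: n_mels must be >= 1")
  if (f_min >= f_max) stop("mel_filterbank: f_min must be < f_max")
  if (f_max > sample_rate / 2) stop("mel_filterbank: f_max above Nyquist")
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- sample_rate / n_fft
  mels <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mels + 2L)
  bounds <- round(mel_to_hz(mels) / bin_hz)          # 0-based bin of each boundary
  if (any(diff(bounds) < 1))
    stop("mel_filterbank: ", n_mels, " filters collide on the ", n_bins,
         "-bin grid; reduce n_mels or increase n_fft")
  k <- 0:(n_bins - 1L)
  weights <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- bounds[m]; ce <- bounds[m + 1L]; hi <- bounds[m + 2L]
    rise <- k >= lo & k <= ce
    fall <- k > ce & k <= hi
    weights[m, rise] <- (k[rise] - lo) / (ce - lo)
    weights[m, fall] <- (hi - k[fall]) / (hi - ce)
  }
  structure(list(weights = weights, center_bins = bounds,
                 center_freqs = bounds * bin_hz, n_mels = n_mels,
                 n_fft = n_fft, sample_rate = sample_rate,
                 f_min = f_min, f_max = f_max),
            class = "mel_filterbank")
}

#' Log Mel-filterbank energies
#'
#' `S(m) = ln(max(sum_k P(k) * H_m(k), floor))`; the floor keeps silent
#' frames finite.
#'
#' @param P Power spectrum matrix from [power_spectrum()].
#' @param bank A [mel_filterbank()] with matching bin count.
#' @param log_floor Lower bound on the filtered energy before the log.
#' @return An `n_frames x n_mels` matrix, finite everywhere.
#' @export
log_mel_energies <- function(P, bank, log_floor = 1e-10) {
  if (ncol(P) != ncol(bank$weights))
    stop("log_mel_energies: spectrum has ", ncol(P), " bins, filterbank has ",
         ncol(bank$weights))
  log(pmax(P %*% t(bank$weights), log_floor))
}

#' Cepstra by discrete cosine transform
#'
#' Orthonormal DCT-II along the Mel axis of each frame:
#' `C(n) = w(n) * sum_m S(m) * cos(pi * n * (m + 1/2) / M)` for
#' `n = 0..L-1`, with `w(0) = sqrt(1/M)` and `w(n>0) = sqrt(2/M)`.
#'
#' @param S Log Mel energy matrix (`n_frames x M`).
#' @param n_cepstra Number of coefficients `L` kept.
#' @return An `n_frames x n_cepstra` matrix.
#' @export
dct_cepstra <- function(S, n_cepstra = 40L) {
  if (n_cepstra < 1) stop("dct_cepstra: n_cepstra must be >= 1")
  M <- ncol(S)
  n <- 0:(n_cepstra - 1L)
  m <- 0:(M - 1L)
  D <- sqrt(2 / M) * cos(pi * outer(n, m + 0.5) / M)
  D[1, ] <- sqrt(1 / M)
  S %*% t(D)
}

#' Differential (delta) coefficients
#'
#' Windowed-regression slope over time for every cepstral track:
#' `D(t) = sum_{i=-k..k} i * C(t+i) / sum_{i=-k..k} i^2`, with edge frames
#' replicated beyond the matrix. Apply twice for the second-order
#' differential.
#'
#' @param C Cepstral matrix (`n_frames x L`).
#' @param k Regression half-window (default 2, denominator 10).
#' @return A matrix of the same shape.
#' @export
delta_coefficients <- function(C, k = 2L) {
  if (k < 1) stop("delta_coefficients: k must be >= 1")
  n <- nrow(C)
  padded <- C[c(rep(1L, k), seq_len(n), rep(n, k)), , drop = FALSE]
  D <- matrix(0, n, ncol(C))
  for (i in seq_len(k)) {
    D <- D + i * (padded[(k + i) + seq_len(n), , drop = FALSE] -
                  padded[(k - i) + seq_len(n), , drop = FALSE])
  }
  D / (2 * sum(seq_len(k)^2))
}

#' Stack static and differential cepstra into the mixed feature
#'
#' Column-wise concatenation `[C | delta | delta2]`; with the default
#' configuration the result is the network's 128 x 120 input.
#'
#' @param C,D,D2 Matrices of identical shape.
#' @return A `mixed_feature` matrix with `3 * ncol(C)` columns.
#' @export
stack_mixed <- function(C, D, D2) {
  if (!identical(dim(C), dim(D)) || !identical(dim(C), dim(D2)))
    stop("stack_mixed: shape mismatch: ", paste(dim(C), collapse = "x"), " vs ",
         paste(dim(D), collapse = "x"), " vs ", paste(dim(D2), collapse = "x"))
  out <- cbind(C, D, D2)
  class(out) <- c("mixed_feature", class(out))
  out
}

#' Extract the mixed MFCC feature from a clip
#'
#' The full front end: resample to the configured rate, standardize to the
#' configured frame count, pre-emphasize, frame, window, power spectrum, Mel
#' filterbank, log, DCT, first- and second-order differentials, stack. The
#' output shape is `n_frames x (3 * n_cepstra)` — 128 x 120 by default —
#' regardless of the input clip's duration or rate.
#'
#' @param clip An [audio_clip()].
#' @param config A [feature_config()].
#' @return A `mixed_feature` matrix with the configuration attached as
#'   attribute `config` and the clip label as attribute `label`.
#' @export
extract_mixed_mfcc <- function(clip, config = feature_config()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(config, "feature_config"))
  clip <- resample_clip(clip, config$sample_rate)
  clip <- standardize_length(clip, config$n_frames, config$frame_len, config$hop)
  clip <- pre_emphasis(clip, config$alpha)
  frames <- frame_signal(clip, config$frame_len, config$hop)
  frames <- apply_window(frames, make_window(config$window, config$frame_len))
  P <- power_spectrum(frames, config$n_fft)
  bank <- mel_filterbank(config$n_mels, config$n_fft, config$sample_rate,
                         config$f_min, config$f_max)
  S <- log_mel_energies(P, bank, config$log_floor)
  C <- dct_cepstra(S, config$n_cepstra)
  D <- delta_coefficients(C, config$delta_k)
  D2 <- delta_coefficients(D, config$delta_k)
  out <- stack_mixed(C, D, D2)
  attr(out, "config") <- config
  attr(out, "label") <- clip$label
  out
}

#' Extract features for a list of clips
#'
#' @param clips List of [audio_clip()] objects.
#' @param config A [feature_config()].
#' @return A list with `x`, an `n_frames x (3*n_cepstra) x n_clips` array,
#'   and `labels`, a character vector (NA where a clip is unlabeled).
#' @export
extract_features <- function(clips, config = feature_config()) {
  feats <- lapply(clips, extract_mixed_mfcc, config = config)
  x <- array(unlist(feats, use.names = FALSE),
             dim = c(nrow(feats[[1]]), ncol(feats[[1]]), length(feats)))
  labels <- vapply(clips, function(cl) cl$label %||% NA_character_, character(1))
  list(x = x, labels = labels, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
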