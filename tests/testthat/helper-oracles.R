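# Independent naive reference implementations used to cross-check the
# package's DSP stages. Deliberately written from the defining formulas
# (direct DFT, explicit triangles, regression deltas with index clamping),
# not by calling the package code.

oracle_pre_emphasis <- function(x, alpha) {
  y <- numeric(length(x))
  y[1] <- x[1]
  for (n in 2:length(x)) y[n] <- x[n] - alpha * x[n - 1]
  y
}

oracle_standardize <- function(x, target) {
  n <- length(x)
  if (n < target) {
    lead <- (target - n) %/% 2
    c(numeric(lead), x, numeric(target - n - lead))
  } else if (n > target) {
    start <- (n - target) %/% 2
    x[(start + 1):(start + target)]
  } else x
}

oracle_frames <- function(x, frame_len, hop) {
  n_frames <- (length(x) - frame_len) %/% hop + 1
  m <- matrix(0, n_frames, frame_len)
  for (i in seq_len(n_frames))
    m[i, ] <- x[((i - 1) * hop + 1):((i - 1) * hop + frame_len)]
  m
}

oracle_hamming <- function(n) {
  k <- 0:(n - 1)
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

# Direct-definition DFT: X(k) = sum_n x(n) exp(-2i pi n k / N).
oracle_dft <- function(x, n_fft) {
  x <- c(x, numeric(n_fft - length(x)))
  n <- 0:(n_fft - 1)
  W <- exp(-2i * pi * outer(n, n) / n_fft)
  as.vector(W %*% x)
}

oracle_power_spectrum <- function(frames, n_fft) {
  n_bins <- n_fft %/% 2 + 1
  P <- matrix(0, nrow(frames), n_bins)
  for (i in seq_len(nrow(frames))) {
    X <- oracle_dft(frames[i, ], n_fft)
    P[i, ] <- Mod(X[1:n_bins])^2 / n_fft
  }
  P
}

# Explicit piecewise triangles on the snapped boundary-bin grid.
oracle_mel_bank <- function(n_mels, n_fft, sample_rate, f_min, f_max) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  bin_hz <- sample_rate / n_fft
  mels <- mel(f_min) + (0:(n_mels + 1)) * (mel(f_max) - mel(f_min)) / (n_mels + 1)
  bounds <- round(imel(mels) / bin_hz)
  n_bins <- n_fft %/% 2 + 1
  H <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    for (k in 0:(n_bins - 1)) {
      lo <- bounds[m]; ce <- bounds[m + 1]; hi <- bounds[m + 2]
      H[m, k + 1] <-
        if (k < lo || k > hi) 0
        else if (k <= ce) (k - lo) / (ce - lo)
        else (hi - k) / (hi - ce)
    }
  }
  H
}

# Double-loop orthonormal DCT-II along the Mel axis of each frame.
oracle_dct2 <- function(S, L) {
  M <- ncol(S)
  C <- matrix(0, nrow(S), L)
  for (f in seq_len(nrow(S))) {
    for (n in 0:(L - 1)) {
      acc <- 0
      for (m in 0:(M - 1)) acc <- acc + S[f, m + 1] * cos(pi * n * (m + 0.5) / M)
      C[f, n + 1] <- acc * if (n == 0) sqrt(1 / M) else sqrt(2 / M)
    }
  }
  C
}

# Windowed-regression delta with edge replication via index clamping.
oracle_delta <- function(C, k) {
  n <- nrow(C)
  D <- matrix(0, n, ncol(C))
  denom <- sum((-k:k)^2)
  for (t in seq_len(n)) {
    for (i in -k:k) {
      ti <- min(max(t + i, 1), n)
      D[t, ] <- D[t, ] + i * C[ti, ]
    }
  }
  D / denom
}

# Full oracle pipeline for a 16 kHz clip (no resampling involved).
oracle_mixed_mfcc <- function(samples, cfg) {
  target <- (cfg$n_frames - 1) * cfg$hop + cfg$frame_len
  x <- oracle_standardize(samples, target)
  x <- oracle_pre_emphasis(x, cfg$alpha)
  fr <- oracle_frames(x, cfg$frame_len, cfg$hop)
  w <- oracle_hamming(cfg$frame_len)
  for (i in seq_len(nrow(fr))) fr[i, ] <- fr[i, ] * w
  P <- oracle_power_spectrum(fr, cfg$n_fft)
  H <- oracle_mel_bank(cfg$n_mels, cfg$n_fft, cfg$sample_rate, cfg$f_min, cfg$f_max)
  S <- log(pmax(P %*% t(H), cfg$log_floor))
  C <- oracle_dct2(S, cfg$n_cepstra)
  D <- oracle_delta(C, cfg$delta_k)
  D2 <- oracle_delta(D, cfg$delta_k)
  cbind(C, D, D2)
}

# Naive counting implementation of the evaluation metrics.
oracle_metrics <- function(true, pred, classes) {
  prec <- rec <- f1 <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    prec[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ci] <- if (prec[ci] + rec[ci] > 0)
      2 * prec[ci] * rec[ci] / (prec[ci] + rec[ci]) else 0
  }
  list(accuracy = mean(true == pred), precision = prec, recall = rec, f1 = f1,
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

# Minimal stereo 16-bit WAV writer for read_wav tests.
write_stereo_wav <- function(left, right, sample_rate, path) {
  pcm <- as.integer(round(rbind(left, right) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL); w32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(2L); w32(sample_rate); w32(sample_rate * 4L); w16(4L); w16(16L)
  writeChar("data", con, eos = NULL); w32(n_bytes)
  writeBin(as.vector(pcm), con, 2, endian = "little")
  path
}
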