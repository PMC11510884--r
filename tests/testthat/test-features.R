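test_that("pre-emphasis follows the first-order high-pass recursion", {
  clip <- audio_clip(c(1, 1, 1), 16000L)
  expect_equal(pre_emphasis(clip, 0.97)$samples, c(1, 0.03, 0.03))
  x <- runif(50, -1, 1)
  expect_equal(pre_emphasis(audio_clip(x, 16000L), 0)$samples, x)
  expect_equal(pre_emphasis(audio_clip(rep(0.4, 10), 16000L), 1)$samples,
               c(0.4, numeric(9)))
  expect_equal(pre_emphasis(audio_clip(x, 16000L), 0.95)$samples,
               oracle_pre_emphasis(x, 0.95))
})

test_that("framing slices with the configured overlap", {
  clip <- audio_clip(runif(20640), 16000L)
  expect_equal(dim(frame_signal(clip, 320L, 160L)), c(128L, 320L))

  whole <- audio_clip(runif(320), 16000L)
  fr <- frame_signal(whole, 320L, 160L)
  expect_equal(nrow(fr), 1L)
  expect_equal(as.numeric(fr[1, ]), whole$samples)

  small <- frame_signal(audio_clip(1:8, 16000L), 4L, 2L)
  expect_equal(small, rbind(1:4, 3:6, 5:8))

  expect_error(frame_signal(audio_clip(1:8, 16000L), 9L, 2L), "exceeds")
})

test_that("window shapes match their defining formulas", {
  for (n in c(11L, 320L)) {
    h <- make_window("hamming", n)
    expect_equal(h[1], 0.08)
    expect_equal(h[n], 0.08)
    expect_equal(h, oracle_hamming(n))
  }
  expect_equal(make_window("hamming", 11L)[6], 1.0)   # odd-length midpoint
  expect_equal(make_window("rectangular", 5L), rep(1, 5))
  hn <- make_window("hanning", 9L)
  expect_equal(hn[1], 0); expect_equal(hn[5], 1)
  expect_true(all(hn >= 0 & hn <= 1))
  expect_error(make_window("kaiser", 8L), "arg")
})

test_that("windowing multiplies frames row by row", {
  fr <- rbind(c(1, 2), c(3, 4))
  expect_equal(apply_window(fr, c(1, 1)), fr)
  expect_equal(apply_window(fr, c(0, 0)), matrix(0, 2, 2))
  expect_equal(apply_window(matrix(c(1, 2), 1), c(0.5, 0.25)),
               matrix(c(0.5, 0.5), 1))
  expect_error(apply_window(fr, c(1, 1, 1)), "length")
})

test_that("power spectrum matches the direct DFT definition", {
  expect_equal(power_spectrum(matrix(0, 2, 8), 8L), matrix(0, 2, 5))

  const <- power_spectrum(matrix(1, 1, 4), 4L)   # |X(0)| = N so P(0) = N
  expect_equal(as.numeric(const), c(4, 0, 0))

  set.seed(5)
  fr <- matrix(runif(16, -1, 1), 2, 8)
  expect_equal(power_spectrum(fr, 8L), oracle_power_spectrum(fr, 8L),
               tolerance = 1e-9)

  # unit impulse: flat spectrum at 1/N on every bin
  imp <- matrix(c(1, numeric(7)), 1, 8)
  expect_equal(as.numeric(power_spectrum(imp, 8L)), rep(1 / 8, 5))
})

test_that("the Mel map matches its closed form and inverts exactly", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  f <- seq(0, 8000, by = 50)
  expect_true(all(diff(hz_to_mel(f)) > 0))
  expect_equal(mel_to_hz(hz_to_mel(f)), f)
  expect_error(hz_to_mel(-1), "negative")
})

test_that("the filterbank is made of unit-peak triangles summing to one", {
  bank <- mel_filterbank(40L, 512L, 16000L, 20, 8000)
  expect_equal(dim(bank$weights), c(40L, 257L))
  # each row peaks at exactly 1 on its center bin and is 0 outside its support
  for (m in c(1L, 17L, 40L)) {
    expect_equal(bank$weights[m, bank$center_bins[m + 1] + 1], 1)
    outside <- setdiff(0:256, bank$center_bins[m]:bank$center_bins[m + 2])
    expect_true(all(bank$weights[m, outside + 1] == 0))
  }
  # partition of unity at every bin strictly between the first and last center
  interior <- (bank$center_bins[2] + 1):(bank$center_bins[41] - 1)
  expect_true(all(abs(colSums(bank$weights)[interior + 1] - 1) < 1e-9))
  expect_equal(bank$weights, oracle_mel_bank(40L, 512L, 16000L, 20, 8000))
})

test_that("a two-filter toy bank reproduces hand-enumerated weights", {
  # boundaries snap to bins 0, 2, 4, 7 on an 8-bin grid (n_fft = 14 at 14 Hz
  # would be awkward; use n_fft = 16, rate 16 so bins are at integer Hz)
  bank <- mel_filterbank(2L, 16L, 16L, 0.0001, 7)
  b <- bank$center_bins
  k <- 0:8
  tri <- function(lo, ce, hi) {
    v <- numeric(9)
    v[k >= lo & k <= ce] <- (k[k >= lo & k <= ce] - lo) / (ce - lo)
    v[k > ce & k <= hi] <- (hi - k[k > ce & k <= hi]) / (hi - ce)
    v
  }
  expect_equal(bank$weights[1, ], tri(b[1], b[2], b[3]))
  expect_equal(bank$weights[2, ], tri(b[2], b[3], b[4]))
})

test_that("filterbank construction rejects impossible configurations", {
  expect_error(mel_filterbank(40L, 512L, 16000L, 20, 9000), "Nyquist")
  expect_error(mel_filterbank(120L, 64L, 16000L, 20, 8000), "collide")
})

test_that("log Mel energies apply the natural log with a finite floor", {
  bank <- mel_filterbank(4L, 64L, 16000L, 100, 8000)
  # craft a spectrum whose filtered energy is exactly 1 and exactly e
  P1 <- matrix(0, 1, 33)
  peak <- bank$center_bins[2] + 1
  P1[1, peak] <- 1
  expect_equal(as.numeric(log_mel_energies(P1, bank))[1], 0)
  expect_equal(as.numeric(log_mel_energies(exp(1) * P1, bank))[1], 1)
  floored <- log_mel_energies(matrix(0, 1, 33), bank)
  expect_true(all(is.finite(floored)))
  expect_equal(as.numeric(floored), rep(log(1e-10), 4))
})

test_that("cepstra match a double-loop DCT-II", {
  expect_equal(dct_cepstra(matrix(0, 3, 8), 4L), matrix(0, 3, 4))
  const <- dct_cepstra(matrix(2.5, 2, 8), 8L)
  expect_equal(const[, 2:8], matrix(0, 2, 7))  # only the 0th term survives
  set.seed(9)
  S <- matrix(rnorm(3 * 10), 3, 10)
  expect_equal(dct_cepstra(S, 6L), oracle_dct2(S, 6L), tolerance = 1e-9)
})

test_that("delta coefficients are regression slopes with replicated edges", {
  const <- matrix(3, 6, 4)
  expect_equal(delta_coefficients(const, 2L), matrix(0, 6, 4))

  ramp <- matrix(rep(0.5 * (1:8), 3), 8, 3)   # slope 0.5 per frame
  D <- delta_coefficients(ramp, 2L)
  expect_equal(D[3:6, ], matrix(0.5, 4, 3))   # interior frames recover it

  set.seed(13)
  C <- matrix(rnorm(18), 6, 3)
  expect_equal(delta_coefficients(C, 2L), oracle_delta(C, 2L))

  # linearity
  A <- matrix(rnorm(18), 6, 3); B <- matrix(rnorm(18), 6, 3)
  expect_equal(delta_coefficients(2 * A - 3 * B, 2L),
               2 * delta_coefficients(A, 2L) - 3 * delta_coefficients(B, 2L))
})

test_that("stacking preserves the [static | delta | delta2] column order", {
  C <- matrix(1, 128, 40); D <- matrix(2, 128, 40); D2 <- matrix(3, 128, 40)
  mixed <- stack_mixed(C, D, D2)
  expect_equal(dim(mixed), c(128L, 120L))
  expect_equal(unname(mixed[1, 41]), 2)    # column 1 of delta is column 41
  expect_equal(unname(mixed[1, 81]), 3)
  expect_equal(stack_mixed(C * 0, D * 0, D2 * 0)[5, 5], 0)
  expect_error(stack_mixed(C, D[, 1:20], D2), "mismatch")
})

test_that("the full extractor is deterministic and shape-stable", {
  cfg <- feature_config()
  for (dur in c(0.4, 1.3, 2.5)) {
    clip <- audio_clip(runif(round(16000 * dur), -1, 1), 16000L)
    expect_equal(dim(extract_mixed_mfcc(clip, cfg)), c(128L, 120L))
  }
  clip <- generate_cry(synth_spec("hungry", seed = 2))
  f1 <- extract_mixed_mfcc(clip, cfg)
  f2 <- extract_mixed_mfcc(clip, cfg)
  expect_identical(f1, f2)
  # a differently-sampled clip still lands on the canonical shape
  clip8k <- audio_clip(runif(8000, -1, 1), 8000L)
  expect_equal(dim(extract_mixed_mfcc(clip8k, cfg)), c(128L, 120L))
})

test_that("feature configurations survive the JSON sidecar round trip", {
  cfg <- feature_config(n_mels = 13L, n_cepstra = 13L, alpha = 0.9)
  path <- withr::local_tempfile(fileext = ".json")
  save_feature_config(cfg, path)
  back <- load_feature_config(path)
  expect_equal(back, cfg)
})

test_that("thirteen-filter configuration remains available", {
  cfg <- feature_config(n_mels = 13L, n_cepstra = 13L)
  clip <- audio_clip(runif(16000, -1, 1), 16000L)
  f <- extract_mixed_mfcc(clip, cfg)
  expect_equal(dim(f), c(128L, 39L))
})
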