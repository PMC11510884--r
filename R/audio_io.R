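#' Construct an audio clip
#'
#' The basic unit of input: a mono waveform with its sample rate and an
#' optional class label.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @param label Optional class label, one of `"hungry"`, `"uncomfortable"`,
#'   `"pain"`.
#' @param source_id Opaque identifier of the clip's origin.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, label = NULL, source_id = NULL) {
  if (length(samples) == 0L) stop("audio_clip: samples must be non-empty")
  if (!is.numeric(samples) || !is.null(dim(samples)))
    stop("audio_clip: samples must be a one-dimensional numeric vector (mono)")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("audio_clip: sample_rate must be a positive number")
  if (!is.null(label)) label <- match.arg(label, cry_classes())
  structure(
    list(samples = as.numeric(samples), sample_rate = as.integer(sample_rate),
         label = label, source_id = source_id),
    class = "audio_clip"
  )
}

#' The three cry classes
#'
#' @return Character vector `c("hungry", "uncomfortable", "pain")`.
#' @export
cry_classes <- function() c("hungry", "uncomfortable", "pain")

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %d Hz (%.2f s)%s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An [audio_clip()].
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

# ---- RIFF/PCM WAV ----------------------------------------------------------

read_u32 <- function(con) readBin(con, "integer", 1, 4, signed = TRUE, endian = "little")

#' Read a RIFF/PCM WAV file
#'
#' Reads 8/16/24-bit integer PCM or 32/64-bit float WAV, averages stereo to
#' mono, and scales integer samples to `[-1, 1]` by the format's full scale.
#'
#' @param path Path to a `.wav` file.
#' @param label,source_id Optional metadata attached to the returned clip;
#'   `source_id` defaults to the file path.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, label = NULL, source_id = NULL) {
  if (!file.exists(path)) stop("read_wav: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  read_u32(con)
  wave <- rawToChar(readBin(con, "raw", 4))
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    chunk_id <- rawToChar(id)
    size <- read_u32(con)
    if (chunk_id == "fmt ") {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(body[3:4]) * c(1L, 256L)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
    } else if (chunk_id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("read_wav: corrupt WAV (missing fmt or data chunk): ", path)

  x <- decode_pcm(data_raw, fmt, path)
  if (fmt$n_channels == 2L) {
    x <- (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]) / 2
  } else if (fmt$n_channels != 1L) {
    stop("read_wav: unsupported channel count ", fmt$n_channels, " in ", path)
  }
  x[x > 1] <- 1; x[x < -1] <- -1
  audio_clip(x, fmt$sample_rate, label = label,
             source_id = if (is.null(source_id)) path else source_id)
}

decode_pcm <- function(raw, fmt, path) {
  n <- length(raw)
  if (fmt$audio_format == 1L) {            # integer PCM
    if (fmt$bits == 16L) {
      readBin(raw, "integer", n / 2, 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 8L) {           # 8-bit WAV is unsigned
      (as.integer(raw) - 128) / 128
    } else if (fmt$bits == 24L) {
      b <- matrix(as.integer(raw), nrow = 3)
      v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else {
      stop("read_wav: unsupported PCM bit depth ", fmt$bits, " in ", path)
    }
  } else if (fmt$audio_format == 3L) {     # IEEE float
    if (fmt$bits == 32L) {
      readBin(raw, "numeric", n / 4, 4, endian = "little")
    } else if (fmt$bits == 64L) {
      readBin(raw, "numeric", n / 8, 8, endian = "little")
    } else {
      stop("read_wav: unsupported float bit depth ", fmt$bits, " in ", path)
    }
  } else {
    stop("read_wav: unsupported WAV encoding (format tag ", fmt$audio_format,
         ") in ", path)
  }
}

#' Write a clip as 16-bit PCM WAV
#'
#' @param clip An [audio_clip()]; samples outside `[-1, 1]` are clipped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(pmax(clip$samples, -1), 1)
  pcm <- as.integer(pmin(round(x * 32768), 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(1L)                       # PCM, mono
  w32(clip$sample_rate)
  w32(clip$sample_rate * 2L)             # byte rate
  w16(2L); w16(16L)                      # block align, bits
  writeChar("data", con, eos = NULL); w32(n_bytes)
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

# ---- resampling and length standardization ---------------------------------

#' Resample a clip
#'
#' Polyphase resampling (via the signal package) to a target rate; the
#' identity rate returns the clip unchanged.
#'
#' @param clip An [audio_clip()].
#' @param target_rate Target sampling rate in Hz.
#' @return An [audio_clip()] at `target_rate` with duration preserved to
#'   within one sample period.
#' @export
resample_clip <- function(clip, target_rate) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("resample_clip: target_rate must be positive")
  target_rate <- as.integer(target_rate)
  if (target_rate == clip$sample_rate) return(clip)
  g <- gcd(clip$sample_rate, target_rate)
  p <- target_rate %/% g
  q <- clip$sample_rate %/% g
  y <- signal::resample(clip$samples, p, q)
  n_target <- round(length(clip$samples) * target_rate / clip$sample_rate)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, numeric(n_target - length(y)))
  y[y > 1] <- 1; y[y < -1] <- -1
  audio_clip(y, target_rate, label = clip$label, source_id = clip$source_id)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Standardize a clip to an exact frame count
#'
#' Pads (symmetrically, with zeros) or truncates (centered) so that framing
#' with the given frame length and hop yields exactly `n_frames` frames, i.e.
#' `(n_frames - 1) * hop + frame_len` samples.
#'
#' @param clip An [audio_clip()].
#' @param n_frames Target number of analysis frames (default 128).
#' @param frame_len Frame length in samples (default 320 = 20 ms at 16 kHz).
#' @param hop Frame shift in samples (default half the frame length).
#' @return An [audio_clip()] of the exact target length.
#' @export
standardize_length <- function(clip, n_frames = 128L, frame_len = 320L,
                               hop = frame_len %/% 2L) {
  stopifnot(inherits(clip, "audio_clip"))
  if (n_frames < 1L) stop("standardize_length: n_frames must be >= 1")
  target <- (n_frames - 1L) * hop + frame_len
  x <- clip$samples
  n <- length(x)
  if (n < target) {
    lead <- (target - n) %/% 2L
    x <- c(numeric(lead), x, numeric(target - n - lead))
  } else if (n > target) {
    start <- (n - target) %/% 2L
    x <- x[(start + 1L):(start + target)]
  }
  audio_clip(x, clip$sample_rate, label = clip$label, source_id = clip$source_id)
}

# ---- manifests -------------------------------------------------------------

#' Load a dataset manifest
#'
#' A manifest is a CSV with header `path,label,source`, one row per clip.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `cry_manifest` with columns
#'   `path`, `label`, `source`, rows in file order.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("load_manifest: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("path", "label", "source"), names(df))
  if (length(missing))
    stop("load_manifest: missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$path))
    stop("load_manifest: duplicate paths: ",
         paste(unique(df$path[duplicated(df$path)]), collapse = ", "))
  if (nrow(df) > 0 && any(!nzchar(df$label)))
    stop("load_manifest: empty labels at row(s): ",
         paste(which(!nzchar(df$label)), collapse = ", "))
  df <- df[, c("path", "label", "source")]
  class(df) <- c("cry_manifest", "data.frame")
  df
}

#' Write a dataset manifest
#'
#' @param manifest A data frame with columns `path`, `label`, `source`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest[, c("path", "label", "source")], path, row.names = FALSE)
  invisible(path)
}
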