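#' Synthetic cry specification
#'
#' Class-specific acoustics for the generator. The three classes are made
#' acoustically separable by construction through disjoint fundamental
#' frequency (f0) ranges and distinct amplitude-modulation (AM) patterns:
#' pain cries sit highest (500-600 Hz) with abrupt on/off bursts, hungry
#' cries are mid-range (330-400 Hz) with a smooth 3 Hz rhythm, and
#' uncomfortable cries are lowest (260-320 Hz) with a slower rhythm and more
#' noise. These signatures are the package's own invention — the generator
#' exists so the pipeline is testable, not to model infant physiology.
#'
#' @param class_name One of `"hungry"`, `"uncomfortable"`, `"pain"`.
#' @param duration_s Clip duration in seconds (default 1.3 s, enough to fill
#'   128 analysis frames at 16 kHz).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed; the generated waveform is a pure function of the
#'   spec.
#' @param f0_range Two-element Hz interval the fundamental is drawn from;
#'   class default if `NULL`.
#' @param am_rate Amplitude-modulation rate in Hz; class default if `NULL`.
#' @param am_shape `"smooth"` (sinusoidal envelope) or `"burst"` (abrupt
#'   onsets); class default if `NULL`.
#' @param noise_level Additive noise amplitude relative to the (unit) peak of
#'   the harmonic stack, in `[0, 1)`; class default if `NULL`.
#' @param n_harmonics Number of harmonics in the stack.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(class_name, duration_s = 1.3, sample_rate = 16000L,
                       seed = 1L, f0_range = NULL, am_rate = NULL,
                       am_shape = NULL, noise_level = NULL, n_harmonics = 8L) {
  class_name <- match.arg(class_name, cry_classes())
  defaults <- list(
    hungry        = list(f0_range = c(330, 400), am_rate = 3.0,
                         am_shape = "smooth", noise_level = 0.05),
    uncomfortable = list(f0_range = c(260, 320), am_rate = 1.5,
                         am_shape = "smooth", noise_level = 0.15),
    pain          = list(f0_range = c(500, 600), am_rate = 5.0,
                         am_shape = "burst",  noise_level = 0.08)
  )[[class_name]]
  f0_range <- f0_range %||% defaults$f0_range
  am_rate <- am_rate %||% defaults$am_rate
  am_shape <- match.arg(am_shape %||% defaults$am_shape, c("smooth", "burst"))
  noise_level <- noise_level %||% defaults$noise_level
  if (noise_level < 0 || noise_level >= 1)
    stop("synth_spec: noise_level must be in [0, 1)")
  structure(list(class_name = class_name, duration_s = duration_s,
                 sample_rate = as.integer(sample_rate), seed = as.integer(seed),
                 f0_range = f0_range, am_rate = am_rate, am_shape = am_shape,
                 noise_level = noise_level, n_harmonics = as.integer(n_harmonics)),
            class = "synth_spec")
}

#' Generate one synthetic cry
#'
#' A harmonic stack at a seeded fundamental drawn from the class's f0 range,
#' shaped by the class's amplitude-modulation envelope, plus additive noise;
#' peak-normalized to `[-1, 1]` and labeled with the class. Deterministic:
#' the same spec always yields bit-identical samples.
#'
#' @param spec A [synth_spec()].
#' @return A labeled [audio_clip()].
#' @export
generate_cry <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- round(spec$duration_s * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  f0 <- runif(1, spec$f0_range[1], spec$f0_range[2])
  phases <- runif(spec$n_harmonics, 0, 2 * pi)
  x <- numeric(n)
  for (h in seq_len(spec$n_harmonics))
    x <- x + sin(2 * pi * h * f0 * t + phases[h]) / h
  x <- x / max(abs(x))

  env <- if (spec$am_shape == "smooth") {
    0.55 + 0.45 * sin(2 * pi * spec$am_rate * t + runif(1, 0, 2 * pi))
  } else {  # abrupt onsets: hard on/off bursts with a small leak floor
    ifelse(sin(2 * pi * spec$am_rate * t + runif(1, 0, 2 * pi)) > 0, 1, 0.05)
  }
  x <- x * env + spec$noise_level * rnorm(n)
  x <- x / max(abs(x))
  audio_clip(x, spec$sample_rate, label = spec$class_name,
             source_id = sprintf("synth:%s:%d", spec$class_name, spec$seed))
}

#' Generate a balanced synthetic dataset
#'
#' `3 * n_per_class` clips with unique per-clip seeds derived from the master
#' seed, plus a manifest. Optionally writes WAV files and the manifest CSV.
#'
#' @param n_per_class Clips per class.
#' @param seed Master seed; the whole dataset is a pure function of it.
#' @param dir If non-`NULL`, write `<class>_<i>.wav` files and `manifest.csv`
#'   there.
#' @return A list with `clips` (list of labeled [audio_clip()]s) and
#'   `manifest` (a `cry_manifest` data frame; paths are empty strings unless
#'   `dir` is given).
#' @export
generate_dataset <- function(n_per_class, seed = 1L, dir = NULL) {
  if (n_per_class < 1) stop("generate_dataset: n_per_class must be >= 1")
  classes <- cry_classes()
  clips <- vector("list", 3L * n_per_class)
  paths <- character(3L * n_per_class)
  j <- 0L
  for (ci in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      j <- j + 1L
      clip_seed <- as.integer((as.double(seed) + 104729 * ci + 7919 * i) %% 2147483647)
      clips[[j]] <- generate_cry(synth_spec(classes[ci], seed = clip_seed))
      paths[j] <- sprintf("%s_%03d.wav", classes[ci], i)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        write_wav(clips[[j]], file.path(dir, paths[j]))
      }
    }
  }
  manifest <- data.frame(
    path = if (is.null(dir)) paths else file.path(dir, paths),
    label = rep(classes, each = n_per_class),
    source = "synthetic", stringsAsFactors = FALSE)
  class(manifest) <- c("cry_manifest", "data.frame")
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(clips = clips, manifest = manifest)
}

#' Default label-harmonization rules
#'
#' Maps the heterogeneous raw labels of public cry corpora onto the three
#' target classes: hunger synonyms to `hungry`; tiredness, being held,
#' hiccups, loneliness, fear, burping and general discomfort to
#' `uncomfortable`; abdominal/head/oral pain to `pain`. Clinical categories
#' with no clear place in this taxonomy (e.g. deafness, asphyxia) are
#' deliberately absent and therefore rejected by [map_source_label()].
#'
#' @return Named character vector: normalized raw label -> target class.
#' @export
default_label_map <- function() {
  c("hungry" = "hungry", "hunger" = "hungry", "need to eat" = "hungry",
    "want something to eat" = "hungry",
    "tiredness" = "uncomfortable", "tired" = "uncomfortable",
    "needing to be held" = "uncomfortable", "hold" = "uncomfortable",
    "hiccup" = "uncomfortable", "hiccups" = "uncomfortable",
    "hiccupping" = "uncomfortable", "loneliness" = "uncomfortable",
    "lonely" = "uncomfortable", "fear" = "uncomfortable",
    "scared" = "uncomfortable", "burping" = "uncomfortable",
    "needs burping" = "uncomfortable", "discomfort" = "uncomfortable",
    "uncomfortable" = "uncomfortable",
    "pain" = "pain", "abdominal pain" = "pain", "belly pain" = "pain",
    "headache" = "pain", "headaches" = "pain", "oral pain" = "pain")
}

#' Harmonize a raw source label
#'
#' Case-folds, trims, and collapses whitespace/underscores before a
#' deterministic lookup. Unknown labels raise an error naming the offending
#' value — they are never silently dropped or guessed.
#'
#' @param raw Raw label string from a source corpus.
#' @param map Named vector of rules, as from [default_label_map()].
#' @return One of `"hungry"`, `"uncomfortable"`, `"pain"`.
#' @export
map_source_label <- function(raw, map = default_label_map()) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("map_source_label: raw label must be a non-empty string")
  key <- tolower(trimws(gsub("[_[:space:]]+", " ", raw)))
  if (!key %in% names(map))
    stop("map_source_label: unknown raw label: \"", raw, "\"")
  unname(map[[key]])
}

#' Load label-harmonization rules from CSV
#'
#' @param path CSV with header `raw,target`.
#' @return Named character vector usable with [map_source_label()].
#' @export
load_label_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("raw", "target"), names(df))
  if (length(missing))
    stop("load_label_map: missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$target), cry_classes())
  if (length(bad))
    stop("load_label_map: invalid target class(es): ", paste(bad, collapse = ", "))
  stats::setNames(df$target, tolower(trimws(gsub("[_[:space:]]+", " ", df$raw))))
}
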