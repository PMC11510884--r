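#' Model architecture configuration
#'
#' Describes the SE-ResNet-Transformer: a 7x7/stride-2 convolution stem with
#' a 3x3/stride-2 max pool, one squeeze-and-excitation multiscale residual
#' block, spatial pyramid pooling to a fixed 21-token sequence, three
#' transformer encoder stacks applied in sequence, and an
#' average-pool/dense/softmax head. The ablation switches (`use_se`,
#' `use_skip`, `multiscale`) select the reduced variants used in the
#' ablation harness.
#'
#' @param input_shape Height and width of the input feature matrix (time
#'   frames x feature columns); the matrix enters the stem as a 1-channel
#'   image.
#' @param stem_channels Output channels of the stem convolution.
#' @param branch_channels Output channels of each residual branch
#'   convolution; must equal `stem_channels` so the skip addition is
#'   well-formed.
#' @param kernel_sizes Odd kernel sizes of the multiscale branches.
#' @param use_se Apply squeeze-and-excitation recalibration to the residual
#'   branch (before the addition).
#' @param use_skip Keep the identity skip connection.
#' @param multiscale Use all `kernel_sizes` branches in parallel; otherwise a
#'   single 3x3 branch (ordinary convolution).
#' @param reduction SE bottleneck ratio `r` (the gate network maps
#'   `C -> C/r -> C`); 16, 32, 64 and 128 are the supported sweep values.
#' @param spp_levels Pyramid grid sizes; `c(1, 2, 4)` yields 21 tokens.
#' @param transformer_stacks List of stacks, each
#'   `c(head_size, n_heads, ff_dim, n_layers)`; the stack's model dimension
#'   is `head_size * n_heads` and tokens are linearly projected on entry
#'   when the dimension changes.
#' @param positional_encoding Add a fixed sinusoidal positional encoding to
#'   the token sequence (off by default: the 21 pyramid tokens already have
#'   fixed identities).
#' @param head_units Width of the fully connected layer before the softmax.
#' @param n_classes Number of output classes.
#' @param seed Seed for weight initialization; building twice with one seed
#'   gives identical weights.
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_shape = c(128L, 120L),
                         stem_channels = 64L, branch_channels = 64L,
                         kernel_sizes = c(3L, 5L, 7L),
                         use_se = TRUE, use_skip = TRUE, multiscale = TRUE,
                         reduction = 16L, spp_levels = c(1L, 2L, 4L),
                         transformer_stacks = list(c(16L, 4L, 32L, 2L),
                                                   c(32L, 8L, 64L, 2L),
                                                   c(64L, 8L, 128L, 2L)),
                         positional_encoding = FALSE,
                         head_units = 1000L, n_classes = 3L, seed = 42L) {
  if (n_classes < 2) stop("model_config: n_classes must be >= 2")
  if (any(kernel_sizes %% 2 == 0)) stop("model_config: kernel sizes must be odd")
  if (stem_channels != branch_channels)
    stop("model_config: stem_channels must equal branch_channels for the skip addition")
  if (branch_channels / reduction < 1)
    stop("model_config: reduction larger than the channel count")
  if (is.matrix(transformer_stacks))   # e.g. re-read from an architecture JSON
    transformer_stacks <- lapply(seq_len(nrow(transformer_stacks)),
                                 function(i) transformer_stacks[i, ])
  structure(list(input_shape = as.integer(input_shape),
                 stem_channels = as.integer(stem_channels),
                 branch_channels = as.integer(branch_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 use_se = use_se, use_skip = use_skip, multiscale = multiscale,
                 reduction = as.integer(reduction),
                 spp_levels = as.integer(spp_levels),
                 transformer_stacks = lapply(transformer_stacks, as.integer),
                 positional_encoding = positional_encoding,
                 head_units = as.integer(head_units),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "model_config")
}

#' Build the classifier
#'
#' Instantiates the network described by a [model_config()] with seeded
#' weight initialization (He-normal before ReLU, Glorot-uniform elsewhere).
#'
#' @param config A [model_config()].
#' @return An object of class `crynet_model`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  m <- new.env(parent = emptyenv())
  m$config <- config
  m$stem <- stem_env(7L, 7L, 1L, config$stem_channels, stride = 2L, pad = 3L)
  m$block <- resblock_env(config$stem_channels, config$kernel_sizes,
                          config$branch_channels, config$use_se,
                          config$use_skip, config$multiscale, config$reduction)
  m$spp <- spp_env(config$spp_levels)
  d <- config$branch_channels
  m$stacks <- lapply(config$transformer_stacks, function(s) {
    st <- encoder_stack_env(d, s[1], s[2], s[3], s[4])
    d <<- st$d_model
    st
  })
  m$head_fc <- dense_env(d, config$head_units, act = "relu")
  m$head_out <- dense_env(config$head_units, config$n_classes, act = "linear")
  m$pe <- if (config$positional_encoding)
    sinusoidal_encoding(m$spp$n_tokens, config$branch_channels) else NULL

  # dimension trace: fail at build time if the pyramid cannot fit
  hw <- floor((config$input_shape - 1) / 2) + 1
  hw <- floor((hw - 1) / 2) + 1
  if (any(hw < max(config$spp_levels)))
    stop("build_model: feature map ", hw[1], "x", hw[2],
         " after the stem is smaller than the finest pyramid grid (",
         max(config$spp_levels), "x", max(config$spp_levels), ")")
  class(m) <- "crynet_model"
  m
}

sinusoidal_encoding <- function(n_tok, d) {
  pos <- matrix(0, n_tok, d)
  p <- seq_len(n_tok) - 1
  for (i in seq_len(d %/% 2)) {
    w <- 1 / 10000^(2 * (i - 1) / d)
    pos[, 2 * i - 1] <- sin(p * w)
    pos[, 2 * i] <- cos(p * w)
  }
  pos
}

#' @export
print.crynet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "<crynet_model> input %dx%d, %s%s%s block (%d ch, r=%d), SPP [%s] -> %d tokens,\n",
    "  %d transformer stacks, head %d -> %d classes, %s parameters\n"),
    cfg$input_shape[1], cfg$input_shape[2],
    if (cfg$use_se) "SE-" else "", if (cfg$use_skip) "Res" else "Conv",
    if (cfg$multiscale) "(multiscale)" else "(ordinary)",
    cfg$branch_channels, cfg$reduction,
    paste(cfg$spp_levels, collapse = ","), x$spp$n_tokens,
    length(x$stacks), cfg$head_units, cfg$n_classes,
    format(n_params(x), big.mark = ",")))
  invisible(x)
}

model_param_envs <- function(model) {
  collect_param_envs(list(model$stem, model$block, model$stacks,
                          model$head_fc, model$head_out))
}

#' Number of trainable parameters
#'
#' @param model A `crynet_model`.
#' @return Integer count of trainable scalars.
#' @export
n_params <- function(model) {
  sum(vapply(model_param_envs(model),
             function(e) sum(vapply(e$params, length, 0L)), 0))
}

# Forward pass to logits. x: (H, W, 1, N) array.
model_forward <- function(model, x, train = FALSE) {
  h <- stem_fwd(model$stem, x, train)
  h <- resblock_fwd(model$block, h, train)
  tok <- spp_fwd(model$spp, h, train)
  n_tok <- model$spp$n_tokens
  if (!is.null(model$pe))
    tok <- tok + model$pe[rep(seq_len(n_tok), nrow(tok) %/% n_tok), ]
  for (st in model$stacks) tok <- encoder_stack_fwd(st, tok, n_tok, train)
  n_items <- nrow(tok) %/% n_tok
  pooled <- rowsum(tok, rep(seq_len(n_items), each = n_tok)) / n_tok
  h1 <- dense_fwd(model$head_fc, pooled, train)
  dense_fwd(model$head_out, h1, train)
}

model_backward <- function(model, dlogits) {
  d <- dense_bwd(model$head_fc, dense_bwd(model$head_out, dlogits))
  n_tok <- model$spp$n_tokens
  dtok <- d[rep(seq_len(nrow(d)), each = n_tok), , drop = FALSE] / n_tok
  for (st in rev(model$stacks)) dtok <- encoder_stack_bwd(st, dtok)
  dh <- spp_bwd(model$spp, dtok)
  dh <- resblock_bwd(model$block, dh)
  stem_bwd(model$stem, dh)
  invisible(NULL)
}

softmax_probs <- function(logits) {
  p <- exp(logits - apply(logits, 1, max))
  p / rowSums(p)
}

#' Predict class probabilities
#'
#' @param object A `crynet_model`.
#' @param x A single feature matrix, or an `H x W x N` array of features.
#' @param batch_size Items per forward pass.
#' @param ... Unused.
#' @return An `N x n_classes` matrix of probabilities (rows sum to 1),
#'   columns named by class.
#' @export
predict.crynet_model <- function(object, x, batch_size = 64L, ...) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  n <- d[3]
  probs <- matrix(0, n, object$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- array(x[, , idx], c(d[1], d[2], 1L, length(idx)))
    probs[idx, ] <- softmax_probs(model_forward(object, xb, train = FALSE))
  }
  colnames(probs) <- if (object$config$n_classes == 3L) cry_classes() else NULL
  probs
}

# ---- standalone SE operators (single feature map) --------------------------

#' Squeeze-and-excitation operators
#'
#' The three stages of channel attention on a single `H x W x C` feature
#' map: `se_squeeze` reduces each channel to its spatial mean; `se_excite`
#' passes the squeezed vector through the bottleneck gate network
#' `sigmoid(W2 %*% relu(W1 %*% z))`; `se_reweight` rescales each channel of
#' a map by its gate.
#'
#' @param map An `H x W x C` numeric array.
#' @param z Length-`C` squeezed vector.
#' @param w1 `C/r x C` weight matrix of the bottleneck layer.
#' @param w2 `C x C/r` weight matrix of the expansion layer.
#' @param gate Length-`C` vector of channel weights in `(0, 1)`.
#' @return `se_squeeze`: length-`C` vector; `se_excite`: length-`C` gate in
#'   `(0, 1)`; `se_reweight`: the rescaled map.
#' @export
se_squeeze <- function(map) {
  stopifnot(length(dim(map)) == 3)
  d <- dim(map)
  colMeans(matrix(map, d[1] * d[2], d[3]))
}

#' @rdname se_squeeze
#' @export
se_excite <- function(z, w1, w2) {
  if (ncol(w1) != length(z) || ncol(w2) != nrow(w1) || nrow(w2) != length(z))
    stop("se_excite: inconsistent shapes: z has length ", length(z),
         ", w1 is ", nrow(w1), "x", ncol(w1), ", w2 is ", nrow(w2), "x", ncol(w2))
  as.numeric(sigmoid(w2 %*% relu(w1 %*% z)))
}

#' @rdname se_squeeze
#' @export
se_reweight <- function(map, gate) {
  stopifnot(length(dim(map)) == 3)
  d <- dim(map)
  if (length(gate) != d[3])
    stop("se_reweight: gate length ", length(gate), " != ", d[3], " channels")
  map * array(rep(gate, each = d[1] * d[2]), d)
}

#' Spatial pyramid pooling of one feature map
#'
#' For each level `l` the map is split into an `l x l` grid and each cell is
#' max-pooled over space, producing a fixed-length token sequence (21 tokens
#' for levels 1, 2, 4) ordered level-major, row-major within a level.
#'
#' @param map An `H x W x C` numeric array with `H, W >= max(levels)`.
#' @param levels Integer pyramid grid sizes.
#' @return A `sum(levels^2) x C` matrix, one token per row.
#' @export
spatial_pyramid_pool <- function(map, levels = c(1L, 2L, 4L)) {
  stopifnot(length(dim(map)) == 3)
  x <- array(map, c(dim(map), 1L))
  cn_spp_forward(x, as.integer(levels))$tokens
}

# ---- persistence -----------------------------------------------------------

#' Save and load model checkpoints
#'
#' `save_model` writes the weights plus the full architecture description;
#' `load_model` rebuilds the model from the stored configuration and
#' restores the weights, giving an exact copy.
#'
#' @param model A `crynet_model`.
#' @param path Checkpoint file path (RDS format).
#' @return `save_model`: `path`, invisibly; `load_model`: a `crynet_model`.
#' @export
save_model <- function(model, path) {
  envs <- model_param_envs(model)
  saveRDS(list(config = unclass(model$config),
               params = lapply(envs, function(e) e$params)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  st <- readRDS(path)
  cfg <- do.call(model_config, st$config)
  model <- build_model(cfg)
  envs <- model_param_envs(model)
  if (length(envs) != length(st$params))
    stop("load_model: checkpoint does not match the stored architecture")
  for (i in seq_along(envs)) {
    envs[[i]]$params <- st$params[[i]]
    zero_grads(envs[[i]])
  }
  model
}

#' Dump the architecture as JSON
#'
#' Records every [model_config()] field so the exact architecture can be
#' rebuilt elsewhere.
#'
#' @param model A `crynet_model` (or a [model_config()]).
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
save_architecture <- function(model, path) {
  cfg <- if (inherits(model, "crynet_model")) model$config else model
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
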