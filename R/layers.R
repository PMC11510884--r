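# Network layer primitives with explicit forward/backward passes.
#
# Each component is an environment holding $params (named arrays), $grads
# (same shapes, accumulated by the backward pass) and $cache (forward-pass
# intermediates). Feature maps are (H, W, C, N) arrays; token sequences are
# ((N * n_tok) x d) matrices with row (i-1)*n_tok + t for item i, token t.

new_component <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$cache <- list()
  e
}

zero_grads <- function(e) {
  e$grads <- lapply(e$params, function(p) array(0, dim = dim(p) %||% length(p)))
  invisible(e)
}

# He-normal for ReLU-facing weights, Glorot-uniform for linear/sigmoid ones.
init_he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
init_glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution -----------------------------------------------------------

conv_env <- function(kh, kw, cin, cout, stride = 1L, pad = (kh - 1L) %/% 2L,
                     act = c("linear", "relu")) {
  e <- new_component("conv")
  e$act <- match.arg(act)
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  fan_in <- kh * kw * cin
  w <- if (e$act == "relu") init_he(c(kh, kw, cin, cout), fan_in)
       else init_glorot(c(kh, kw, cin, cout), fan_in, kh * kw * cout)
  e$params <- list(w = w, b = numeric(cout))
  zero_grads(e)
}

conv_fwd <- function(e, x, train = FALSE) {
  act <- if (e$act == "relu") 1L else 0L
  y <- cn_conv2d_forward(x, e$params$w, e$params$b, e$stride, e$pad, act)
  if (train) {
    e$cache$x <- x
    if (act == 1L) e$cache$y <- y
  }
  y
}

# need_dx = FALSE skips the input-gradient (for the first layer).
conv_bwd <- function(e, dy, need_dx = TRUE) {
  act <- if (e$act == "relu") 1L else 0L
  g <- cn_conv2d_backward(e$cache$x, e$params$w, dy, e$stride, e$pad, need_dx,
                          act, if (act == 1L) e$cache$y else NULL)
  e$grads$w <- e$grads$w + g$dw
  e$grads$b <- e$grads$b + g$db
  g$dx
}

# ---- fused stem: conv + ReLU + max pool ------------------------------------

stem_env <- function(kh, kw, cin, cout, stride = 2L, pad = 3L,
                     pool_k = 3L, pool_stride = 2L, pool_pad = 1L) {
  e <- new_component("stempool")
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$pool_k <- as.integer(pool_k); e$pool_stride <- as.integer(pool_stride)
  e$pool_pad <- as.integer(pool_pad)
  e$params <- list(w = init_he(c(kh, kw, cin, cout), kh * kw * cin),
                   b = numeric(cout))
  zero_grads(e)
}

stem_fwd <- function(e, x, train = FALSE) {
  out <- cn_stempool_forward(x, e$params$w, e$params$b, e$stride, e$pad,
                             e$pool_k, e$pool_k, e$pool_stride, e$pool_pad)
  if (train) e$cache <- list(x = x, y = out$y, idx = out$idx)
  out$y
}

stem_bwd <- function(e, dy) {
  g <- cn_stempool_backward(e$cache$x, e$params$w, dy, e$cache$y, e$cache$idx,
                            e$stride, e$pad)
  e$grads$w <- e$grads$w + g$dw
  e$grads$b <- e$grads$b + g$db
  invisible(NULL)
}

# ---- max pooling -----------------------------------------------------------

pool_env <- function(kh = 3L, kw = 3L, stride = 2L, pad = 1L) {
  e <- new_component("maxpool")
  e$kh <- kh; e$kw <- kw; e$stride <- stride; e$pad <- pad
  e
}

pool_fwd <- function(e, x, train = FALSE) {
  out <- cn_maxpool_forward(x, e$kh, e$kw, e$stride, e$pad)
  if (train) { e$cache$idx <- out$idx; e$cache$xdim <- dim(x) }
  out$y
}

pool_bwd <- function(e, dy) cn_maxpool_backward(dy, e$cache$idx, e$cache$xdim)

# ---- squeeze-and-excitation ------------------------------------------------

se_env <- function(channels, reduction) {
  e <- new_component("se")
  cr <- max(1L, channels %/% reduction)
  e$params <- list(w1 = init_he(c(cr, channels), channels),
                   w2 = init_glorot(c(channels, cr), cr, channels))
  zero_grads(e)
}

# Mean over the spatial dims of a (H, W, C, N) batch -> C x N matrix.
batch_squeeze <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
}

# Broadcast a C x N matrix over the spatial dims of a (H, W, C, N) batch.
bcast_channels <- function(s, d) array(rep(s, each = d[1] * d[2]), d)

se_fwd <- function(e, x, train = FALSE) {
  d <- dim(x)
  z <- batch_squeeze(x)
  a1 <- relu(e$params$w1 %*% z)
  s <- sigmoid(e$params$w2 %*% a1)
  if (train) e$cache <- list(x = x, z = z, a1 = a1, s = s)
  x * bcast_channels(s, d)
}

se_bwd <- function(e, dy) {
  cc <- e$cache
  d <- dim(cc$x)
  hw <- d[1] * d[2]
  # gate path: ds_c = sum over space of dy * x
  ds <- matrix(colSums(matrix(dy * cc$x, hw)), d[3], d[4])
  dpre2 <- ds * cc$s * (1 - cc$s)
  e$grads$w2 <- e$grads$w2 + dpre2 %*% t(cc$a1)
  da1 <- t(e$params$w2) %*% dpre2
  dpre1 <- da1 * (cc$a1 > 0)
  e$grads$w1 <- e$grads$w1 + dpre1 %*% t(cc$z)
  dz <- t(e$params$w1) %*% dpre1
  # direct path + squeeze path (product rule: x feeds both the map and the gate)
  dy * bcast_channels(cc$s, d) + bcast_channels(dz / hw, d)
}

# ---- SE multiscale residual block ------------------------------------------

resblock_env <- function(channels, kernel_sizes = c(3L, 5L, 7L),
                         branch_channels = channels, use_se = TRUE,
                         use_skip = TRUE, multiscale = TRUE, reduction = 16L) {
  e <- new_component("resblock")
  e$use_se <- use_se; e$use_skip <- use_skip; e$multiscale <- multiscale
  ks <- if (multiscale) kernel_sizes else kernel_sizes[1]
  e$branches <- lapply(ks, function(k)
    conv_env(k, k, channels, branch_channels, act = "relu"))
  e$proj <- conv_env(1L, 1L, branch_channels * length(ks), channels, act = "linear")
  e$se <- if (use_se) se_env(channels, reduction) else NULL
  e
}

resblock_fwd <- function(e, x, train = FALSE) {
  bs <- lapply(e$branches, conv_fwd, x = x, train = train)
  cat_ <- if (length(bs) > 1) cn_concat_channels(bs) else bs[[1]]
  f <- conv_fwd(e$proj, cat_, train = train)
  if (e$use_se) f <- se_fwd(e$se, f, train = train)
  if (train) e$cache$nbranch <- length(bs)
  if (e$use_skip) x + f else f
}

resblock_bwd <- function(e, dy) {
  df <- dy  # gradient through the residual branch
  if (e$use_se) df <- se_bwd(e$se, df)
  dcat <- conv_bwd(e$proj, df)
  nb <- e$cache$nbranch
  parts <- if (nb > 1) cn_split_channels(dcat, nb) else list(dcat)
  dx <- if (e$use_skip) dy else array(0, dim(dy))
  for (i in seq_len(nb))
    dx <- dx + conv_bwd(e$branches[[i]], parts[[i]])
  dx
}

# ---- spatial pyramid pooling -----------------------------------------------

spp_env <- function(levels = c(1L, 2L, 4L)) {
  e <- new_component("spp")
  e$levels <- as.integer(levels)
  e$n_tokens <- sum(e$levels^2)
  e
}

spp_fwd <- function(e, x, train = FALSE) {
  out <- cn_spp_forward(x, e$levels)
  if (train) { e$cache$idx <- out$idx; e$cache$xdim <- dim(x) }
  out$tokens
}

spp_bwd <- function(e, dtok) cn_spp_backward(dtok, e$cache$idx, e$cache$xdim)

# ---- dense -----------------------------------------------------------------

dense_env <- function(nin, nout, act = c("linear", "relu")) {
  e <- new_component("dense")
  e$act <- match.arg(act)
  w <- if (e$act == "relu") init_he(c(nin, nout), nin)
       else init_glorot(c(nin, nout), nin, nout)
  e$params <- list(w = w, b = numeric(nout))
  zero_grads(e)
}

dense_fwd <- function(e, x, train = FALSE) {
  y <- x %*% e$params$w + rep(e$params$b, each = nrow(x))
  if (e$act == "relu") {
    if (train) e$cache$mask <- y > 0
    y <- relu(y)
  }
  if (train) e$cache$x <- x
  y
}

dense_bwd <- function(e, dy) {
  if (e$act == "relu") dy <- dy * e$cache$mask
  e$grads$w <- e$grads$w + crossprod(e$cache$x, dy)
  e$grads$b <- e$grads$b + colSums(dy)
  dy %*% t(e$params$w)
}

# ---- layer normalization ---------------------------------------------------

ln_env <- function(d, eps = 1e-5) {
  e <- new_component("layernorm")
  e$eps <- eps
  e$params <- list(gamma = rep(1, d), beta = numeric(d))
  zero_grads(e)
}

ln_fwd <- function(e, x, train = FALSE) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc^2) + e$eps)
  xhat <- xc / sd_
  if (train) e$cache <- list(xhat = xhat, sd = sd_)
  xhat * rep(e$params$gamma, each = nrow(x)) + rep(e$params$beta, each = nrow(x))
}

ln_bwd <- function(e, dy) {
  xhat <- e$cache$xhat
  e$grads$gamma <- e$grads$gamma + colSums(dy * xhat)
  e$grads$beta <- e$grads$beta + colSums(dy)
  dxhat <- dy * rep(e$params$gamma, each = nrow(dy))
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / e$cache$sd
}

# ---- multi-head self-attention ---------------------------------------------

mha_env <- function(d_model, n_heads) {
  e <- new_component("mha")
  e$n_heads <- as.integer(n_heads)
  e$d_head <- d_model %/% n_heads
  if (e$d_head * n_heads != d_model)
    stop("mha: d_model ", d_model, " not divisible by ", n_heads, " heads")
  mk <- function() init_glorot(c(d_model, d_model), d_model, d_model)
  e$params <- list(wq = mk(), wk = mk(), wv = mk(), wo = mk(),
                   bq = numeric(d_model), bk = numeric(d_model),
                   bv = numeric(d_model), bo = numeric(d_model))
  zero_grads(e)
}

softmax_rows <- function(s) {
  s <- exp(s - apply(s, 1, max))
  s / rowSums(s)
}

mha_fwd <- function(e, x, n_tok, train = FALSE) {
  p <- e$params
  out <- cn_mha_forward(x, p$wq, p$wk, p$wv, p$wo, p$bq, p$bk, p$bv, p$bo,
                        n_tok, e$n_heads)
  if (train) e$cache <- c(out[c("q", "k", "v", "o", "attn")],
                          list(x = x, n_tok = n_tok))
  out$y
}

mha_bwd <- function(e, dy) {
  cc <- e$cache; p <- e$params
  g <- cn_mha_backward(cc$x, p$wq, p$wk, p$wv, p$wo, cc$q, cc$k, cc$v, cc$o,
                       cc$attn, dy, cc$n_tok, e$n_heads)
  for (nm in c("wq", "wk", "wv", "wo", "bq", "bk", "bv", "bo"))
    e$grads[[nm]] <- e$grads[[nm]] + as.numeric(g[[paste0("d", nm)]])
  g$dx
}

# ---- transformer encoder (post-norm) ---------------------------------------

encoder_layer_env <- function(d_model, n_heads, ff_dim) {
  e <- new_component("encoder_layer")
  e$mha <- mha_env(d_model, n_heads)
  e$ln1 <- ln_env(d_model)
  e$ff1 <- dense_env(d_model, ff_dim, act = "relu")
  e$ff2 <- dense_env(ff_dim, d_model, act = "linear")
  e$ln2 <- ln_env(d_model)
  e
}

encoder_layer_fwd <- function(e, x, n_tok, train = FALSE) {
  a <- mha_fwd(e$mha, x, n_tok, train = train)
  x1 <- ln_fwd(e$ln1, x + a, train = train)
  f <- dense_fwd(e$ff2, dense_fwd(e$ff1, x1, train = train), train = train)
  ln_fwd(e$ln2, x1 + f, train = train)
}

encoder_layer_bwd <- function(e, dy) {
  d2 <- ln_bwd(e$ln2, dy)
  dx1 <- d2 + dense_bwd(e$ff1, dense_bwd(e$ff2, d2))
  d1 <- ln_bwd(e$ln1, dx1)
  d1 + mha_bwd(e$mha, d1)
}

# A stack: optional input projection to the stack's model dimension, then
# n_layers encoder layers.
encoder_stack_env <- function(d_in, head_size, n_heads, ff_dim, n_layers) {
  e <- new_component("encoder_stack")
  d_model <- head_size * n_heads
  e$d_model <- d_model
  e$proj <- if (d_in != d_model) dense_env(d_in, d_model, act = "linear") else NULL
  e$layers <- lapply(seq_len(n_layers), function(i)
    encoder_layer_env(d_model, n_heads, ff_dim))
  e
}

encoder_stack_fwd <- function(e, x, n_tok, train = FALSE) {
  if (!is.null(e$proj)) x <- dense_fwd(e$proj, x, train = train)
  for (l in e$layers) x <- encoder_layer_fwd(l, x, n_tok, train = train)
  x
}

encoder_stack_bwd <- function(e, dy) {
  for (l in rev(e$layers)) dy <- encoder_layer_bwd(l, dy)
  if (!is.null(e$proj)) dy <- dense_bwd(e$proj, dy)
  dy
}

# ---- parameter traversal ---------------------------------------------------

# Flat list of every parameter-holding environment inside a component tree.
collect_param_envs <- function(e) {
  if (is.null(e)) return(list())
  if (is.list(e) && !is.environment(e)) return(do.call(c, lapply(e, collect_param_envs)))
  out <- if (length(e$params)) list(e) else list()
  for (f in c("branches", "proj", "se", "mha", "ln1", "ff1", "ff2", "ln2", "layers"))
    if (!is.null(e[[f]])) out <- c(out, collect_param_envs(e[[f]]))
  out
}
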