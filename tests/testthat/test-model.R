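test_that("se_squeeze is the spatial mean per channel", {
  map <- array(0, c(2, 2, 3))
  map[, , 1] <- 7
  map[, , 2] <- matrix(c(1, 3, 2, 4), 2)   # [1,2;3,4]
  map[, , 3] <- c(0, 0, 0, 8)
  z <- se_squeeze(map)
  expect_equal(z, c(7, 2.5, 2))
  one <- array(c(5, -2), c(1, 1, 2))
  expect_equal(se_squeeze(one), c(5, -2))   # 1x1 map is the identity
})

test_that("se_excite is a sigmoid bottleneck gate strictly inside (0,1)", {
  z <- c(1, -2)
  expect_equal(se_excite(z, matrix(0, 1, 2), matrix(0, 2, 1)), c(0.5, 0.5))
  w1 <- matrix(c(0.5, -0.25), 1, 2)         # C = 2, r = 2
  w2 <- matrix(c(2, -1), 2, 1)
  # by hand: relu(0.5*1 - 0.25*(-2)) = 1; sigmoid(c(2, -1))
  expect_equal(se_excite(z, w1, w2), 1 / (1 + exp(-c(2, -1))))
  set.seed(3)
  for (i in 1:20) {
    s <- se_excite(rnorm(4), matrix(rnorm(8), 2, 4), matrix(rnorm(8), 4, 2))
    expect_true(all(s > 0 & s < 1))
  }
  expect_error(se_excite(z, matrix(0, 1, 3), matrix(0, 2, 1)), "shapes")
})

test_that("se_reweight rescales channels by their gates", {
  map <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  expect_equal(se_reweight(map, rep(1, 4)), map)
  expect_equal(se_reweight(map, rep(0, 4)), map * 0)
  single <- array(runif(6), c(2, 3, 1))
  expect_equal(se_reweight(single, 0.5), single / 2)
  expect_error(se_reweight(map, c(1, 1)), "gate length")
})

test_that("the residual block is the identity under zero branch weights", {
  for (use_se in c(TRUE, FALSE)) {
    blk <- crynet:::resblock_env(4L, use_se = use_se, use_skip = TRUE,
                                 multiscale = TRUE, reduction = 2L)
    for (e in crynet:::collect_param_envs(blk)) {
      if (identical(e, blk$se)) next     # gate weights may stay arbitrary
      e$params <- lapply(e$params, function(p) p * 0)
    }
    x <- array(rnorm(5 * 6 * 4 * 2), c(5, 6, 4, 2))
    expect_identical(crynet:::resblock_fwd(blk, x), x)
  }
  # skip off, everything zero, SE off: output collapses to zero
  blk <- crynet:::resblock_env(4L, use_se = FALSE, use_skip = FALSE,
                               multiscale = TRUE, reduction = 2L)
  for (e in crynet:::collect_param_envs(blk))
    e$params <- lapply(e$params, function(p) p * 0)
  x <- array(rnorm(5 * 6 * 4 * 2), c(5, 6, 4, 2))
  expect_equal(crynet:::resblock_fwd(blk, x), x * 0)
})

test_that("the multiscale branch preserves spatial size and composes convs", {
  blk <- crynet:::resblock_env(3L, use_se = FALSE, use_skip = FALSE,
                               multiscale = TRUE, reduction = 1L)
  x <- array(rnorm(8 * 9 * 3 * 2), c(8, 9, 3, 2))
  y <- crynet:::resblock_fwd(blk, x)
  expect_equal(dim(y), dim(x))   # same-padding at every kernel size

  # single-pixel input with only center taps set behaves like a 1x1 conv
  blk1 <- crynet:::resblock_env(2L, use_se = FALSE, use_skip = FALSE,
                                multiscale = TRUE, reduction = 1L)
  ks <- c(3L, 5L, 7L)
  A <- matrix(c(1, 0.5, -1, 2), 2)          # per-branch center-tap matrix
  for (i in 1:3) {
    w <- array(0, dim(blk1$branches[[i]]$params$w))
    ctr <- (ks[i] + 1) %/% 2
    w[ctr, ctr, , ] <- A
    blk1$branches[[i]]$params$w <- w
    blk1$branches[[i]]$params$b <- c(0, 0)
  }
  P <- matrix(rnorm(12), 6, 2)               # 1x1 projection, 6 -> 2
  blk1$proj$params$w <- array(P, dim(blk1$proj$params$w))
  blk1$proj$params$b <- c(0, 0)
  v <- c(0.3, -0.8)
  x1 <- array(v, c(1, 1, 2, 1))
  y1 <- crynet:::resblock_fwd(blk1, x1)
  relu <- function(a) pmax(a, 0)
  expect_equal(as.numeric(y1), as.numeric(rep(relu(t(A) %*% v), 3) %*% P),
               tolerance = 1e-6)
})

test_that("spatial pyramid pooling emits level-major max tokens", {
  const <- array(2.5, c(6, 8, 3))
  tok <- spatial_pyramid_pool(const, c(1, 2, 4))
  expect_equal(dim(tok), c(21L, 3L))
  expect_true(all(tok == 2.5))

  map <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  g <- spatial_pyramid_pool(map, 1L)
  expect_equal(as.numeric(g), apply(map, 3, max))

  hot <- array(0, c(4, 4, 1))
  hot[1, 1, 1] <- 9
  tok <- spatial_pyramid_pool(hot, c(1, 2, 4))
  expect_equal(tok[1, 1], 9)    # global cell
  expect_equal(tok[2, 1], 9)    # level-2 cell (1,1)
  expect_equal(tok[6, 1], 9)    # level-4 cell (1,1) is the pixel itself
  expect_equal(sum(tok == 9), 3)

  expect_error(spatial_pyramid_pool(array(0, c(3, 3, 1)), c(1, 2, 4)),
               "smaller")
})

test_that("attention weights are row-stochastic and keep sequence length", {
  set.seed(8)
  d <- 6L; n_tok <- 5L
  e <- crynet:::mha_env(d, 2L)
  x <- matrix(rnorm(2 * n_tok * d), 2 * n_tok, d)
  y <- crynet:::mha_fwd(e, x, n_tok, train = TRUE)
  expect_equal(dim(y), dim(x))
  a <- e$cache$attn                       # n_tok x n_tok x (heads*items)
  expect_equal(apply(a, 3, rowSums), matrix(1, n_tok, 4))
  expect_true(all(a >= 0))
})

test_that("a single token attends only to itself", {
  set.seed(9)
  d <- 4L
  e <- crynet:::mha_env(d, 2L)
  x <- matrix(rnorm(d), 1, d)
  y <- crynet:::mha_fwd(e, x, 1L)
  p <- e$params
  v <- x %*% p$wv + p$bv                  # attention = 1 on the lone token
  expect_equal(y, v %*% p$wo + p$bo)
})

test_that("encoder stacks preserve token count and project dimensions", {
  set.seed(10)
  st <- crynet:::encoder_stack_env(6L, 4L, 2L, 16L, 2L)
  x <- matrix(rnorm(3 * 7 * 6), 21, 6)
  y <- crynet:::encoder_stack_fwd(st, x, 7L)
  expect_equal(dim(y), c(21L, 8L))        # 7 tokens/item, d_model = 8
})

test_that("the full model outputs a probability simplex, deterministically", {
  m <- build_model(tiny_model_config())
  x <- array(rnorm(20 * 16 * 4), c(20, 16, 4))
  p <- predict(m, x)
  expect_equal(dim(p), c(4L, 3L))
  expect_true(all(p > 0 & p < 1))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_identical(predict(m, x), p)
  # single matrix input works too
  p1 <- predict(m, x[, , 2])
  expect_equal(as.numeric(p1), as.numeric(p[2, ]), tolerance = 1e-5)
})

test_that("building twice with one seed gives identical weights", {
  m1 <- build_model(tiny_model_config())
  m2 <- build_model(tiny_model_config())
  e1 <- crynet:::model_param_envs(m1)
  e2 <- crynet:::model_param_envs(m2)
  expect_identical(lapply(e1, function(e) e$params),
                   lapply(e2, function(e) e$params))
})

test_that("the default parameter count matches an independent tally", {
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  dense_p <- function(nin, nout) nin * nout + nout
  enc_layer <- function(d, ff) 4 * dense_p(d, d) + 2 * (2 * d) +
    dense_p(d, ff) + dense_p(ff, d)
  tally <- conv_p(7, 1, 64) +                                  # stem
    conv_p(3, 64, 64) + conv_p(5, 64, 64) + conv_p(7, 64, 64) +
    conv_p(1, 192, 64) +                                       # projection
    (64 / 16) * 64 + 64 * (64 / 16) +                          # SE gate
    2 * enc_layer(64, 32) +                                    # stack 1 (64 in)
    dense_p(64, 256) + 2 * enc_layer(256, 64) +                # stack 2
    dense_p(256, 512) + 2 * enc_layer(512, 128) +              # stack 3
    dense_p(512, 1000) + dense_p(1000, 3)                      # head
  m <- build_model(model_config())
  expect_equal(n_params(m), tally)
  expect_equal(n_params(m), 4025955)      # frozen regression value
})

test_that("all ablation variants build and emit valid simplex outputs", {
  x <- array(rnorm(20 * 16 * 2), c(20, 16, 2))
  for (v in names(ablation_variants())) {
    cfg <- do.call(model_config,
                   modifyList(unclass(tiny_model_config()),
                              ablation_variants()[[v]]))
    m <- build_model(cfg)
    p <- predict(m, x)
    expect_true(all(p > 0 & p < 1), info = v)
    expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6, info = v)
  }
})

test_that("checkpoints and architecture dumps round-trip exactly", {
  m <- build_model(tiny_model_config())
  x <- array(rnorm(20 * 16 * 2), c(20, 16, 2))
  p <- predict(m, x)
  ckpt <- withr::local_tempfile(fileext = ".rds")
  save_model(m, ckpt)
  m2 <- load_model(ckpt)
  expect_identical(predict(m2, x), p)
  arch <- withr::local_tempfile(fileext = ".json")
  save_architecture(m, arch)
  cfg <- do.call(model_config, jsonlite::read_json(arch, simplifyVector = TRUE))
  expect_equal(cfg, m$config)
})

test_that("analytic gradients match finite differences layer by layer", {
  set.seed(14)
  # dense + layernorm + attention in double precision: tight tolerance
  check_env <- function(e, fwd, bwd, x, tol = 1e-6) {
    crynet:::zero_grads(e)
    y <- fwd(x, TRUE)
    dy <- matrix(rnorm(length(y)), nrow(y))
    bwd(dy)
    loss <- function() sum(fwd(x, FALSE) * dy)
    for (pn in names(e$params)) {
      np <- length(e$params[[pn]])
      for (j in unique(round(seq(1, np, length.out = 4)))) {
        eps <- 1e-6
        orig <- e$params[[pn]][j]
        e$params[[pn]][j] <- orig + eps; lp <- loss()
        e$params[[pn]][j] <- orig - eps; lm <- loss()
        e$params[[pn]][j] <- orig
        expect_equal(e$grads[[pn]][j], (lp - lm) / (2 * eps), tolerance = tol,
                     info = paste(e$type, pn, j))
      }
    }
  }
  de <- crynet:::dense_env(5L, 4L, act = "relu")
  check_env(de, function(x, t) crynet:::dense_fwd(de, x, t),
            function(dy) crynet:::dense_bwd(de, dy), matrix(rnorm(15), 3, 5))
  le <- crynet:::ln_env(6L)
  le$params$gamma <- runif(6, 0.5, 1.5); le$params$beta <- rnorm(6)
  check_env(le, function(x, t) crynet:::ln_fwd(le, x, t),
            function(dy) crynet:::ln_bwd(le, dy), matrix(rnorm(24), 4, 6))
  me <- crynet:::mha_env(6L, 2L)
  check_env(me, function(x, t) crynet:::mha_fwd(me, x, 3L, t),
            function(dy) crynet:::mha_bwd(me, dy), matrix(rnorm(36), 6, 6),
            tol = 1e-5)
  se <- crynet:::se_env(4L, 2L)
  xs <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  crynet:::zero_grads(se)
  ys <- crynet:::se_fwd(se, xs, TRUE)
  dys <- array(rnorm(length(ys)), dim(ys))
  crynet:::se_bwd(se, dys)
  loss_se <- function() sum(crynet:::se_fwd(se, xs, FALSE) * dys)
  for (pn in c("w1", "w2")) {
    for (j in 1:3) {
      eps <- 1e-6
      orig <- se$params[[pn]][j]
      se$params[[pn]][j] <- orig + eps; lp <- loss_se()
      se$params[[pn]][j] <- orig - eps; lm <- loss_se()
      se$params[[pn]][j] <- orig
      expect_equal(se$grads[[pn]][j], (lp - lm) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("end-to-end gradients agree with finite differences", {
  # the convolution path runs in single precision, so compare only where the
  # gradient signal clears the float noise floor, at a matching tolerance
  set.seed(15)
  m <- build_model(tiny_model_config())
  x <- array(rnorm(20 * 16 * 3), c(20, 16, 1, 3))
  y <- crynet:::one_hot(c("hungry", "pain", "uncomfortable"), cry_classes())
  envs <- crynet:::model_param_envs(m)
  for (e in envs) crynet:::zero_grads(e)
  p <- crynet:::softmax_probs(crynet:::model_forward(m, x, train = TRUE))
  crynet:::model_backward(m, p - y)
  loss <- function() {
    pp <- crynet:::softmax_probs(crynet:::model_forward(m, x, train = FALSE))
    -sum(log(rowSums(pp * y)))
  }
  checked <- 0L
  for (e in envs) {
    for (pn in names(e$params)) {
      np <- length(e$params[[pn]])
      for (j in unique(round(seq(1, np, length.out = 3)))) {
        eps <- 1e-3
        orig <- e$params[[pn]][j]
        e$params[[pn]][j] <- orig + eps; lp <- loss()
        e$params[[pn]][j] <- orig - eps; lm <- loss()
        e$params[[pn]][j] <- orig
        num <- (lp - lm) / (2 * eps)
        ana <- e$grads[[pn]][j]
        if (abs(num) + abs(ana) > 1e-2) {
          checked <- checked + 1L
          expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 0.05)
        }
      }
    }
  }
  expect_gt(checked, 50L)
})
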