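#' Training configuration
#'
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param seed Seed controlling data order; training twice with one seed on
#'   one machine gives identical weights.
#' @param verbose Print one line per epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 64L, learning_rate = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         seed = 1L, verbose = FALSE) {
  if (epochs < 1) stop("train_config: epochs must be >= 1")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Stratified train/test split
#'
#' Per class, `round(test_fraction * n_class)` items are drawn (seeded) for
#' the test set, so each class's test share is within one item of the target
#' fraction; without stratification the draw is over the whole set. The same
#' seed always produces the same membership.
#'
#' @param labels Character vector of class labels, one per item.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Split seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return A list with integer index vectors `train` and `test` forming a
#'   partition of `seq_along(labels)`.
#' @export
split_dataset <- function(labels, test_fraction = 0.2, seed = 1L,
                          stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("split_dataset: test_fraction must be in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(labels)
  if (stratified) {
    if (any(table(labels) < 1)) stop("split_dataset: empty class")
    test <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_test <- round(test_fraction * length(idx))
      test <- c(test, sort(sample(idx, n_test)))
    }
    test <- sort(test)
  } else {
    test <- sort(sample(n, round(test_fraction * n)))
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

one_hot <- function(y, classes) {
  m <- matrix(0, length(y), length(classes))
  m[cbind(seq_along(y), match(y, classes))] <- 1
  m
}

#' Train a model
#'
#' Minimizes categorical cross-entropy by mini-batch Adam. Fully seeded:
#' the shuffling order derives from `config$seed` and the initial weights
#' from the model's own seed, so a rebuild-and-retrain with the same seeds
#' reproduces the run.
#'
#' @param model A `crynet_model` from [build_model()]; updated in place and
#'   returned.
#' @param x Feature array `H x W x N` (e.g. from [extract_features()]).
#' @param y Character vector of `N` class labels.
#' @param config A [train_config()].
#' @param classes Class order used for the output units.
#' @return The trained model, with a `history` data frame (per-epoch train
#'   loss and accuracy) attached as `model$history`.
#' @export
train_model <- function(model, x, y, config = train_config(),
                        classes = cry_classes()) {
  stopifnot(inherits(model, "crynet_model"), inherits(config, "train_config"))
  n <- dim(x)[3]
  if (n == 0 || length(y) != n)
    stop("train_model: need a non-empty training set with one label per item")
  if (!all(y %in% classes))
    stop("train_model: labels outside the class set: ",
         paste(setdiff(unique(y), classes), collapse = ", "))
  targets <- one_hot(y, classes)

  envs <- model_param_envs(model)
  adam <- lapply(envs, function(e)
    lapply(e$params, function(p) list(m = p * 0, v = p * 0)))
  step <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  history <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  d <- dim(x)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      xb <- array(x[, , idx], c(d[1], d[2], 1L, length(idx)))
      yb <- targets[idx, , drop = FALSE]
      for (e in envs) zero_grads(e)
      logits <- model_forward(model, xb, train = TRUE)
      probs <- softmax_probs(logits)
      eps <- 1e-12
      ep_loss <- ep_loss - sum(log(pmax(rowSums(probs * yb), eps)))
      ep_correct <- ep_correct +
        sum(max.col(probs, ties.method = "first") == max.col(yb, ties.method = "first"))
      model_backward(model, (probs - yb) / length(idx))
      step <- step + 1L
      for (i in seq_along(envs)) {
        e <- envs[[i]]
        for (pn in names(e$params)) {
          st <- adam[[i]][[pn]]
          g <- e$grads[[pn]]
          st$m <- config$beta1 * st$m + (1 - config$beta1) * g
          st$v <- config$beta2 * st$v + (1 - config$beta2) * g^2
          mhat <- st$m / (1 - config$beta1^step)
          vhat <- st$v / (1 - config$beta2^step)
          e$params[[pn]] <- e$params[[pn]] -
            config$learning_rate * mhat / (sqrt(vhat) + config$epsilon)
          adam[[i]][[pn]] <- st
        }
        e$cache <- list()
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / n,
                                         accuracy = ep_correct / n))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch,
                      ep_loss / n, ep_correct / n))
  }
  model$history <- history
  model
}

# ---- metrics ---------------------------------------------------------------

#' Confusion matrix
#'
#' @param true,pred Character vectors of true and predicted labels.
#' @param classes Class order of the rows/columns.
#' @return An `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(true, pred, classes = sort(unique(c(true, pred)))) {
  if (length(true) != length(pred))
    stop("confusion_matrix: length mismatch")
  m <- table(factor(true, levels = classes), factor(pred, levels = classes))
  cm <- matrix(as.integer(m), length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  cm
}

#' Evaluation report with macro-averaged metrics
#'
#' Per-class precision, recall and F1 are computed from one-vs-rest
#' reductions of the confusion matrix; macro metrics are their unweighted
#' means (insensitive to class frequency) and accuracy is the fraction of
#' correct predictions. A class that is never predicted (or never occurs)
#' gets precision (or recall) 0, and F1 is 0 when precision + recall = 0.
#'
#' @param true,pred Character vectors of true and predicted labels.
#' @param classes Class order.
#' @return A list of class `eval_report`: `confusion`, `per_class` (data
#'   frame with precision/recall/f1 per class), `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `n`.
#' @export
eval_report <- function(true, pred, classes = sort(unique(c(true, pred)))) {
  cm <- confusion_matrix(true, pred, classes)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    confusion = cm,
    per_class = data.frame(class = classes, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           row.names = NULL),
    accuracy = sum(tp) / sum(cm),
    macro_precision = mean(prec), macro_recall = mean(rec),
    macro_f1 = mean(f1), n = sum(cm)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.4f\n", x$n, x$accuracy))
  cat(sprintf("  macro precision %.4f, recall %.4f, F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Save an evaluation report as JSON
#'
#' @param report An [eval_report()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
save_eval_report <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              macro_precision = report$macro_precision,
              macro_recall = report$macro_recall,
              macro_f1 = report$macro_f1,
              per_class = report$per_class,
              confusion = as.data.frame.matrix(report$confusion), n = report$n)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Evaluate a model on labeled features
#'
#' @param model A trained `crynet_model`.
#' @param x Feature array `H x W x N`.
#' @param y Character vector of true labels.
#' @param classes Class order.
#' @return An [eval_report()].
#' @export
evaluate_model <- function(model, x, y, classes = cry_classes()) {
  if (dim(x)[3] == 0) stop("evaluate_model: empty test set")
  probs <- predict(model, x)
  pred <- classes[max.col(probs, ties.method = "first")]
  eval_report(y, pred, classes)
}

# ---- ablation harness ------------------------------------------------------

#' Ablation variants of the architecture
#'
#' The named switch settings behind [ablate()]: the four
#' attention/residual variants (SE and skip on/off, all multiscale), the
#' ordinary-convolution variant, and the three single-stack encoder
#' variants.
#'
#' @return Named list of [model_config()] argument lists.
#' @export
ablation_variants <- function() {
  stacks <- list(c(16L, 4L, 32L, 2L), c(32L, 8L, 64L, 2L), c(64L, 8L, 128L, 2L))
  list(
    se_resnet_transformer = list(use_se = TRUE, use_skip = TRUE, multiscale = TRUE),
    resnet_transformer = list(use_se = FALSE, use_skip = TRUE, multiscale = TRUE),
    se_conv_transformer = list(use_se = TRUE, use_skip = FALSE, multiscale = TRUE),
    conv_transformer = list(use_se = FALSE, use_skip = FALSE, multiscale = TRUE),
    se_resnet_transformer_ordinary = list(use_se = TRUE, use_skip = TRUE,
                                          multiscale = FALSE),
    transformer_1 = list(transformer_stacks = stacks[1]),
    transformer_2 = list(transformer_stacks = stacks[2]),
    transformer_3 = list(transformer_stacks = stacks[3])
  )
}

#' Run the ablation study
#'
#' Trains and evaluates each requested architecture variant under identical
#' data split, seeds and hyperparameters, and consolidates the
#' macro-averaged results into one table.
#'
#' @param x Feature array `H x W x N` for the full dataset.
#' @param y Character vector of labels.
#' @param variants Character vector of variant names from
#'   [ablation_variants()].
#' @param base_config A [model_config()] whose fields the variant switches
#'   override.
#' @param train_cfg A [train_config()].
#' @param split A split from [split_dataset()]; by default an 80/20
#'   stratified split with the training seed.
#' @param classes Class order.
#' @return A data frame of class `ablation_report` with one row per variant
#'   (accuracy, macro precision/recall/F1, parameter count) and the full
#'   [eval_report()]s attached as attribute `reports`.
#' @export
ablate <- function(x, y, variants = names(ablation_variants()),
                   base_config = model_config(), train_cfg = train_config(),
                   split = split_dataset(y, 0.2, train_cfg$seed),
                   classes = cry_classes()) {
  defs <- ablation_variants()
  unknown <- setdiff(variants, names(defs))
  if (length(unknown))
    stop("ablate: unknown variant(s): ", paste(unknown, collapse = ", "))
  d <- dim(x)
  xtr <- x[, , split$train, drop = FALSE]
  xte <- x[, , split$test, drop = FALSE]
  reports <- list()
  rows <- list()
  for (v in variants) {
    cfg <- do.call(model_config, modifyList(unclass(base_config), defs[[v]]))
    model <- build_model(cfg)
    model <- train_model(model, xtr, y[split$train], train_cfg, classes)
    rep_ <- evaluate_model(model, xte, y[split$test], classes)
    reports[[v]] <- rep_
    rows[[v]] <- data.frame(variant = v, accuracy = rep_$accuracy,
                            macro_precision = rep_$macro_precision,
                            macro_recall = rep_$macro_recall,
                            macro_f1 = rep_$macro_f1,
                            parameters = n_params(model))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  class(out) <- c("ablation_report", "data.frame")
  out
}
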