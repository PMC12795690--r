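#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Pairs per minibatch.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience in epochs without validation
#'   loss improvement (must be `<= max_epochs`).
#' @param decision_threshold Threshold for the thresholded metrics.
#' @param rng_seed Seed controlling shuffling, dropout and initialisation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         max_epochs = 80L, patience = 15L,
                         decision_threshold = 0.5, rng_seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience <= max_epochs,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 loss = "binary_cross_entropy",
                 decision_threshold = decision_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

eval_loss <- function(params, cfg, pack) {
  p <- pmin(pmax(nn_forward(params, cfg, pack)$prob, 1e-12), 1 - 1e-12)
  -mean(pack$y * log(p) + (1 - pack$y) * log(1 - p))
}

#' Train a PT-PPI model
#'
#' Adam optimisation of binary cross-entropy with per-epoch validation and
#' early stopping: training stops when the validation loss has not
#' improved for `patience` consecutive epochs (or at `max_epochs`), and the
#' weights from the best validation epoch are returned. Fully seeded: the
#' same data and seeds reproduce the loss history exactly.
#'
#' @param train_pairs List of `pair_sample`s used for gradient steps; both
#'   classes must be present.
#' @param val_pairs List of `pair_sample`s used for early stopping.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print one line per epoch?
#' @return Object of class `ptppi_model` with fields `params`,
#'   `model_config`, `train_config`, `history` (per-epoch data frame),
#'   `best_epoch`.
#' @export
ptppi_train <- function(train_pairs, val_pairs, model_cfg = model_config(),
                        train_cfg = train_config(), verbose = FALSE) {
  y <- vapply(train_pairs, function(p) p$label, numeric(1))
  if (length(unique(y)) < 2)
    stop_ptppi("ptppi_training_setup",
               "training set must contain both classes")
  if (!length(val_pairs)) stop_ptppi("ptppi_training_setup",
                                     "empty validation set")

  set.seed(train_cfg$rng_seed)
  mc <- model_cfg
  mc$rng_seed <- derive_seed(train_cfg$rng_seed, mc$rng_seed)
  params <- init_ptppi_params(mc)
  state <- adam_init(params)
  val_pack <- pack_pairs(val_pairs)

  n <- length(train_pairs)
  bs <- min(train_cfg$batch_size, n)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  since_best <- 0L

  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      pack <- pack_pairs(train_pairs[idx])
      lg <- nn_loss_grad(params, mc, pack, train = TRUE)
      upd <- adam_step(params, lg$grads, state, train_cfg$learning_rate)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, lg$loss)
    }
    vl <- eval_loss(params, mc, val_pack)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = vl))
    if (verbose)
      cat(sprintf("epoch %3d  train %.4f  val %.4f\n", epoch, mean(losses), vl))
    if (vl < best_val - 1e-9) {
      best_val <- vl
      best_params <- params
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= train_cfg$patience) break
    }
  }
  structure(list(params = best_params, model_config = mc,
                 train_config = train_cfg, history = history,
                 best_epoch = best_epoch, best_val_loss = best_val),
            class = "ptppi_model")
}

#' @export
print.ptppi_model <- function(x, ...) {
  cfg <- x$model_config
  cat(sprintf(paste0("<ptppi_model> H=%d, %s, pos.enc=%s, sequence=%s | ",
                     "trained %d epochs (best %d, val loss %.4f)\n"),
              cfg$hidden_dim,
              if (cfg$use_pt_block)
                sprintf("%d PT layer(s)", cfg$num_pt_layers)
              else "MLP block",
              cfg$use_positional_encoder, cfg$use_sequence,
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.ptppi_model <- function(object, ...) {
  np <- sum(vapply(object$params, length, numeric(1)))
  cat("PT-PPI interaction classifier\n")
  print(object)
  cat(sprintf("  parameters: %d\n", np))
  cat(sprintf("  final train loss: %.4f | best val loss: %.4f\n",
              utils::tail(object$history$train_loss, 1), object$best_val_loss))
  invisible(object)
}

#' @export
coef.ptppi_model <- function(object, ...) object$params

#' @export
plot.ptppi_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Predict interaction probabilities
#'
#' @param object A fitted [ptppi_train()] model.
#' @param newdata List of `pair_sample`s.
#' @param type `"prob"` for probabilities, `"class"` for thresholded 0/1.
#' @param chunk_size Pairs per forward chunk.
#' @param ... Unused.
#' @return Numeric vector (probabilities or class labels), named by pair
#'   id.
#' @export
predict.ptppi_model <- function(object, newdata, type = c("prob", "class"),
                                chunk_size = 64L, ...) {
  type <- match.arg(type)
  probs <- numeric(0)
  ids <- character(0)
  for (start in seq(1, length(newdata), by = chunk_size)) {
    sl <- newdata[start:min(start + chunk_size - 1, length(newdata))]
    pack <- pack_pairs(sl)
    probs <- c(probs, nn_forward(object$params, object$model_config,
                                 pack)$prob)
    ids <- c(ids, pack$ids)
  }
  names(probs) <- ids
  if (type == "class")
    return(setNames(as.integer(probs >= object$train_config$decision_threshold),
                    ids))
  probs
}

#' Evaluate a model on a labelled test set
#'
#' @param model A fitted `ptppi_model`.
#' @param test_pairs List of labelled `pair_sample`s.
#' @param threshold Decision threshold (defaults to the training
#'   configuration's).
#' @return A [compute_metrics()] record.
#' @export
evaluate_pairs <- function(model, test_pairs, threshold = NULL) {
  if (!length(test_pairs)) stop_ptppi("ptppi_parameter_error",
                                      "empty test set")
  threshold <- threshold %||% model$train_config$decision_threshold
  probs <- predict(model, test_pairs)
  labels <- vapply(test_pairs, function(p) p$label, numeric(1))
  compute_metrics(probs, labels, threshold)
}

#' k-fold cross-validation
#'
#' Trains on `k - 1` folds and evaluates the held-out fold (which also
#' serves as the early-stopping validation set), for each fold in turn.
#'
#' @param pairs Labelled `pair_sample`s.
#' @param k Number of folds.
#' @param seed Seed controlling the fold assignment and (offset per fold)
#'   the training runs.
#' @param model_cfg,train_cfg Configurations.
#' @return List with `folds` (per-fold `metrics_record`s), `table`
#'   (per-fold data frame) and `summary` (mean and sd per metric).
#' @export
cross_validate <- function(pairs, k = 3L, seed = 1L,
                           model_cfg = model_config(),
                           train_cfg = train_config()) {
  folds <- make_splits(pairs, k = k, seed = seed)
  records <- vector("list", k)
  rows <- list()
  for (f in seq_len(k)) {
    tr <- pairs[folds != f]
    te <- pairs[folds == f]
    tc <- train_cfg
    tc$rng_seed <- derive_seed(seed, f, salt = 101L)
    model <- ptppi_train(tr, te, model_cfg, tc)
    records[[f]] <- evaluate_pairs(model, te)
    rows[[f]] <- data.frame(fold = f, seed = tc$rng_seed,
                            accuracy = records[[f]]$accuracy,
                            precision = records[[f]]$precision,
                            recall = records[[f]]$recall,
                            f1 = records[[f]]$f1,
                            auroc = records[[f]]$auroc,
                            auprc = records[[f]]$auprc)
  }
  tab <- do.call(rbind, rows)
  metrics <- c("accuracy", "precision", "recall", "f1", "auroc", "auprc")
  summ <- data.frame(metric = metrics,
                     mean = vapply(metrics, function(m) mean(tab[[m]]),
                                   numeric(1)),
                     sd = vapply(metrics, function(m) sd(tab[[m]]),
                                 numeric(1)))
  list(folds = records, table = tab, summary = summ)
}

#' Run an ablation grid
#'
#' Evaluates one model per grid row; rows may set `use_sequence`,
#' `use_positional_encoder`, `use_pt_block` and `num_pt_layers`. The
#' returned table labels the block as `"mlp"` when the transformer stack is
#' ablated. Reruns with identical seeds reproduce the table exactly.
#'
#' @param train_pairs,val_pairs,test_pairs Labelled `pair_sample`s.
#' @param grid Data frame of configuration overrides (one row per run).
#' @param model_cfg,train_cfg Base configurations.
#' @return Data frame: one row per configuration with its test metrics.
#' @export
run_ablation <- function(train_pairs, val_pairs, test_pairs, grid,
                         model_cfg = model_config(),
                         train_cfg = train_config()) {
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    mc <- model_cfg
    for (nm in intersect(names(grid),
                         c("use_sequence", "use_positional_encoder",
                           "use_pt_block", "num_pt_layers")))
      mc[[nm]] <- if (nm == "num_pt_layers") as.integer(grid[[nm]][i])
                  else isTRUE(grid[[nm]][i])
    model <- ptppi_train(train_pairs, val_pairs, mc, train_cfg)
    met <- evaluate_pairs(model, test_pairs)
    rows[[i]] <- data.frame(
      block = if (mc$use_pt_block) "pt" else "mlp",
      layers = if (mc$use_pt_block) mc$num_pt_layers else NA_integer_,
      use_sequence = mc$use_sequence,
      use_positional_encoder = mc$use_positional_encoder,
      accuracy = met$accuracy, precision = met$precision,
      recall = met$recall, f1 = met$f1, auroc = met$auroc,
      auprc = met$auprc)
  }
  do.call(rbind, rows)
}

#' Save / load a fitted model
#'
#' Weights go to a single RDS file; the model configuration is mirrored to
#' a JSON sidecar (`<path>.json`) for inspection.
#'
#' @param model A `ptppi_model`.
#' @param path Checkpoint path.
#' @return `save_ptppi()` returns `path` invisibly; `load_ptppi()` the
#'   model.
#' @export
save_ptppi <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$model_config[names(model$model_config)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_ptppi
#' @export
load_ptppi <- function(path) readRDS(path)
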