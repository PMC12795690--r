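# Metrics, training loop, cross-validation and the ablation harness.

test_that("metrics match hand-computed values on canonical fixtures", {
  m <- compute_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(m$accuracy, 1)
  expect_equal(m$auroc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$f1, 1)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(2, 0, 2, 0))

  # tie convention: half credit
  expect_equal(auroc(c(0.6, 0.6), c(1, 0)), 0.5)

  # single-class labels: curve areas undefined, threshold metrics computed
  s <- compute_metrics(c(0.7, 0.2), c(1, 1))
  expect_true(is.na(s$auroc) && is.na(s$auprc))
  expect_equal(s$accuracy, 0.5)
})

test_that("AUROC equals exhaustive pair counting with ties at half credit", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 50
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    cnt <- 0
    for (a in pos) for (b in neg)
      cnt <- cnt + (a > b) + 0.5 * (a == b)
    expect_equal(auroc(scores, labels), cnt / (length(pos) * length(neg)))
  }
})

test_that("AUPRC equals the explicit step integral", {
  set.seed(5)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  rec <- cumsum(y) / sum(y)
  manual <- sum(diff(c(0, rec)) * prec)  # unique scores here
  expect_equal(auprc(scores, labels), manual)
  expect_equal(compute_metrics(scores, labels)$auprc, manual)
})

test_that("F1 and accuracy identities hold on random evaluations", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 40
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    m <- compute_metrics(scores, labels)
    expect_equal(m$accuracy, (m$tp + m$tn) / n)
    expect_equal(m$tp + m$fp + m$tn + m$fn, n)
    if (!is.na(m$f1))
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
  }
})

test_that("training rejects single-class training sets", {
  pairs <- lapply(1:4, function(i) toy_pair(1, seed = i))
  expect_error(ptppi_train(pairs, pairs, toy_cfg(), train_config()),
               class = "ptppi_training_setup")
})

test_that("early stopping halts after patience epochs without improvement", {
  # validation pairs carry inverted labels, so fitting the training set
  # makes validation loss worsen monotonically from the start
  tr <- toy_pairs(8, seed = 3)
  va <- lapply(tr, function(p) { p$label <- 1 - p$label; p })
  tc <- train_config(learning_rate = 0.05, max_epochs = 30, patience = 1,
                     rng_seed = 2)
  m <- ptppi_train(tr, va, toy_cfg(), tc)
  expect_equal(nrow(m$history), 2)
  expect_gt(m$history$val_loss[2], m$history$val_loss[1])
  expect_equal(m$best_epoch, 1)
})

test_that("identical seeds reproduce the loss history exactly", {
  ds <- small_dataset(1)[1:24]
  mc <- model_config(hidden_dim = 8, num_pt_layers = 1, rng_seed = 1)
  tc <- train_config(learning_rate = 1e-3, batch_size = 8, max_epochs = 3,
                     patience = 3, rng_seed = 11)
  m1 <- ptppi_train(ds[1:16], ds[17:24], mc, tc)
  m2 <- ptppi_train(ds[1:16], ds[17:24], mc, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  tc2 <- tc; tc2$rng_seed <- 12L
  m3 <- ptppi_train(ds[1:16], ds[17:24], mc, tc2)
  expect_false(identical(m1$history, m3$history))
})

test_that("training reduces the loss on signal-bearing synthetic data", {
  ds <- small_dataset(1)
  folds <- make_splits(ds, k = 5, seed = 3)
  mc <- model_config(hidden_dim = 16, num_pt_layers = 2, rng_seed = 1)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 12, patience = 12,
                     rng_seed = 5)
  m <- ptppi_train(ds[folds > 1], ds[folds == 1], mc, tc)
  expect_lt(utils::tail(m$history$train_loss, 1), m$history$train_loss[1])
  expect_s3_class(m, "ptppi_model")
  # the fitted-model interface behaves
  pr <- predict(m, ds[folds == 1])
  expect_true(all(pr > 0 & pr < 1))
  cl <- predict(m, ds[folds == 1], type = "class")
  expect_true(all(cl %in% c(0L, 1L)))
  expect_named(coef(m))
  expect_output(print(m), "ptppi_model")
  expect_output(summary(m), "parameters")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(m); grDevices::dev.off()
  expect_true(file.exists(tf))
  # checkpoint round trip
  ck <- tempfile(fileext = ".rds")
  save_ptppi(m, ck)
  m2 <- load_ptppi(ck)
  expect_equal(predict(m2, ds[folds == 1]), pr)
  expect_true(file.exists(paste0(ck, ".json")))
})

test_that("cross-validation returns one record per fold with exact aggregation", {
  pairs <- toy_pairs(9, seed = 20)
  mc <- toy_cfg()
  tc <- train_config(learning_rate = 1e-2, max_epochs = 2, patience = 2,
                     rng_seed = 3)
  cv <- cross_validate(pairs, k = 3, seed = 2, mc, tc)
  expect_length(cv$folds, 3)
  expect_equal(nrow(cv$table), 3)
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"],
               mean(cv$table$accuracy))
  expect_equal(cv$summary$sd[cv$summary$metric == "f1"], sd(cv$table$f1))
  # a different seed changes folds but not the schema
  cv2 <- cross_validate(pairs, k = 3, seed = 9, mc, tc)
  expect_identical(names(cv2$table), names(cv$table))
})

test_that("the ablation harness runs the grid and records the MLP substitute", {
  pairs <- toy_pairs(12, seed = 30)
  grid <- rbind(
    data.frame(use_sequence = TRUE, use_positional_encoder = TRUE,
               use_pt_block = TRUE, num_pt_layers = 1),
    data.frame(use_sequence = FALSE, use_positional_encoder = TRUE,
               use_pt_block = TRUE, num_pt_layers = 1),
    data.frame(use_sequence = TRUE, use_positional_encoder = FALSE,
               use_pt_block = TRUE, num_pt_layers = 1),
    data.frame(use_sequence = TRUE, use_positional_encoder = TRUE,
               use_pt_block = FALSE, num_pt_layers = 1))
  tc <- train_config(learning_rate = 1e-2, max_epochs = 2, patience = 2,
                     rng_seed = 4)
  tab <- run_ablation(pairs[1:6], pairs[7:9], pairs[10:12], grid,
                      toy_cfg(), tc)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$block, c("pt", "pt", "pt", "mlp"))
  expect_true(is.na(tab$layers[4]))
  # bitwise reproducibility under identical seeds
  tab2 <- run_ablation(pairs[1:6], pairs[7:9], pairs[10:12], grid,
                       toy_cfg(), tc)
  expect_identical(tab, tab2)
})

test_that("held-out AUROC is monotone in the synthetic signal strength", {
  med <- vapply(c(0, 0.5, 1), function(s) {
    ds <- small_dataset(s)
    median(vapply(1:3, function(seed) train_eval_auroc(ds, seed),
                  numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})
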