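test_that("the model accepts image pairs and emits probability and activity", {
  tens <- tiny_tensors()
  model <- build_model(tiny_cfg(), L = tens$L)
  pred <- predict(model, tens)
  expect_equal(nrow(pred), length(tens$label))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_true(all(pred$activity >= 0 & pred$activity <= 1))
  # empty batch -> empty output
  empty <- offtargetr:::subset_tensors(tens, integer(0))
  pred0 <- predict(model, empty)
  expect_equal(nrow(pred0), 0L)
  # zero conv blocks is rejected
  expect_error(model_config(conv_blocks = list()), "conv")
})

test_that("the sister branches share weights: same image, same embedding", {
  tens <- tiny_tensors()
  model <- build_model(tiny_cfg(), L = tens$L)
  mats <- offtargetr:::tensors_matrices(tens)
  rows <- offtargetr:::batch_rows(1:4, tens$L)
  X <- mats$Xo[rows, , drop = FALSE]
  fw <- offtargetr:::nn_forward(model, X, X, 4L, training = FALSE)
  expect_equal(fw$emb_t$value, fw$emb_o$value)
  # and the parameter set contains a single branch's weights
  expect_false(any(grepl("_2$", names(model$params))))
  # the no-sharing variant duplicates them
  m2 <- build_model(tiny_cfg(share_weights = FALSE), L = tens$L)
  expect_true(any(grepl("conv1_W_2", names(m2$params))))
})

test_that("analytic gradients match finite differences through every layer", {
  tens <- tiny_tensors()
  model <- build_model(tiny_cfg(), L = tens$L)
  cw <- c(positive = 1.5, negative = 0.7)
  idx <- 1:8
  bl <- offtargetr:::nn_batch_loss(model, tens, idx, cw, training = TRUE,
                                   with_grads = TRUE)
  eps <- 1e-5
  set.seed(99)
  for (nm in c("conv1_W", "bn1_gamma", "bn2_beta", "lstm_f_Wx", "lstm_b_Wh",
               "lstm_f_b", "cls_W1", "cls_b3", "reg_W3")) {
    p <- model$params[[nm]]
    for (k in sample(length(p), min(3, length(p)))) {
      m2 <- model
      up <- p; up[k] <- up[k] + eps; m2$params[[nm]] <- up
      l1 <- offtargetr:::nn_batch_loss(m2, tens, idx, cw,
                                       training = TRUE)$loss[["combined"]]
      dn <- p; dn[k] <- dn[k] - eps; m2$params[[nm]] <- dn
      l2 <- offtargetr:::nn_batch_loss(m2, tens, idx, cw,
                                       training = TRUE)$loss[["combined"]]
      num <- (l1 - l2) / (2 * eps)
      ana <- bl$grads[[nm]][k]
      expect_equal(ana, num, tolerance = 1e-4, info = nm)
    }
  }
})

test_that("the combined loss decomposes exactly and masks negatives", {
  # closed-form checks on the loss function itself
  perfect <- combined_loss(c(1, 0), c(1, 0), c(0.5, 0), c(0.5, 0))
  expect_equal(unname(perfect[["combined"]]), 0, tolerance = 1e-9)

  # equal-weight half probabilities: BCE = ln 2
  l <- combined_loss(c(1, 0), c(0.5, 0.5), c(0.3, 0), c(0.9, 0.4))
  expect_equal(unname(l[["cls"]]), log(2))
  # masked regression ignores the negative sample entirely
  l2 <- combined_loss(c(1, 0), c(0.5, 0.5), c(0.3, 0.77), c(0.9, 0.12))
  expect_equal(unname(l[["reg"]]), unname(l2[["reg"]]))
  expect_equal(unname(l[["reg"]]), 0.36)

  # decomposition identity at the default factor
  expect_equal(unname(l[["combined"]]),
               unname(l[["cls"]]) + 2e-4 * unname(l[["reg"]]))
  # the lambda -> 0 limit approaches the pure classification loss
  l3 <- combined_loss(c(1, 0), c(0.5, 0.5), c(0.3, 0), c(0.9, 0.4),
                      lambda = 1e-12)
  expect_equal(unname(l3[["combined"]]), unname(l3[["cls"]]), tolerance = 1e-10)
  expect_error(combined_loss(c(1, NA), c(0.5, 0.5), c(0, 0), c(0, 0)), "NaN")

  # the training loss obeys the same identities on a real batch
  tens <- tiny_tensors()
  model <- build_model(tiny_cfg(), L = tens$L)
  cw <- c(positive = 2, negative = 0.6)
  bl <- offtargetr:::nn_batch_loss(model, tens, 1:16, cw, training = FALSE)
  expect_equal(bl$loss[["combined"]],
               bl$loss[["cls"]] + 2e-4 * bl$loss[["reg"]])
  # perturbing negative-sample activities leaves the loss unchanged
  tens2 <- tens
  neg <- tens2$label == 0
  tens2$activity[neg] <- runif(sum(neg))
  bl2 <- offtargetr:::nn_batch_loss(model, tens2, 1:16, cw, training = FALSE)
  expect_equal(bl$loss, bl2$loss)
})

test_that("training is reproducible, tracks losses, and halves the rate on plateaus", {
  tens <- tiny_tensors(seed = 8, n_pos = 15, n_neg = 45)
  # an aggressive rate on a tiny set plateaus quickly, exercising the halvings
  cfg <- tiny_cfg(epochs = 8, patience = 1, lr = 0.1)
  fit1 <- train_model(NULL, tens, tens, cfg = cfg)
  fit2 <- train_model(NULL, tens, tens, cfg = cfg)
  expect_identical(fit1$report, fit2$report)
  r <- fit1$report
  expect_equal(nrow(r), 8L)
  expect_true(all(diff(r$lr) <= 0))      # non-increasing trace
  # the whole trace reproduces from the plateau rule applied to val losses
  sim_lr <- function(val, lr0, patience) {
    lr <- lr0; best <- Inf; stall <- 0L; out <- numeric(length(val))
    for (e in seq_along(val)) {
      out[e] <- lr
      if (val[e] < best - 1e-12) {
        best <- val[e]; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) { lr <- lr / 2; stall <- 0L }
      }
    }
    out
  }
  expect_equal(r$lr, sim_lr(r$val_loss, cfg$lr, cfg$patience))
  expect_true(any(diff(r$lr) < 0))       # patience 1 forces halvings here
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_equal(glance(fit1)$epochs, 8L)
})

test_that("a mildly imbalanced separable set of ~500 pairs is learned to high MCC", {
  tens <- tiny_tensors(seed = 12, n_pos = 100, n_neg = 150)
  cfg <- model_config(conv_blocks = list(c(8, 5), c(16, 3)), lstm_units = 8,
                      head_dense_sizes = c(16, 8), batch_size = 32,
                      epochs = 30, lr = 2e-3, dropout = 0, seed = 5)
  n <- length(tens$label)
  set.seed(1)
  tr_idx <- sample(n, round(0.75 * n))
  tr <- offtargetr:::subset_tensors(tens, tr_idx)
  va <- offtargetr:::subset_tensors(tens, setdiff(seq_len(n), tr_idx))
  fit <- train_model(NULL, tr, va, cfg = cfg)
  m <- evaluate_model(fit, va)
  expect_gte(m$summary$mcc, 0.9)
  # a training example re-fed lands on the correct side of 0.5
  p <- predict(fit, tr)
  expect_true(mean((p$prob >= 0.5) == (tr$label == 1)) > 0.95)
})

test_that("grid search sweeps the Cartesian grid deterministically", {
  tens <- tiny_tensors()
  base <- tiny_cfg(epochs = 2)
  expect_error(grid_search(tens, tens, list(), base), "empty")
  g1 <- grid_search(tens, tens, list(lstm_units = list(4L)), base)
  expect_equal(nrow(g1$leaderboard), 1L)
  expect_equal(g1$best_config$lstm_units, 4L)
  g4 <- grid_search(tens, tens,
                    list(lstm_units = list(4L, 6L), lr = list(1e-3, 5e-4)),
                    base)
  expect_equal(nrow(g4$leaderboard), 4L)
  expect_equal(g4$leaderboard$val_loss, sort(g4$leaderboard$val_loss))
  g4b <- grid_search(tens, tens,
                     list(lstm_units = list(4L, 6L), lr = list(1e-3, 5e-4)),
                     base)
  expect_identical(g4$leaderboard, g4b$leaderboard)
})

test_that("repeated evaluation reports a distribution over distinct splits", {
  ds <- generate_dataset(generator_config(n_targets = 2, n_pos_per_target = 15,
                                          n_neg_per_target = 60, seed = 13))
  ds <- normalize_read_counts(deduplicate_and_relabel(ds))
  al <- align_dataset(ds)
  expect_error(repeated_evaluation(al, tiny_cfg(), n_repeats = 1), "n_repeats")
  re <- repeated_evaluation(al, tiny_cfg(epochs = 2), n_repeats = 2)
  expect_equal(nrow(re$runs), 2L)
  expect_equal(length(unique(re$runs$split_seed)), 2L)
  expect_true(all(c("mean", "sd") %in% names(re$summary)))
  expect_s3_class(glance(re), "tbl_df")
})
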