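# Multitask Siamese CNN-biLSTM off-target model.
#
# Two weight-shared ("identical sister") branches read the target image and
# the off-target image. Each branch applies two convolution + batch
# normalization + ReLU blocks along the position axis, then a bidirectional
# LSTM whose final states (both directions) form the branch embedding. The
# two embeddings are concatenated and fed to two independent fully connected
# stacks: a classification head emitting a probability that the candidate is
# a true (cleaved) off-target, and a regression head estimating the extent of
# cleavage activity (normalized read count). The combined loss is
# class-weighted binary cross-entropy plus lambda times the masked (positives
# only) mean squared error of the regression head.

#' Model configuration
#'
#' @param conv_blocks List of `c(filters, kernel_size)` pairs (default
#'   `list(c(64, 5), c(128, 3))`). Kernels must be odd ("same" padding).
#' @param lstm_units Hidden units per LSTM direction (default 64).
#' @param head_dense_sizes Sizes of the two hidden dense layers in each head
#'   (default `c(128, 64)`).
#' @param l2 L2 penalty on dense-layer weights (default `5e-4`); applied as a
#'   weight penalty during optimization, not folded into the reported loss.
#' @param lr Initial Adam learning rate (default `1e-4`).
#' @param reg_loss_weight Factor `lambda` scaling the regression loss in the
#'   combined loss (default `2e-4`, bringing the two losses to the same
#'   scale).
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 128).
#' @param patience Epochs without validation-loss improvement before the
#'   learning rate is halved (default 5).
#' @param share_weights Use true Siamese weight sharing between the two
#'   branches (default `TRUE`); `FALSE` gives each branch its own weights.
#' @param lstm_readout How the biLSTM states form the branch embedding:
#'   `"sequence"` (default) concatenates the hidden states of every position,
#'   preserving position-resolved evidence for the heads; `"mean"` averages
#'   the states over positions (global average pooling); `"final"` uses only
#'   the final state of each direction.
#' @param mask_regression Compute the regression loss over positive samples
#'   only (default `TRUE`); `FALSE` uses all samples with negatives' targets
#'   at 0.
#' @param reg_l2_scale Multiplier on `l2` for the regression head's weights
#'   (default `NULL` = `reg_loss_weight`): the regression gradients are
#'   `reg_loss_weight`-scaled, so the head's penalty is scaled down with them
#'   or it would pin the stack at zero.
#' @param dropout Dropout rate applied (during training) to the concatenated
#'   branch embedding and after each hidden dense layer of both heads
#'   (default 0, i.e. off).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A list of class `ot_model_config`.
#' @export
model_config <- function(conv_blocks = list(c(64, 5), c(128, 3)),
                         lstm_units = 64, head_dense_sizes = c(128, 64),
                         l2 = 5e-4, lr = 1e-4, reg_loss_weight = 2e-4,
                         epochs = 30, batch_size = 128, patience = 5,
                         share_weights = TRUE,
                         lstm_readout = c("sequence", "mean", "final"),
                         mask_regression = TRUE, reg_l2_scale = NULL,
                         dropout = 0, seed = 1L) {
  if (length(conv_blocks) < 1) abort("at least one convolution block is required")
  for (b in conv_blocks) {
    if (length(b) != 2 || any(b < 1) || b[2] %% 2 == 0) {
      abort("each conv block must be c(filters, odd kernel_size)")
    }
  }
  if (reg_loss_weight <= 0) abort("reg_loss_weight must be positive")
  if (l2 < 0) abort("l2 must be non-negative")
  if (lr <= 0) abort("lr must be positive")
  lstm_readout <- match.arg(lstm_readout)
  structure(list(conv_blocks = conv_blocks,
                 lstm_units = as.integer(lstm_units),
                 head_dense_sizes = as.integer(head_dense_sizes),
                 l2 = l2, lr = lr, reg_loss_weight = reg_loss_weight,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 share_weights = isTRUE(share_weights),
                 lstm_readout = lstm_readout,
                 mask_regression = isTRUE(mask_regression),
                 reg_l2_scale = reg_l2_scale,
                 dropout = dropout,
                 seed = as.integer(seed)),
            class = "ot_model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

init_branch_params <- function(cfg, suffix = "") {
  p <- list()
  cin <- 5L
  for (i in seq_along(cfg$conv_blocks)) {
    f <- cfg$conv_blocks[[i]][1]
    k <- cfg$conv_blocks[[i]][2]
    p[[paste0("conv", i, "_W", suffix)]] <- glorot(k * cin, f)
    p[[paste0("conv", i, "_b", suffix)]] <- matrix(0, 1, f)
    p[[paste0("bn", i, "_gamma", suffix)]] <- matrix(1, 1, f)
    p[[paste0("bn", i, "_beta", suffix)]] <- matrix(0, 1, f)
    cin <- f
  }
  H <- cfg$lstm_units
  for (dir in c("f", "b")) {
    p[[paste0("lstm_", dir, "_Wx", suffix)]] <- glorot(cin, 4 * H)
    p[[paste0("lstm_", dir, "_Wh", suffix)]] <- glorot(H, 4 * H)
    bias <- matrix(0, 1, 4 * H)
    bias[1, (H + 1):(2 * H)] <- 1  # forget-gate bias init
    p[[paste0("lstm_", dir, "_b", suffix)]] <- bias
  }
  p
}

init_head_params <- function(cfg, head, L) {
  p <- list()
  # two branches x two directions; sequence readout keeps all L positions
  din <- if (identical(cfg$lstm_readout, "sequence")) {
    4L * cfg$lstm_units * L
  } else {
    4L * cfg$lstm_units
  }
  sizes <- c(cfg$head_dense_sizes, 1L)
  for (i in seq_along(sizes)) {
    p[[paste0(head, "_W", i)]] <- glorot(din, sizes[i])
    p[[paste0(head, "_b", i)]] <- matrix(0, 1, sizes[i])
    din <- sizes[i]
  }
  p
}

#' Build an untrained multitask model
#'
#' @param cfg A [model_config()].
#' @param L Image width the model accepts (default 26).
#' @return A list of class `ot_model` holding the configuration, parameter
#'   matrices and batch-normalization running statistics.
#' @export
build_model <- function(cfg = model_config(), L = 26L) {
  stopifnot(inherits(cfg, "ot_model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  params <- init_branch_params(cfg, "")
  if (!cfg$share_weights) params <- c(params, init_branch_params(cfg, "_2"))
  params <- c(params, init_head_params(cfg, "cls", L),
              init_head_params(cfg, "reg", L))
  bn_state <- list()
  sfx <- if (cfg$share_weights) "" else c("", "_2")
  for (s in sfx) {
    for (i in seq_along(cfg$conv_blocks)) {
      st <- new.env(parent = emptyenv())
      st$mean <- NULL; st$var <- NULL
      bn_state[[paste0("bn", i, s)]] <- st
    }
  }
  structure(list(cfg = cfg, L = as.integer(L), params = params,
                 bn_state = bn_state),
            class = "ot_model")
}

#' @export
print.ot_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("<ot_model> Siamese CNN-biLSTM multitask network ",
                     "(%d parameters, input 5 x %d)\n"), np, x$L))
  invisible(x)
}

# Convert an (n, 5, L) tensor slab into the (n*L) x 5 sample-major matrix the
# graph consumes: row (i-1)*L + t holds sample i, position t.
tensor_to_matrix <- function(arr) {
  n <- dim(arr)[1]; L <- dim(arr)[3]
  matrix(aperm(arr, c(3, 1, 2)), nrow = n * L, ncol = dim(arr)[2])
}

# Flatten both image stacks once; minibatches then slice rows directly.
tensors_matrices <- function(tens) {
  list(Xt = tensor_to_matrix(tens$target), Xo = tensor_to_matrix(tens$offtarget))
}

batch_rows <- function(idx, L) rep((idx - 1L) * L, each = L) + seq_len(L)

# Memoized im2col index maps (keyed by n, L, kernel width).
im2col_cache <- new.env(parent = emptyenv())

# im2col row-index map: for each (sample, position, kernel offset) the source
# row in the (n*L) x C matrix, 0 for out-of-range (zero padding).
im2col_index <- function(n, L, k) {
  half <- (k - 1) / 2
  t <- rep(seq_len(L), times = n)
  i <- rep(seq_len(n), each = L)
  idx <- matrix(0L, nrow = n * L, ncol = k)
  for (j in seq_len(k)) {
    tt <- t + (j - 1L - half)
    ok <- tt >= 1L & tt <= L
    idx[ok, j] <- (i[ok] - 1L) * L + tt[ok]
  }
  idx
}

# One branch: conv/bn/relu blocks then biLSTM; returns the n x 2H embedding
# node. `pn` maps parameter name -> leaf node; `suffix` selects the branch's
# parameter set when weights are not shared.
nn_branch <- function(tape, X, n, L, model, pn, training, suffix = "") {
  cfg <- model$cfg
  h <- X
  cin <- 5L
  for (i in seq_along(cfg$conv_blocks)) {
    k <- cfg$conv_blocks[[i]][2]
    key <- paste(n, L, k, sep = "_")
    if (is.null(im2col_cache[[key]])) im2col_cache[[key]] <- im2col_index(n, L, k)
    idx <- im2col_cache[[key]]
    cols <- ad_cbind(tape, lapply(seq_len(k), function(j)
      ad_gather_rows(tape, h, idx[, j])))
    conv <- ad_add_bias(tape,
                        ad_matmul(tape, cols, pn[[paste0("conv", i, "_W", suffix)]]),
                        pn[[paste0("conv", i, "_b", suffix)]])
    bn <- ad_batchnorm(tape, conv,
                       pn[[paste0("bn", i, "_gamma", suffix)]],
                       pn[[paste0("bn", i, "_beta", suffix)]],
                       model$bn_state[[paste0("bn", i, suffix)]], training)
    h <- ad_relu(tape, bn)
    cin <- cfg$conv_blocks[[i]][1]
  }
  H <- cfg$lstm_units
  run_lstm <- function(dir) {
    all_h <- ad_lstm(tape, h,
                     pn[[paste0("lstm_", dir, "_Wx", suffix)]],
                     pn[[paste0("lstm_", dir, "_Wh", suffix)]],
                     pn[[paste0("lstm_", dir, "_b", suffix)]],
                     n, L, reverse = (dir == "b"))
    if (identical(cfg$lstm_readout, "final")) {
      # final state: last position for the forward pass, first for backward
      t_last <- if (dir == "f") L else 1L
      ad_cols(tape, all_h, ((t_last - 1) * H + 1):(t_last * H))
    } else if (identical(cfg$lstm_readout, "mean")) {
      # global average pooling over positions: all_h %*% M, M (L*H x H)
      M <- matrix(0, L * H, H)
      M[cbind(seq_len(L * H), rep(seq_len(H), times = L))] <- 1 / L
      ad_matmul(tape, all_h, ad_leaf(tape, M))
    } else {
      all_h
    }
  }
  ad_cbind(tape, list(run_lstm("f"), run_lstm("b")))
}

nn_head <- function(tape, x, pn, head, n_layers, dropout = 0,
                    training = FALSE) {
  h <- x
  for (i in seq_len(n_layers)) {
    h <- ad_add_bias(tape, ad_matmul(tape, h, pn[[paste0(head, "_W", i)]]),
                     pn[[paste0(head, "_b", i)]])
    if (i < n_layers) {
      h <- ad_relu(tape, h)
      h <- ad_dropout(tape, h, dropout, training)
    }
  }
  h
}

# Full forward pass. Returns tape, input leaves, pre-activation heads.
nn_forward <- function(model, Xt, Xo, n, training) {
  cfg <- model$cfg
  tape <- ad_tape()
  pn <- lapply(model$params, function(p) ad_leaf(tape, p))
  xt_node <- ad_leaf(tape, Xt)
  xo_node <- ad_leaf(tape, Xo)
  L <- model$L
  sfx2 <- if (cfg$share_weights) "" else "_2"
  emb_t <- nn_branch(tape, xt_node, n, L, model, pn, training, "")
  emb_o <- nn_branch(tape, xo_node, n, L, model, pn, training, sfx2)
  merged <- ad_cbind(tape, list(emb_t, emb_o))
  dropout <- if (is.null(cfg$dropout)) 0 else cfg$dropout
  merged <- ad_dropout(tape, merged, dropout, training)
  n_layers <- length(cfg$head_dense_sizes) + 1L
  cls_logit <- nn_head(tape, merged, pn, "cls", n_layers, dropout, training)
  reg_raw <- nn_head(tape, merged, pn, "reg", n_layers, dropout, training)
  list(tape = tape, pn = pn, xt = xt_node, xo = xo_node,
       emb_t = emb_t, emb_o = emb_o,
       cls_logit = cls_logit, reg_raw = reg_raw)
}

#' Combined multitask loss
#'
#' Class-weighted binary cross-entropy on the classification output plus
#' `lambda` times the mean squared error of the regression output, the
#' latter computed over positive-class samples only (loss masking) so that
#' negatives, whose activity is 0 by construction, contribute no regression
#' signal. `combined == cls + lambda * reg` exactly.
#'
#' @param y_cls 0/1 labels.
#' @param p_cls Predicted probabilities in (0, 1).
#' @param y_reg Regression targets in `[0,1]`.
#' @param p_reg Regression predictions.
#' @param class_wts Named weights (`positive`, `negative`) as from
#'   [class_weights()]; defaults to equal weights.
#' @param lambda Regression loss factor (default `2e-4`).
#' @param mask_regression Mask the regression term to positives (default
#'   `TRUE`).
#' @return Named numeric vector `c(combined, cls, reg)`.
#' @export
combined_loss <- function(y_cls, p_cls, y_reg, p_reg,
                          class_wts = c(positive = 1, negative = 1),
                          lambda = 2e-4, mask_regression = TRUE) {
  stopifnot(length(y_cls) == length(p_cls),
            length(y_reg) == length(p_reg),
            length(y_cls) == length(y_reg))
  if (anyNA(c(y_cls, p_cls, y_reg, p_reg))) abort("NaN/NA in loss inputs")
  if (lambda <= 0) abort("lambda must be positive")
  eps <- 1e-12
  w <- ifelse(y_cls == 1, class_wts[["positive"]], class_wts[["negative"]])
  cls <- mean(w * -(y_cls * log(pmax(p_cls, eps)) +
                      (1 - y_cls) * log(pmax(1 - p_cls, eps))))
  mask <- if (mask_regression) as.numeric(y_cls == 1) else rep(1, length(y_reg))
  m <- max(sum(mask), 1)
  reg <- sum(mask * (p_reg - y_reg)^2) / m
  c(combined = cls + lambda * reg, cls = cls, reg = reg)
}

# Adam with decoupled-gradient L2 weight penalty on dense-layer weights.
adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, l2 = 0,
                      penalty_scale = numeric(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (l2 > 0 && !is.na(penalty_scale[nm]) && penalty_scale[nm] > 0) {
      g <- g + 2 * l2 * penalty_scale[[nm]] * params[[nm]]
    }
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# Forward + loss on one batch; returns loss components and (optionally) the
# parameter gradients.
nn_batch_loss <- function(model, tens, idx, class_wts, training,
                          with_grads = FALSE, mats = NULL) {
  cfg <- model$cfg
  n <- length(idx)
  if (is.null(mats)) mats <- tensors_matrices(tens)
  rows <- batch_rows(idx, tens$L)
  Xt <- mats$Xt[rows, , drop = FALSE]
  Xo <- mats$Xo[rows, , drop = FALSE]
  y <- tens$label[idx]
  a <- tens$activity[idx]
  fw <- nn_forward(model, Xt, Xo, n, training)
  w <- ifelse(y == 1, class_wts[["positive"]], class_wts[["negative"]])
  mask <- if (cfg$mask_regression) as.numeric(y == 1) else rep(1, n)
  cls_node <- ad_wbce_logits(fw$tape, fw$cls_logit, y, w)
  reg_node <- ad_masked_mse(fw$tape, fw$reg_raw, a, mask)
  total <- ad_add(fw$tape, cls_node, ad_scale(fw$tape, reg_node,
                                              cfg$reg_loss_weight))
  loss <- c(combined = total$value[1, 1], cls = cls_node$value[1, 1],
            reg = reg_node$value[1, 1])
  if (!all(is.finite(loss))) {
    abort(paste0("loss diverged (non-finite) on a batch of ", n, " samples"))
  }
  grads <- NULL
  if (with_grads) {
    ad_backward(fw$tape, total)
    grads <- lapply(fw$pn, function(nd) nd$grad)
  }
  list(loss = loss, grads = grads, n = n)
}

# Average loss over a dataset in inference mode.
nn_eval_loss <- function(model, tens, class_wts, batch_size, mats = NULL) {
  n <- length(tens$label)
  if (is.null(mats)) mats <- tensors_matrices(tens)
  sums <- c(combined = 0, cls = 0, reg = 0)
  done <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    bl <- nn_batch_loss(model, tens, idx, class_wts, training = FALSE,
                        mats = mats)
    sums <- sums + bl$loss * length(idx)
    done <- done + length(idx)
  }
  sums / done
}

# L2 penalty multipliers for the dense-layer weights. The classification head
# is penalized at full strength. The regression loss enters the combined loss
# scaled by lambda, so its head gradients are ~lambda-scaled: a penalty
# calibrated against the classification loss would overwhelm them and pin the
# regression stack at zero. Its penalty is therefore scaled down by
# `reg_l2_scale` (see model_config).
dense_penalty_scales <- function(cfg) {
  n_layers <- length(cfg$head_dense_sizes) + 1L
  nms <- as.character(outer(c("cls", "reg"), seq_len(n_layers),
                            function(h, i) paste0(h, "_W", i)))
  scl <- if (is.null(cfg$reg_l2_scale)) cfg$reg_loss_weight else cfg$reg_l2_scale
  setNames(ifelse(grepl("^reg", nms), scl, 1), nms)
}

#' Train the multitask model
#'
#' Adam optimization with class weighting, L2 penalty on dense weights,
#' loss-masked regression, and learning-rate halving when the validation
#' combined loss fails to improve for `patience` consecutive epochs. The
#' parameters with the best validation loss are kept. Fully reproducible
#' given `cfg$seed`.
#'
#' @param model An [build_model()] object (or `NULL` to build from `cfg`).
#' @param train_tensors,val_tensors Encoded datasets ([encode_dataset()]).
#' @param cfg Configuration; defaults to `model$cfg`.
#' @param class_wts Class weights; computed from the training labels by
#'   default.
#' @param verbose Print a line per epoch.
#' @return A list of class `ot_fit`: the trained `model` (best-validation
#'   weights), the per-epoch `report` tibble (`epoch`, `train_loss`,
#'   `train_cls`, `train_reg`, `val_loss`, `val_cls`, `val_reg`, `lr`), and
#'   `best_epoch`.
#' @export
train_model <- function(model = NULL, train_tensors, val_tensors,
                        cfg = NULL, class_wts = NULL, verbose = FALSE) {
  if (is.null(model)) model <- build_model(cfg, L = train_tensors$L)
  if (is.null(cfg)) cfg <- model$cfg
  stopifnot(inherits(model, "ot_model"), inherits(train_tensors, "ot_tensors"))
  if (is.null(class_wts)) {
    lbl <- train_tensors$label
    if (all(lbl == 1) || all(lbl == 0)) {
      class_wts <- c(positive = 1, negative = 1)
    } else {
      n <- length(lbl)
      class_wts <- c(positive = n / (2 * sum(lbl == 1)),
                     negative = n / (2 * sum(lbl == 0)))
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  params <- model$params
  opt <- adam_state(params)
  pscale <- dense_penalty_scales(cfg)
  lr <- cfg$lr
  n <- length(train_tensors$label)
  best_val <- Inf
  best_params <- params
  best_bn <- NULL
  best_epoch <- 0L
  stall <- 0L
  t_global <- 0L
  train_mats <- tensors_matrices(train_tensors)
  val_mats <- tensors_matrices(val_tensors)
  rows <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample(n)
    ep_sums <- c(combined = 0, cls = 0, reg = 0)
    seen <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, n)]
      model$params <- params
      bl <- nn_batch_loss(model, train_tensors, idx, class_wts,
                          training = TRUE, with_grads = TRUE,
                          mats = train_mats)
      t_global <- t_global + 1L
      upd <- adam_step(params, bl$grads, opt, lr, t_global,
                       l2 = cfg$l2, penalty_scale = pscale)
      params <- upd$params
      opt <- upd$state
      ep_sums <- ep_sums + bl$loss * length(idx)
      seen <- seen + length(idx)
    }
    model$params <- params
    val <- nn_eval_loss(model, val_tensors, class_wts, cfg$batch_size,
                        mats = val_mats)
    tr <- ep_sums / seen
    rows[[epoch]] <- tibble(epoch = epoch,
                            train_loss = tr[["combined"]],
                            train_cls = tr[["cls"]], train_reg = tr[["reg"]],
                            val_loss = val[["combined"]],
                            val_cls = val[["cls"]], val_reg = val[["reg"]],
                            lr = lr)
    if (verbose) {
      cat(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e\n",
                  epoch, tr[["combined"]], val[["combined"]], lr))
    }
    if (val[["combined"]] < best_val - 1e-12) {
      best_val <- val[["combined"]]
      best_params <- params
      best_bn <- lapply(model$bn_state, function(st)
        list(mean = st$mean, var = st$var))
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) {
        lr <- lr / 2
        stall <- 0L
      }
    }
  }
  model$params <- best_params
  if (!is.null(best_bn)) {
    for (nm in names(best_bn)) {
      model$bn_state[[nm]]$mean <- best_bn[[nm]]$mean
      model$bn_state[[nm]]$var <- best_bn[[nm]]$var
    }
  }
  structure(list(model = model, report = bind_rows(rows),
                 best_epoch = best_epoch, class_wts = class_wts),
            class = "ot_fit")
}

#' @export
print.ot_fit <- function(x, ...) {
  cat(sprintf("<ot_fit> %d epochs, best validation loss %.5f at epoch %d\n",
              nrow(x$report), min(x$report$val_loss), x$best_epoch))
  invisible(x)
}

#' Predict off-target probability and activity
#'
#' @param object A trained `ot_model` or `ot_fit`.
#' @param tensors Encoded pairs ([encode_dataset()]).
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return A tibble with `prob` (classification probability in `[0,1]`) and
#'   `activity` (regression estimate clipped to `[0,1]`).
#' @export
predict.ot_model <- function(object, tensors, batch_size = 256L, ...) {
  stopifnot(inherits(tensors, "ot_tensors"))
  n <- length(tensors$label)
  if (n == 0) return(tibble(prob = numeric(0), activity = numeric(0)))
  probs <- numeric(n)
  acts <- numeric(n)
  mats <- tensors_matrices(tensors)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    rows <- batch_rows(idx, tensors$L)
    fw <- nn_forward(object, mats$Xt[rows, , drop = FALSE],
                     mats$Xo[rows, , drop = FALSE],
                     length(idx), training = FALSE)
    probs[idx] <- 1 / (1 + exp(-as.numeric(fw$cls_logit$value)))
    acts[idx] <- pmin(pmax(as.numeric(fw$reg_raw$value), 0), 1)
  }
  tibble(prob = probs, activity = acts)
}

#' @rdname predict.ot_model
#' @export
predict.ot_fit <- function(object, tensors, batch_size = 256L, ...) {
  predict(object$model, tensors, batch_size = batch_size)
}
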