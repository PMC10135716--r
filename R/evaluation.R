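# Classification and regression metrics for imbalanced off-target data:
# precision/recall/F1, Matthews correlation, Cohen's kappa, the area under
# the precision-recall curve (average precision), the F1-MCC threshold sweep,
# and the coefficient of determination for the activity regressor.

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "positive")
  } else {
    as.integer(labels != 0)
  }
}

#' Confusion counts at a threshold
#'
#' Predicted positive iff `probability >= threshold`.
#'
#' @param labels True labels: 0/1, logical, or `"positive"`/`"negative"`.
#' @param probabilities Scores in `[0,1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return A named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) == 0) abort("empty input")
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(probabilities))
  pred <- as.integer(probabilities >= threshold)
  c(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
    TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from confusion counts
#'
#' Standard definitions: precision = TP/(TP+FP), recall = TP/(TP+FN), F1 the
#' harmonic mean, MCC the contingency correlation, and Cohen's kappa.
#' Zero-denominator cases return 0 with `degenerate = TRUE` instead of
#' raising, so threshold sweeps never abort.
#'
#' @param cc Named counts as from [confusion_counts()].
#' @return A tibble row: `precision`, `recall`, `f1`, `mcc`, `kappa`,
#'   `degenerate`.
#' @export
classification_metrics <- function(cc) {
  TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  n <- TP + FP + TN + FN
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  f1 <- f_score(precision, recall)
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  po <- safe_div(TP + TN, n)
  pe <- safe_div((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN), n^2)
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
  degenerate <- (TP + FP) == 0 || (TP + FN) == 0 || mcc_den == 0 ||
    abs(1 - pe) < 1e-15
  tibble(precision = precision, recall = recall, f1 = f1, mcc = mcc,
         kappa = kappa, degenerate = degenerate)
}

#' F-score from precision and recall
#'
#' @param precision,recall Component rates.
#' @return Harmonic mean `2PR/(P+R)` (0 when both are 0).
#' @export
f_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Precision-recall curve and area
#'
#' Precision and recall at every distinct score threshold; the area is the
#' average precision (step-wise summation over recall increments, not the
#' trapezoid, avoiding optimistic interpolation on imbalanced data).
#'
#' @param labels,probabilities As in [confusion_counts()].
#' @return A list of class `ot_pr_curve`: `curve` tibble (`threshold`,
#'   `precision`, `recall`) and `auc`.
#' @export
pr_curve <- function(labels, probabilities) {
  y <- as_binary_labels(labels)
  if (all(y == 1) || all(y == 0)) abort("both classes must be present")
  ord <- order(probabilities, decreasing = TRUE)
  y <- y[ord]
  p <- probabilities[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  npos <- sum(y)
  # curve points at the last instance of each distinct score
  last <- which(!duplicated(p, fromLast = TRUE))
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / npos
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = tibble(threshold = p[last], precision = precision,
                      recall = recall),
       auc = ap) -> out
  class(out) <- "ot_pr_curve"
  out
}

#' @export
print.ot_pr_curve <- function(x, ...) {
  cat(sprintf("<ot_pr_curve> %d points, average precision %.4f\n",
              nrow(x$curve), x$auc))
  invisible(x)
}

#' F1-MCC threshold sweep
#'
#' Evaluates F1 and MCC on an even grid of thresholds over `[0,1]`,
#' integrating classifier behaviour across operating points; the best
#' possible point is (F1 = 1, MCC = 1) and the worst (0, -1), carried as
#' attributes for plotting.
#'
#' @param labels,probabilities As in [confusion_counts()].
#' @param n_thresholds Grid size (default 101, i.e. steps of 0.01).
#' @return A tibble (`threshold`, `f1`, `mcc`) with attributes `best_point`
#'   and `worst_point`.
#' @export
f1_mcc_curve <- function(labels, probabilities, n_thresholds = 101L) {
  y <- as_binary_labels(labels)
  if (all(y == 1) || all(y == 0)) abort("both classes must be present")
  th <- seq(0, 1, length.out = n_thresholds)
  rows <- purrr::map(th, function(t) {
    m <- classification_metrics(confusion_counts(y, probabilities, t))
    tibble(threshold = t, f1 = m$f1, mcc = m$mcc)
  })
  out <- bind_rows(rows)
  attr(out, "best_point") <- c(f1 = 1, mcc = 1)
  attr(out, "worst_point") <- c(f1 = 0, mcc = -1)
  out
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param y_true Observed values (variance must be positive).
#' @param y_pred Predicted values.
#' @return Numeric scalar (<= 1).
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 2) abort("need at least 2 samples")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) abort("y_true has zero variance")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Evaluate a fitted model on encoded data
#'
#' Computes the full metrics report on one dataset: threshold metrics at
#' `threshold`, PR-AUC, the F1-MCC sweep, and R^2 of the activity regression
#' over the positive-class samples (where activity is defined).
#'
#' @param object `ot_model` or `ot_fit`.
#' @param tensors Encoded dataset.
#' @param threshold Classification threshold (default 0.5).
#' @return A list of class `ot_metrics`: `summary` (one-row tibble),
#'   `sweep` (F1-MCC table), `pr` (`ot_pr_curve`), `threshold`.
#' @export
evaluate_model <- function(object, tensors, threshold = 0.5) {
  pred <- predict(object, tensors)
  y <- tensors$label
  cm <- classification_metrics(confusion_counts(y, pred$prob, threshold))
  pr <- pr_curve(y, pred$prob)
  sweep_tbl <- f1_mcc_curve(y, pred$prob)
  pos <- y == 1
  r2 <- if (sum(pos) >= 2 && var(tensors$activity[pos]) > 0) {
    r_squared(tensors$activity[pos], pred$activity[pos])
  } else NA_real_
  structure(list(
    summary = mutate(cm, pr_auc = pr$auc, r_squared = r2,
                     threshold = threshold, n = length(y)),
    sweep = sweep_tbl, pr = pr, threshold = threshold,
    predictions = pred
  ), class = "ot_metrics")
}

#' @export
print.ot_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<ot_metrics> n=%d  precision %.3f  recall %.3f  ",
                     "F1 %.3f  MCC %.3f  kappa %.3f  PR-AUC %.3f  R2 %s\n"),
              s$n, s$precision, s$recall, s$f1, s$mcc, s$kappa, s$pr_auc,
              ifelse(is.na(s$r_squared), "NA", sprintf("%.3f", s$r_squared))))
  invisible(x)
}

#' Repeated evaluation over independent splits
#'
#' Splits, trains and evaluates `n_repeats` times with distinct split seeds
#' and reports the distribution of the evaluation metrics.
#'
#' @param ds Aligned, normalized off-target dataset.
#' @param cfg A [model_config()].
#' @param n_repeats Number of repeats (default 5, >= 2).
#' @param spec Base [split_spec()]; repeat `r` uses `spec$seed + r`.
#' @param L Image width.
#' @return A list of class `ot_repeated_eval`: `runs` (one metrics row per
#'   repeat) and `summary` (mean and sd per metric).
#' @export
repeated_evaluation <- function(ds, cfg = model_config(), n_repeats = 5,
                                spec = split_spec(), L = 26L) {
  if (n_repeats < 2) abort("n_repeats must be >= 2")
  runs <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- split_spec(spec$train, spec$val, spec$test,
                     seed = spec$seed + r,
                     stratify_by_label = spec$stratify_by_label)
    splits <- make_splits(ds, sp)
    tr <- encode_dataset(splits$train, L)
    va <- encode_dataset(splits$val, L)
    te <- encode_dataset(splits$test, L)
    fit <- train_model(NULL, tr, va, cfg = cfg)
    m <- evaluate_model(fit, te)
    runs[[r]] <- mutate(m$summary, repeat_index = r, split_seed = sp$seed)
  }
  runs <- bind_rows(runs)
  metric_cols <- c("precision", "recall", "f1", "mcc", "kappa",
                   "pr_auc", "r_squared")
  summary <- runs %>%
    tidyr::pivot_longer(all_of(metric_cols), names_to = "metric") %>%
    group_by(.data$metric) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(runs = runs, summary = summary),
            class = "ot_repeated_eval")
}

#' Grid search over model hyperparameters
#'
#' Exhaustive Cartesian sweep over candidate values of [model_config()]
#' fields; each candidate is trained on the same split and ranked by
#' validation combined loss. Deterministic given the seeds.
#'
#' @param train_tensors,val_tensors Encoded train/validation data.
#' @param grid Named list mapping config fields to candidate value lists,
#'   e.g. `list(lstm_units = c(16, 32), lr = c(1e-3, 1e-4))`.
#' @param base_cfg Defaults for fields not in the grid.
#' @return A list of class `ot_grid_search`: `best_config` and the
#'   `leaderboard` tibble sorted by validation loss.
#' @export
grid_search <- function(train_tensors, val_tensors, grid,
                        base_cfg = model_config()) {
  if (length(grid) == 0) abort("empty grid")
  combos <- expand.grid(lapply(grid, seq_along))
  results <- vector("list", nrow(combos))
  cfgs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- base_cfg
    for (nm in names(grid)) {
      value <- grid[[nm]][[combos[i, nm]]]
      cfg[[nm]] <- if (is.numeric(base_cfg[[nm]]) &&
                         is.integer(base_cfg[[nm]])) {
        as.integer(value)
      } else value
    }
    fit <- train_model(NULL, train_tensors, val_tensors, cfg = cfg)
    cfgs[[i]] <- cfg
    results[[i]] <- tibble(
      config_index = i,
      val_loss = min(fit$report$val_loss),
      best_epoch = fit$best_epoch,
      !!!setNames(lapply(names(grid), function(nm)
        paste(grid[[nm]][[combos[i, nm]]], collapse = ",")), names(grid))
    )
  }
  leaderboard <- bind_rows(results) %>% arrange(.data$val_loss)
  best <- cfgs[[leaderboard$config_index[1]]]
  structure(list(best_config = best, leaderboard = leaderboard),
            class = "ot_grid_search")
}
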