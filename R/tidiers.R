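# broom-style tidiers for the fitted objects.

#' Tidy a training fit
#'
#' @param x An `ot_fit`.
#' @param ... Unused.
#' @return The per-epoch report tibble (`epoch`, losses, `lr`).
#' @export
tidy.ot_fit <- function(x, ...) x$report

#' Glance at a training fit
#'
#' @param x An `ot_fit`.
#' @param ... Unused.
#' @return One row: best validation loss and epoch, final learning rate,
#'   epochs run.
#' @export
glance.ot_fit <- function(x, ...) {
  tibble(epochs = nrow(x$report),
         best_epoch = x$best_epoch,
         best_val_loss = min(x$report$val_loss),
         final_lr = tail(x$report$lr, 1),
         train_loss = tail(x$report$train_loss, 1))
}

#' Tidy a metrics report
#'
#' @param x An `ot_metrics`.
#' @param ... Unused.
#' @return The per-threshold F1/MCC sweep tibble.
#' @export
tidy.ot_metrics <- function(x, ...) x$sweep

#' Glance at a metrics report
#'
#' @param x An `ot_metrics`.
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @export
glance.ot_metrics <- function(x, ...) x$summary

#' Tidy a repeated evaluation
#'
#' @param x An `ot_repeated_eval`.
#' @param ... Unused.
#' @return One metrics row per repeat.
#' @export
tidy.ot_repeated_eval <- function(x, ...) x$runs

#' Glance at a repeated evaluation
#'
#' @param x An `ot_repeated_eval`.
#' @param ... Unused.
#' @return Mean and sd per metric.
#' @export
glance.ot_repeated_eval <- function(x, ...) x$summary

#' Tidy an attribution map
#'
#' @param x An `ot_attribution`.
#' @param ... Unused.
#' @return Long tibble: `branch`, `base`, `column`, `score`.
#' @export
tidy.ot_attribution <- function(x, ...) {
  to_long <- function(m, branch) {
    tibble(branch = branch,
           base = rep(rownames(m), times = ncol(m)),
           column = rep(seq_len(ncol(m)), each = nrow(m)),
           score = as.numeric(m))
  }
  bind_rows(to_long(x$target, "target"), to_long(x$offtarget, "offtarget"))
}
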