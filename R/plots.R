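# ggplot2 views of the result types: per-position propensity bars, PR and
# F1-MCC curves, training traces, attribution heatmaps.

#' Plot a per-position mismatch or gap profile
#'
#' @param profile Output of [mismatch_profile()] or [gap_profile()].
#' @return A ggplot object (percentage per protospacer/PAM position).
#' @export
plot_position_profile <- function(profile) {
  ycol <- if ("mismatch_fraction" %in% names(profile)) {
    "mismatch_fraction"
  } else "gap_fraction"
  what <- if (ycol == "mismatch_fraction") "Mismatch" else "Gap (bulge)"
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position,
                               y = 100 * .data[[ycol]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 20.5, linetype = "dashed") +
    ggplot2::labs(x = "Position (PAM-distal → PAM)",
                  y = paste0(what, " (% of sequences)"),
                  title = paste0(what, " occurrence along the protospacer"),
                  subtitle = if (isTRUE(profile$weighted[1]))
                    "weighted by normalized cleavage frequency" else NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ot_pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("Precision-recall curve (AP = %.3f)",
                                  object$auc),
                  x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Plot an F1-MCC threshold sweep
#'
#' @param sweep Output of [f1_mcc_curve()].
#' @return A ggplot object; the best- and worst-possible points are marked.
#' @export
plot_f1_mcc <- function(sweep) {
  refs <- tibble(f1 = c(1, 0), mcc = c(1, -1),
                 what = c("best possible", "worst possible"))
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$f1, y = .data$mcc)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(data = refs,
                        ggplot2::aes(shape = .data$what), size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(-1, 1)) +
    ggplot2::labs(title = "F1-MCC curve over classification thresholds",
                  x = "F1 score", y = "Matthews correlation", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training trace
#'
#' @param fit An `ot_fit`.
#' @return A ggplot of train/validation combined loss by epoch.
#' @export
plot_training <- function(fit) {
  long <- fit$report %>%
    select("epoch", "train_loss", "val_loss") %>%
    tidyr::pivot_longer(-"epoch", names_to = "split", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Training trace", x = "Epoch",
                  y = "Combined loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ot_attribution <- function(object, ...) {
  to_long <- function(m, branch) {
    tibble(branch = branch,
           base = rep(rownames(m), times = ncol(m)),
           column = rep(seq_len(ncol(m)), each = nrow(m)),
           score = as.numeric(m))
  }
  long <- bind_rows(to_long(object$target, "target"),
                    to_long(object$offtarget, "off-target")) %>%
    mutate(base = factor(.data$base, levels = rev(OT_ALPHABET)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$base,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~branch, ncol = 1) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(title = sprintf("Attribution map (%s, %s head)",
                                  object$method, object$head),
                  x = "Image column", y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}
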