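# Gradient attribution over the trained network. All methods differentiate a
# chosen head's pre-activation output (pre-sigmoid for classification,
# avoiding gradient saturation) with respect to the input pixels of BOTH
# branch images, and report a signed 5 x L map per branch. The network is
# evaluated in inference mode (running batch-norm statistics) so per-sample
# gradients are well defined.

as_pair_matrices <- function(pair) {
  if (inherits(pair, "ot_tensors")) {
    stopifnot(length(pair$label) == 1)
    return(list(target = matrix(pair$target[1, , ], nrow = 5),
                offtarget = matrix(pair$offtarget[1, , ], nrow = 5)))
  }
  stopifnot(is.list(pair), !is.null(pair$target), !is.null(pair$offtarget))
  list(target = unclass(pair$target)[, , drop = FALSE],
       offtarget = unclass(pair$offtarget)[, , drop = FALSE])
}

new_attribution <- function(target, offtarget, method, head, baseline, n = 1L) {
  structure(list(target = target, offtarget = offtarget, method = method,
                 head = head, baseline = baseline, n = n),
            class = "ot_attribution")
}

#' @export
print.ot_attribution <- function(x, ...) {
  cat(sprintf("<ot_attribution> method=%s head=%s (5 x %d per branch, n=%d)\n",
              x$method, x$head, ncol(x$target), x$n))
  invisible(x)
}

# Gradient of the head output w.r.t. a batch of inputs. Xt/Xo are
# (n*L) x 5 matrices (n copies of a pair, possibly perturbed). Returns the
# per-row input gradients for both branches.
input_gradients <- function(model, Xt, Xo, n, head) {
  head <- match.arg(head, c("classification", "regression"))
  fw <- nn_forward(model, Xt, Xo, n, training = FALSE)
  out <- if (head == "classification") fw$cls_logit else fw$reg_raw
  ad_backward(fw$tape, out, seed = 1)
  list(target = fw$xt$grad, offtarget = fw$xo$grad,
       output = as.numeric(out$value))
}

# Convert a 5 x L image matrix into the 1-sample (L x 5) graph layout and
# back.
img_to_rows <- function(img) t(unclass(img))
rows_to_img <- function(rows, L) {
  m <- t(rows)
  rownames(m) <- OT_ALPHABET
  m
}

# Stack k perturbed copies of a pair into the batch layout.
stack_rows <- function(rows_list) do.call(rbind, rows_list)

split_rows <- function(g, k, L) {
  lapply(seq_len(k), function(i) g[((i - 1) * L + 1):(i * L), , drop = FALSE])
}

#' Gradient saliency map
#'
#' Absolute gradient of the chosen head's pre-activation output with respect
#' to every input pixel of the target and off-target images.
#'
#' @param model `ot_model` or `ot_fit`.
#' @param pair Encoded pair: a list with `target` and `offtarget` 5 x L
#'   matrices (see [encode_pair()]) or a single-record `ot_tensors`.
#' @param head `"classification"` (default) or `"regression"`.
#' @return An `ot_attribution` (non-negative values).
#' @export
gradient_saliency <- function(model, pair, head = "classification") {
  if (inherits(model, "ot_fit")) model <- model$model
  p <- as_pair_matrices(pair)
  L <- ncol(p$target)
  g <- input_gradients(model, img_to_rows(p$target), img_to_rows(p$offtarget),
                       1L, head)
  new_attribution(abs(rows_to_img(g$target, L)),
                  abs(rows_to_img(g$offtarget, L)),
                  "saliency", head, baseline = NULL)
}

#' Smoothed saliency map
#'
#' Average of `n` saliency maps computed on copies of the input perturbed by
#' zero-mean Gaussian noise of standard deviation `sigma` times the input
#' range (the one-hot range is 1). With `n = 1, sigma = 0` this reduces
#' exactly to [gradient_saliency()].
#'
#' @inheritParams gradient_saliency
#' @param n Number of noisy samples (default 25).
#' @param sigma Noise scale (default 0.15).
#' @param seed Seed for the noise draws.
#' @return An `ot_attribution`.
#' @export
smoothed_saliency <- function(model, pair, head = "classification",
                              n = 25L, sigma = 0.15, seed = 1L) {
  if (inherits(model, "ot_fit")) model <- model$model
  stopifnot(n >= 1, sigma >= 0)
  p <- as_pair_matrices(pair)
  L <- ncol(p$target)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rt <- img_to_rows(p$target)
  ro <- img_to_rows(p$offtarget)
  noisy_t <- lapply(seq_len(n), function(i)
    rt + if (sigma > 0) matrix(rnorm(length(rt), 0, sigma), nrow(rt)) else 0)
  noisy_o <- lapply(seq_len(n), function(i)
    ro + if (sigma > 0) matrix(rnorm(length(ro), 0, sigma), nrow(ro)) else 0)
  g <- input_gradients(model, stack_rows(noisy_t), stack_rows(noisy_o),
                       n, head)
  gt <- split_rows(abs(g$target), n, L)
  go <- split_rows(abs(g$offtarget), n, L)
  new_attribution(rows_to_img(Reduce(`+`, gt) / n, L),
                  rows_to_img(Reduce(`+`, go) / n, L),
                  "smoothed_saliency", head,
                  baseline = list(sigma = sigma, n = n))
}

#' Integrated gradients
#'
#' Path-integrates the head gradient as the input is scaled from a reference
#' baseline to the actual input:
#' `IG_i = (x_i - x'_i) * mean_k d f / d x_i` evaluated at
#' `x' + (k - 1/2)/steps * (x - x')` (midpoint rule). Satisfies completeness:
#' the attributions over both branch images sum to `f(x) - f(x')` up to the
#' Riemann discretization error, which shrinks as `steps` grows.
#'
#' @inheritParams gradient_saliency
#' @param baseline Baseline pair (same structure as `pair`); default the
#'   all-zero (all-'N') image, the natural "no sequence" reference under this
#'   encoding.
#' @param steps Number of integration steps (default 50, >= 2).
#' @return An `ot_attribution` (signed) with attributes `completeness_gap`
#'   (absolute error of the completeness identity) and `delta_f`.
#' @export
integrated_gradients <- function(model, pair, head = "classification",
                                 baseline = NULL, steps = 50L) {
  if (inherits(model, "ot_fit")) model <- model$model
  stopifnot(steps >= 2)
  p <- as_pair_matrices(pair)
  L <- ncol(p$target)
  b <- if (is.null(baseline)) {
    list(target = matrix(0, 5, L), offtarget = matrix(0, 5, L))
  } else {
    as_pair_matrices(baseline)
  }
  if (!all(dim(b$target) == dim(p$target))) abort("baseline shape mismatch")
  rt <- img_to_rows(p$target); bt <- img_to_rows(b$target)
  ro <- img_to_rows(p$offtarget); bo <- img_to_rows(b$offtarget)
  alphas <- (seq_len(steps) - 0.5) / steps
  batch_t <- stack_rows(lapply(alphas, function(a) bt + a * (rt - bt)))
  batch_o <- stack_rows(lapply(alphas, function(a) bo + a * (ro - bo)))
  g <- input_gradients(model, batch_t, batch_o, steps, head)
  mean_gt <- Reduce(`+`, split_rows(g$target, steps, L)) / steps
  mean_go <- Reduce(`+`, split_rows(g$offtarget, steps, L)) / steps
  ig_t <- (rt - bt) * mean_gt
  ig_o <- (ro - bo) * mean_go
  f_x <- input_gradients(model, rt, ro, 1L, head)$output
  f_b <- input_gradients(model, bt, bo, 1L, head)$output
  out <- new_attribution(rows_to_img(ig_t, L), rows_to_img(ig_o, L),
                         "integrated_gradients", head,
                         baseline = list(type = if (is.null(baseline))
                           "zero" else "custom", steps = steps))
  attr(out, "delta_f") <- f_x - f_b
  attr(out, "completeness_gap") <- abs(sum(ig_t) + sum(ig_o) - (f_x - f_b))
  out
}

#' Expected gradients
#'
#' Monte-Carlo SHAP-style attribution: averages
#' `(x - x~) * d f / d x` at `x~ + alpha (x - x~)` over baselines `x~` drawn
#' from a background set and `alpha ~ U(0,1)`. With a single background pair
#' it converges to [integrated_gradients()] with that baseline as the number
#' of samples grows.
#'
#' @inheritParams gradient_saliency
#' @param background An `ot_tensors` object (or list of pairs) supplying the
#'   background distribution.
#' @param n_samples Number of Monte-Carlo samples (default 100).
#' @param seed Seed for baseline and alpha draws.
#' @return A signed `ot_attribution`.
#' @export
expected_gradients <- function(model, pair, head = "classification",
                               background, n_samples = 100L, seed = 1L) {
  if (inherits(model, "ot_fit")) model <- model$model
  p <- as_pair_matrices(pair)
  L <- ncol(p$target)
  if (inherits(background, "ot_tensors")) {
    nb <- length(background$label)
    bg <- lapply(seq_len(nb), function(i)
      as_pair_matrices(subset_tensors(background, i)))
  } else {
    bg <- lapply(background, as_pair_matrices)
  }
  if (length(bg) == 0) abort("background must be non-empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pick <- sample.int(length(bg), n_samples, replace = TRUE)
  alpha <- runif(n_samples)
  rt <- img_to_rows(p$target)
  ro <- img_to_rows(p$offtarget)
  bts <- lapply(bg, function(q) img_to_rows(q$target))
  bos <- lapply(bg, function(q) img_to_rows(q$offtarget))
  batch_t <- stack_rows(lapply(seq_len(n_samples), function(s)
    bts[[pick[s]]] + alpha[s] * (rt - bts[[pick[s]]])))
  batch_o <- stack_rows(lapply(seq_len(n_samples), function(s)
    bos[[pick[s]]] + alpha[s] * (ro - bos[[pick[s]]])))
  g <- input_gradients(model, batch_t, batch_o, n_samples, head)
  gt <- split_rows(g$target, n_samples, L)
  go <- split_rows(g$offtarget, n_samples, L)
  acc_t <- matrix(0, L, 5)
  acc_o <- matrix(0, L, 5)
  for (s in seq_len(n_samples)) {
    acc_t <- acc_t + (rt - bts[[pick[s]]]) * gt[[s]]
    acc_o <- acc_o + (ro - bos[[pick[s]]]) * go[[s]]
  }
  new_attribution(rows_to_img(acc_t / n_samples, L),
                  rows_to_img(acc_o / n_samples, L),
                  "expected_gradients", head,
                  baseline = list(type = "background",
                                  n_background = length(bg),
                                  n_samples = n_samples))
}

#' Average attribution maps
#'
#' Elementwise mean of maps of identical shape and method, e.g. the
#' class-averaged map over all positive off-targets of one target site.
#'
#' @param maps List of `ot_attribution` objects.
#' @return An `ot_attribution` whose `n` records the number averaged.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  m0 <- maps[[1]]
  for (m in maps) {
    stopifnot(inherits(m, "ot_attribution"))
    if (!identical(dim(m$target), dim(m0$target)) ||
        !identical(m$method, m0$method)) {
      abort("maps must share shape and method to be averaged")
    }
  }
  k <- length(maps)
  new_attribution(
    Reduce(`+`, lapply(maps, function(m) m$target)) / k,
    Reduce(`+`, lapply(maps, function(m) m$offtarget)) / k,
    m0$method, m0$head, m0$baseline, n = sum(vapply(maps, function(m)
      m$n, numeric(1)))
  )
}

#' Per-position sequence view of an attribution map
#'
#' Collapses the alphabet axis to the score of the occupied cell in every
#' column, alongside the aligned bases and difference calls, so the map can
#' be read along the sequence.
#'
#' @param map An `ot_attribution`.
#' @param ap The `ot_aligned_pair` the map was computed for.
#' @return A tibble: `column`, `position` (negative for padding), `padding`,
#'   `target_base`, `offtarget_base`, `call`, `score_target`,
#'   `score_offtarget`.
#' @export
sequence_view <- function(map, ap) {
  stopifnot(inherits(map, "ot_attribution"), inherits(ap, "ot_aligned_pair"))
  L <- ncol(map$target)
  w <- nchar(ap$target_aln)
  if (w > L) abort("aligned pair is wider than the attribution map")
  P <- L - w
  labels <- c(if (P > 0) seq(-P, -1L) else integer(0),
              alignment_position_labels(ap$target_aln))
  tc <- c(rep("N", P), strsplit(ap$target_aln, "")[[1]])
  oc <- c(rep("N", P), strsplit(ap$offtarget_aln, "")[[1]])
  calls <- c(rep(NA_character_, P), ap$diff_calls)
  cell <- function(m, chars) {
    vapply(seq_len(L), function(j) {
      k <- match(chars[j], OT_ALPHABET)
      if (is.na(k)) NA_real_ else m[k, j]
    }, numeric(1))
  }
  tibble(column = seq_len(L), position = labels, padding = seq_len(L) <= P,
         target_base = tc, offtarget_base = oc, call = calls,
         score_target = cell(map$target, tc),
         score_offtarget = cell(map$offtarget, oc))
}
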