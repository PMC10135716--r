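# One-hot "image" encoding. Each sequence becomes a 5 x L binary matrix
# (rows A, C, G, T, gap). Sequences shorter than L are front-padded with 'N';
# an 'N' column is all-zero so padding carries no signal. Columns are
# numbered from the PAM-distal end towards the PAM (1..20 protospacer,
# 21..23 PAM); padding columns are numbered negatively.

#' Front-pad a sequence with N
#'
#' @param seq Sequence string (possibly gapped).
#' @param L Padded length; must be >= `nchar(seq)`.
#' @return The padded string `N...N + seq`.
#' @export
pad_front <- function(seq, L) {
  n <- nchar(seq)
  if (n > L) abort(paste0("sequence length ", n, " exceeds padded length ", L))
  paste0(strrep("N", L - n), seq)
}

#' One-hot encode a sequence as an image
#'
#' @param seq String over `{A,C,G,T,-,N}`; front-padded with `N` to `L`.
#' @param L Padded length (default 26 = 23 + up to 3 gap columns). Longer
#'   sequences are rejected, never truncated.
#' @param position_labels Optional integer labels per column; by default
#'   padding columns get `-P..-1` and sequence columns are numbered
#'   sequentially `1..k` (gap columns included). [encode_pair()] overrides
#'   this with target-anchored positions.
#' @return A 5 x L binary matrix of class `ot_image` with rownames
#'   `A,C,G,T,-` and a `position_labels` attribute.
#' @export
encode_seq <- function(seq, L = 26L, position_labels = NULL) {
  if (!grepl("^[ACGTN-]*$", seq)) {
    abort("sequence may only contain A, C, G, T, '-' and N")
  }
  padded <- pad_front(seq, L)
  chars <- strsplit(padded, "")[[1]]
  m <- matrix(0, nrow = 5L, ncol = L,
              dimnames = list(OT_ALPHABET, NULL))
  hit <- match(chars, OT_ALPHABET)   # NA for N
  occ <- which(!is.na(hit))
  m[cbind(hit[occ], occ)] <- 1
  if (is.null(position_labels)) {
    # leading N's (explicit or added here) are padding, numbered negatively
    P <- nchar(padded) - nchar(sub("^N*", "", padded))
    position_labels <- c(if (P > 0) seq(-P, -1L) else integer(0),
                         seq_len(L - P))
  }
  stopifnot(length(position_labels) == L)
  structure(m, position_labels = as.integer(position_labels),
            class = c("ot_image", "matrix", "array"))
}

#' Decode a one-hot image back to its sequence
#'
#' Inverse of [encode_seq()] including the padding: all-zero columns decode
#' to `N`.
#'
#' @param img An `ot_image` matrix.
#' @return The padded sequence string.
#' @export
decode_image <- function(img) {
  stopifnot(is.matrix(img), nrow(img) == 5L)
  paste(apply(img, 2, function(col) {
    k <- which(col == 1)
    if (length(k) == 0) "N" else OT_ALPHABET[k]
  }), collapse = "")
}

# Target-anchored position labels for the columns of an alignment: each
# column is labelled with the 1-based index of the target base it contains;
# a gap-in-target column (inserted off-target base) takes the label of the
# next target base (the insertion sits immediately 5' of it).
alignment_position_labels <- function(target_aln) {
  tc <- strsplit(target_aln, "")[[1]]
  pos <- cumsum(tc != "-")
  ins <- tc == "-"
  if (any(ins)) pos[ins] <- pmin(pos[ins] + 1L, max(pos))
  as.integer(pos)
}

#' Encode an aligned pair as two images
#'
#' Both members are padded to the same width so columns correspond; both
#' carry target-anchored position labels (padding negative, then 1..23 by
#' target base, with gap-in-target columns labelled by the next target base).
#'
#' @param ap An `ot_aligned_pair` from [align_pair()].
#' @param L Padded length (default 26).
#' @return A list with elements `target` and `offtarget`, each an `ot_image`.
#' @export
encode_pair <- function(ap, L = 26L) {
  stopifnot(inherits(ap, "ot_aligned_pair"))
  w <- nchar(ap$target_aln)
  if (w > L) abort(paste0("aligned width ", w, " exceeds padded length ", L))
  P <- L - w
  labels <- c(if (P > 0) seq(-P, -1L) else integer(0),
              alignment_position_labels(ap$target_aln))
  list(target = encode_seq(ap$target_aln, L, position_labels = labels),
       offtarget = encode_seq(ap$offtarget_aln, L, position_labels = labels))
}

#' Encode an aligned dataset into model tensors
#'
#' Converts every record of an aligned dataset into paired one-hot images and
#' stacks them into arrays ready for the network.
#'
#' @param ds Aligned off-target dataset (see [align_dataset()]); must carry
#'   `norm_activity` (see [normalize_read_counts()]).
#' @param L Padded length (default 26).
#' @return A list of class `ot_tensors`: `target` and `offtarget` arrays of
#'   dimension `n x 5 x L`, `label` (integer 0/1), `activity` (numeric),
#'   `position_labels` (n x L integer matrix) and the source tibble `records`.
#' @export
encode_dataset <- function(ds, L = 26L) {
  ds <- validate_dataset(ds, require_aligned = TRUE)
  if (!"norm_activity" %in% names(ds)) {
    abort("dataset lacks norm_activity; run normalize_read_counts() first")
  }
  n <- nrow(ds)
  tg <- array(0, dim = c(n, 5L, L))
  ot <- array(0, dim = c(n, 5L, L))
  pl <- matrix(NA_integer_, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    ap <- structure(list(target_aln = ds$target_aln[i],
                         offtarget_aln = ds$offtarget_aln[i]),
                    class = "ot_aligned_pair")
    imgs <- encode_pair(ap, L)
    tg[i, , ] <- imgs$target
    ot[i, , ] <- imgs$offtarget
    pl[i, ] <- attr(imgs$target, "position_labels")
  }
  structure(list(
    target = tg, offtarget = ot,
    label = as.integer(ds$label == "positive"),
    activity = as.numeric(ds$norm_activity),
    position_labels = pl,
    records = ds,
    L = as.integer(L)
  ), class = "ot_tensors")
}

#' @export
print.ot_tensors <- function(x, ...) {
  cat(sprintf("<ot_tensors> %d pairs, 5 x %d images (%d positive, %d negative)\n",
              length(x$label), x$L, sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

# Subset tensors by index (used by splitting / batching).
subset_tensors <- function(tens, idx) {
  structure(list(
    target = tens$target[idx, , , drop = FALSE],
    offtarget = tens$offtarget[idx, , , drop = FALSE],
    label = tens$label[idx],
    activity = tens$activity[idx],
    position_labels = tens$position_labels[idx, , drop = FALSE],
    records = tens$records[idx, , drop = FALSE],
    L = tens$L
  ), class = "ot_tensors")
}
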