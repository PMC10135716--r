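# Independent oracles used to cross-check the implementations.

# Exhaustive global-alignment score: plain recursion over all alignments
# (diagonal / gap-in-offtarget / gap-in-target at every step) with affine
# scoring carried along the path. Exponential; only for short sequences.
oracle_align_score <- function(target, offtarget, match = 2, mismatch = -1,
                               gap_open = -2, gap_extend = -1) {
  tc <- strsplit(target, "")[[1]]
  oc <- strsplit(offtarget, "")[[1]]
  nt <- length(tc)
  no <- length(oc)
  rec <- function(i, j, last) {
    if (i > nt && j > no) return(0)
    best <- -Inf
    if (i <= nt && j <= no) {
      s <- if (tc[i] == oc[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= nt) {
      pen <- if (last == "X") gap_extend else gap_open
      best <- max(best, pen + rec(i + 1L, j, "X"))
    }
    if (j <= no) {
      pen <- if (last == "Y") gap_extend else gap_open
      best <- max(best, pen + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# Biostrings score oracle for the same affine scheme. Biostrings charges a
# gap of length k as gapOpening + k * gapExtension, so our per-first-char
# gap_open maps to gapOpening = gap_extend - gap_open (as costs).
oracle_align_score_biostrings <- function(target, offtarget, match = 2,
                                          mismatch = -1, gap_open = -2,
                                          gap_extend = -1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    offtarget, target, type = "global", substitutionMatrix = sm,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend,
    scoreOnly = TRUE
  )
}

# Brute-force confusion tally by explicit looping.
oracle_confusion <- function(labels01, probs, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (k in seq_along(labels01)) {
    pred <- probs[k] >= threshold
    if (pred && labels01[k] == 1) tp <- tp + 1L
    if (pred && labels01[k] == 0) fp <- fp + 1L
    if (!pred && labels01[k] == 0) tn <- tn + 1L
    if (!pred && labels01[k] == 1) fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

oracle_metrics <- function(cc) {
  TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / den else 0
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

# Average precision by direct summation over the ranked list.
oracle_average_precision <- function(labels01, probs) {
  ord <- order(probs, decreasing = TRUE)
  y <- labels01[ord]
  p <- probs[ord]
  npos <- sum(y)
  ap <- 0
  prev_recall <- 0
  k <- 1
  n <- length(y)
  while (k <= n) {
    # advance over ties
    k2 <- k
    while (k2 < n && p[k2 + 1] == p[k]) k2 <- k2 + 1
    tp <- sum(y[1:k2])
    prec <- tp / k2
    rec <- tp / npos
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
    k <- k2 + 1
  }
  ap
}

# Independent window scan: Hamming-distance candidates of width 23 on both
# strands with an allowed PAM, by explicit looping.
oracle_candidate_scan <- function(genome, target, max_diff,
                                  pams = c("NGG", "NGA", "NAG")) {
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  tails <- substr(pams, 2, 3)
  hits <- list()
  for (nm in names(genome)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genome[[nm]] else rc(genome[[nm]])
      n <- nchar(s)
      if (n < 23) next
      for (st in 1:(n - 22)) {
        w <- substr(s, st, st + 22)
        if (grepl("[^ACGT]", w)) next
        if (!substr(w, 22, 23) %in% tails) next
        d <- sum(strsplit(w, "")[[1]] != strsplit(target, "")[[1]])
        if (d <= max_diff) {
          hits[[length(hits) + 1]] <- list(seqname = nm, strand = strand,
                                           start = st, seq = w)
        }
      }
    }
  }
  hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
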