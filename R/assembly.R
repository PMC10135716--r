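# Negative-candidate enumeration and dataset splitting. The candidate scan is
# a brute-force surrogate for a dedicated off-target search tool: every
# PAM-adjacent window on either strand within the allowed edit distance of
# the target becomes a candidate.

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", sapply(lapply(strsplit(seq, ""), rev),
                                  paste, collapse = ""))
}

#' Read genome segments from a FASTA file
#'
#' @param path FASTA file with one or more records.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Enumerate candidate off-target sites in genome sequence
#'
#' Slides windows over both strands (minus-strand windows are
#' reverse-complemented into protospacer orientation), keeps windows whose
#' 3'-terminal trinucleotide matches an allowed PAM class and whose aligned
#' distance (mismatches + gaps) to the target does not exceed `max_diff`.
#' Window lengths 22..24 admit single-base bulges. Output order is
#' deterministic: by sequence name, strand (+ then -), then window start.
#'
#' @param genome Named character vector of sequences over `{A,C,G,T,N}`
#'   (see [read_genome_fasta()]).
#' @param target 23-nt target (protospacer + NGG PAM).
#' @param max_diff Maximum mismatches + gaps (default 9).
#' @param pams Allowed PAM classes for the candidate, compared with the first
#'   base wildcarded (default `c("NGG","NGA","NAG")`).
#' @param params [alignment_params()] used for the distance computation.
#' @return A tibble with `seqname`, `strand`, `start` (1-based, on the given
#'   strand's forward coordinates), `offtarget_seq`, `pam`, `n_mismatch`,
#'   `n_gap`.
#' @export
enumerate_candidates <- function(genome, target, max_diff = 9,
                                 pams = c("NGG", "NGA", "NAG"),
                                 params = alignment_params()) {
  if (length(genome) == 0 || all(nchar(genome) == 0)) abort("empty genome")
  assert_dna(target, "target")
  if (nchar(target) != OT_TARGET_LEN) abort("target must be 23 nt")
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  pam_tail <- substr(pams, 2, 3)
  out <- list()
  for (nm in names(genome)) {
    for (strand in c("+", "-")) {
      s <- toupper(genome[[nm]])
      if (strand == "-") s <- revcomp(s)
      slen <- nchar(s)
      for (w in 22:24) {
        if (slen < w) next
        starts <- seq_len(slen - w + 1)
        wins <- substring(s, starts, starts + w - 1)
        keep <- grepl("^[ACGT]+$", wins) &
          substring(wins, w - 1, w) %in% pam_tail
        for (k in which(keep)) {
          ap <- align_pair(target, wins[k], params)
          d <- ap$n_mismatch + ap$n_gap
          if (d <= max_diff) {
            out[[length(out) + 1]] <- tibble(
              seqname = nm, strand = strand, start = starts[k], width = w,
              offtarget_seq = wins[k],
              pam = paste0("N", substring(wins[k], w - 1, w)),
              n_mismatch = ap$n_mismatch, n_gap = ap$n_gap
            )
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(seqname = character(0), strand = character(0),
                  start = integer(0), width = integer(0),
                  offtarget_seq = character(0), pam = character(0),
                  n_mismatch = integer(0), n_gap = integer(0)))
  }
  bind_rows(out) %>%
    distinct(.data$seqname, .data$strand, .data$start, .data$width,
             .keep_all = TRUE) %>%
    arrange(.data$seqname, .data$strand, .data$start, .data$width)
}

#' Split specification
#'
#' @param train,val,test Fractions summing to 1 (default 0.8/0.1/0.1, the
#'   standard train/validation/test regimen).
#' @param seed Integer seed making the split reproducible.
#' @param stratify_by_label Preserve the class ratio within every split
#'   (default `TRUE`; with a ~20:1 imbalance this keeps validation metrics
#'   meaningful).
#' @return A list of class `ot_split_spec`.
#' @export
split_spec <- function(train = 0.8, val = 0.1, test = 0.1, seed = 1L,
                       stratify_by_label = TRUE) {
  fr <- c(train, val, test)
  if (any(fr <= 0)) abort("all split fractions must be positive")
  if (abs(sum(fr) - 1) > 1e-8) abort("split fractions must sum to 1")
  structure(list(train = train, val = val, test = test,
                 seed = as.integer(seed),
                 stratify_by_label = isTRUE(stratify_by_label)),
            class = "ot_split_spec")
}

partition_indices <- function(n, fr) {
  idx <- sample(n)
  n_train <- round(fr[1] * n)
  n_val <- round(fr[2] * n)
  n_val <- min(n_val, n - n_train)
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[setdiff(seq_len(n), seq_len(n_train + n_val))])
}

#' Split a dataset into train/validation/test sets
#'
#' Produces a disjoint, exhaustive partition, reproducible given the seed;
#' when stratified, each class is partitioned separately so label proportions
#' are preserved within rounding.
#'
#' @param ds Off-target dataset.
#' @param spec A [split_spec()].
#' @return A named list of three tibbles: `train`, `val`, `test`.
#' @export
make_splits <- function(ds, spec = split_spec()) {
  ds <- validate_dataset(ds)
  if (nrow(ds) == 0) abort("cannot split an empty dataset")
  fr <- c(spec$train, spec$val, spec$test)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  if (spec$stratify_by_label) {
    parts <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cls in unique(ds$label)) {
      rows <- which(ds$label == cls)
      if (length(rows) < 3) {
        abort(paste0("class '", cls, "' has fewer than 3 records; ",
                     "cannot stratify"))
      }
      p <- partition_indices(length(rows), fr)
      parts$train <- c(parts$train, rows[p$train])
      parts$val <- c(parts$val, rows[p$val])
      parts$test <- c(parts$test, rows[p$test])
    }
  } else {
    parts <- partition_indices(nrow(ds), fr)
  }
  lapply(parts, function(ix) ds[sort(ix), , drop = FALSE])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Balanced class weights
#'
#' The standard balanced heuristic `weight(c) = N_total / (2 * N_c)`: the
#' minority class is up-weighted above 1 and the majority class down-weighted
#' below 1, equalizing the two classes' contributions to the loss.
#'
#' @param ds Off-target dataset (or any data frame with a `label` column).
#' @return Named numeric vector with elements `positive` and `negative`.
#' @export
class_weights <- function(ds) {
  if (!"label" %in% names(ds)) abort("dataset lacks a label column")
  n_pos <- sum(ds$label == "positive")
  n_neg <- sum(ds$label == "negative")
  if (n_pos == 0 || n_neg == 0) {
    abort("class weights require both classes to be present")
  }
  n <- n_pos + n_neg
  c(positive = n / (2 * n_pos), negative = n / (2 * n_neg))
}
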