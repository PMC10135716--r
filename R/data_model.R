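# Off-target datasets are plain tibbles with one row per (target, candidate
# off-target) pair. Required columns:
#   target_id     chr  identifier of the guide/target site
#   target_seq    chr  23 nt = 20-nt protospacer + NGG PAM, PAM-distal -> PAM
#   offtarget_seq chr  raw (unaligned) candidate sequence over {A,C,G,T}
#   read_count    int  experimental read count (0 for negatives)
#   label         chr  "positive" (cleaved) or "negative" (genome candidate,
#                      no cleavage observed)
# Optional: norm_activity in [0,1] (per-target max-scaled read count).

OT_REQUIRED_COLS <- c("target_id", "target_seq", "offtarget_seq",
                      "read_count", "label")

#' Validate an off-target dataset
#'
#' Checks that `ds` carries the required columns with the expected types and
#' that the core invariants hold: target sequences are 23 nt and end in GG
#' (the canonical NGG PAM), labels are "positive"/"negative", read counts are
#' non-negative integers, and negatives have zero read count.
#'
#' @param ds A data frame of off-target records.
#' @param require_aligned Also require alignment columns (`target_aln`,
#'   `offtarget_aln`, `n_mismatch`, `n_gap`) as produced by [align_dataset()].
#' @return `ds` as a tibble, invisibly usable in pipes.
#' @export
validate_dataset <- function(ds, require_aligned = FALSE) {
  if (!is.data.frame(ds)) abort("`ds` must be a data frame of off-target records")
  missing <- setdiff(OT_REQUIRED_COLS, names(ds))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  ds <- as_tibble(ds)
  if (nrow(ds) == 0) return(ds)
  bad_label <- !ds$label %in% c("positive", "negative")
  if (any(bad_label)) {
    abort(paste0("label must be 'positive' or 'negative'; offending row(s): ",
                 paste(head(which(bad_label), 5), collapse = ", ")))
  }
  rc <- ds$read_count
  bad_rc <- !is.finite(rc) | rc < 0 | rc != floor(rc)
  if (any(bad_rc)) {
    abort(paste0("read_count must be a non-negative integer; offending row(s): ",
                 paste(head(which(bad_rc), 5), collapse = ", ")))
  }
  neg_with_reads <- ds$label == "negative" & rc > 0
  if (any(neg_with_reads)) {
    abort(paste0("negative records must have read_count 0; offending row(s): ",
                 paste(head(which(neg_with_reads), 5), collapse = ", ")))
  }
  bad_len <- nchar(ds$target_seq) != OT_TARGET_LEN
  if (any(bad_len)) {
    abort(paste0("target_seq must be ", OT_TARGET_LEN, " nt; offending row(s): ",
                 paste(head(which(bad_len), 5), collapse = ", ")))
  }
  bad_pam <- substr(ds$target_seq, 22, 23) != "GG"
  if (any(bad_pam)) {
    abort(paste0("target_seq must end in the canonical 'GG' PAM dinucleotide; ",
                 "offending row(s): ",
                 paste(head(which(bad_pam), 5), collapse = ", ")))
  }
  if ("norm_activity" %in% names(ds)) {
    na_ok <- is.na(ds$norm_activity) |
      (ds$norm_activity >= 0 & ds$norm_activity <= 1)
    if (!all(na_ok)) abort("norm_activity must lie in [0, 1]")
  }
  if (require_aligned) {
    aln_cols <- c("target_aln", "offtarget_aln", "n_mismatch", "n_gap")
    missing_aln <- setdiff(aln_cols, names(ds))
    if (length(missing_aln) > 0) {
      abort(paste0("dataset is not aligned; run align_dataset() first ",
                   "(missing: ", paste(missing_aln, collapse = ", "), ")"))
    }
  }
  ds
}

#' Read an off-target table
#'
#' Reads a TSV or CSV table of target/off-target pairs with header columns
#' `target_id, target_seq, offtarget_seq, read_count, label`. Lines starting
#' with `#` are treated as comments. Rows whose sequences contain characters
#' outside `{A,C,G,T,N}` are rejected (dropped with a warning).
#'
#' @param path Path to the table.
#' @param dialect `"auto"` (by file extension, default), `"tsv"` or `"csv"`.
#' @return A tibble of validated off-target records.
#' @export
read_offtarget_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  header <- reader(path, comment = "#", n_max = 0, col_types = readr::cols(),
                   progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(OT_REQUIRED_COLS, names(header))
  if (length(missing) > 0) {
    abort(paste0("table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ds <- reader(path, comment = "#", col_types = readr::cols(
    target_id = readr::col_character(),
    target_seq = readr::col_character(),
    offtarget_seq = readr::col_character(),
    read_count = readr::col_double(),
    label = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE, show_col_types = FALSE)
  bad_rc <- !is.finite(ds$read_count) | ds$read_count < 0 |
    ds$read_count != floor(ds$read_count)
  if (any(bad_rc)) {
    abort(paste0("malformed read_count at data row(s): ",
                 paste(head(which(bad_rc), 5), collapse = ", ")))
  }
  valid_seq <- function(s) grepl("^[ACGTN]*$", s)
  keep <- valid_seq(ds$target_seq) & valid_seq(ds$offtarget_seq)
  if (any(!keep)) {
    warn(paste0("rejected ", sum(!keep),
                " row(s) with characters outside {A,C,G,T,N}"))
    ds <- ds[keep, , drop = FALSE]
  }
  validate_dataset(ds)
}

#' Write an off-target table
#'
#' Inverse of [read_offtarget_table()]; a read/write/read round trip
#' reproduces the dataset exactly.
#'
#' @param ds Off-target dataset tibble.
#' @param path Output path.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return `ds`, invisibly.
#' @export
write_offtarget_table <- function(ds, path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  ds <- validate_dataset(ds)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  writer <- if (dialect == "csv") readr::write_csv else readr::write_tsv
  writer(ds, path, progress = FALSE)
  invisible(ds)
}

#' Normalize read counts per target
#'
#' For each target independently, scales read counts to `[0,1]` by the
#' maximum read count observed for that target (`norm_activity =
#' read_count / max(read_count)`); negatives receive 0. The normalized value
#' is the regression response of the multitask model. Idempotent.
#'
#' @param ds Off-target dataset.
#' @return `ds` with a `norm_activity` column.
#' @export
normalize_read_counts <- function(ds) {
  ds <- validate_dataset(ds)
  if (nrow(ds) == 0) return(mutate(ds, norm_activity = numeric(0)))
  mx <- ds %>%
    group_by(.data$target_id) %>%
    summarise(.max_rc = max(.data$read_count), .groups = "drop")
  dead <- mx$target_id[mx$.max_rc == 0]
  if (length(dead) > 0) {
    abort(paste0("target(s) with all-zero read counts: ",
                 paste(dead, collapse = ", ")))
  }
  ds %>%
    left_join(mx, by = "target_id") %>%
    mutate(norm_activity = if_else(.data$label == "negative", 0,
                                   .data$read_count / .data$.max_rc)) %>%
    select(-".max_rc")
}

#' Collapse duplicates and resolve conflicting labels
#'
#' Exact duplicate `(target_id, offtarget_seq)` pairs are collapsed to one
#' record. A positive label dominates (experimental evidence of cleavage
#' outweighs a predicted-inactive call), and the maximum read count is kept;
#' in particular any negative matching a positive is removed.
#'
#' @param ds Off-target dataset.
#' @return Deduplicated dataset tibble.
#' @export
deduplicate_and_relabel <- function(ds) {
  ds <- validate_dataset(ds)
  if (nrow(ds) == 0) return(ds)
  extra <- setdiff(names(ds), c("target_id", "offtarget_seq",
                                "read_count", "label"))
  ds %>%
    group_by(.data$target_id, .data$offtarget_seq) %>%
    arrange(dplyr::desc(.data$label == "positive"),
            dplyr::desc(.data$read_count), .by_group = TRUE) %>%
    summarise(
      label = if_else(any(.data$label == "positive"), "positive", "negative"),
      read_count = max(.data$read_count),
      across(all_of(extra), first),
      .groups = "drop"
    ) %>%
    select(all_of(union(names(ds), names(.))))
}

#' Expand positives in proportion to read count
#'
#' Materializes the read-count weighting by replicating each positive record
#' `round(read_count / min positive read_count of its target)` times
#' (floor 1). The propensity functions use continuous weights instead and are
#' exactly equivalent for proportional integer weights; this expansion exists
#' for cross-checking and for workflows that require unweighted counting.
#'
#' @param ds Off-target dataset.
#' @return Expanded dataset tibble (negatives are left unreplicated).
#' @export
weighted_expansion <- function(ds) {
  ds <- validate_dataset(ds)
  if (nrow(ds) == 0) return(ds)
  ds %>%
    group_by(.data$target_id) %>%
    mutate(.minpos = {
      pos <- .data$read_count[.data$label == "positive"]
      if (length(pos) == 0) NA_real_ else min(pos[pos > 0])
    }) %>%
    ungroup() %>%
    mutate(.times = if_else(
      .data$label == "positive" & !is.na(.data$.minpos),
      pmax(1, round(.data$read_count / .data$.minpos)),
      1
    )) %>%
    tidyr::uncount(.data$.times) %>%
    select(-".minpos")
}
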