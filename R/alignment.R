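# Bulge-aware pairwise alignment. Cas9 tolerates DNA/RNA bulges in the
# guide-DNA heteroduplex; representing them as alignment gaps lets the
# downstream encodings and propensity profiles see them. The dynamic program
# (affine gaps, Gotoh) lives in src/align.cpp.

#' Alignment scoring parameters
#'
#' @param match Score for an identical aligned pair (default 2).
#' @param mismatch Penalty (<= 0) for a substitution (default -1).
#' @param gap_open Penalty (<= 0) for opening a gap (default -2).
#' @param gap_extend Penalty (<= 0) for extending a gap (default -1); a gap of
#'   length k scores `gap_open + (k-1) * gap_extend`.
#' @param max_total_diff Maximum tolerated mismatches + gaps for
#'   [passes_distance_filter()] (default 9).
#' @param lock_pam Forbid gaps within the 3-nt PAM frame at the target 3' end
#'   (default `TRUE`), keeping the NGG columns intact.
#' @return A list of class `ot_alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -1, gap_open = -2,
                             gap_extend = -1, max_total_diff = 9,
                             lock_pam = TRUE) {
  if (match <= mismatch) abort("match score must exceed mismatch penalty")
  if (mismatch > 0) abort("mismatch penalty must be <= 0")
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    abort("need gap_open <= gap_extend <= 0")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 max_total_diff = as.integer(max_total_diff),
                 lock_pam = isTRUE(lock_pam)),
            class = "ot_alignment_params")
}

assert_dna <- function(seq, what, allow_gap = FALSE) {
  pat <- if (allow_gap) "^[ACGT-]+$" else "^[ACGT]+$"
  if (length(seq) != 1 || is.na(seq) || !grepl(pat, seq)) {
    abort(paste0(what, " must be a non-empty DNA string over {A,C,G,T}",
                 if (allow_gap) " (and '-')"))
  }
}

#' Per-column difference calls of an alignment
#'
#' @param target_aln,offtarget_aln Gapped aligned strings of equal length.
#' @return Character vector over `match`, `mismatch`, `gap_in_target`
#'   (extra off-target base, a DNA bulge), `gap_in_offtarget` (missing
#'   off-target base, an RNA bulge).
#' @export
diff_calls <- function(target_aln, offtarget_aln) {
  tc <- strsplit(target_aln, "")[[1]]
  oc <- strsplit(offtarget_aln, "")[[1]]
  if (length(tc) != length(oc)) abort("aligned strings differ in length")
  if (any(tc == "-" & oc == "-")) abort("column gapped on both sides")
  dplyr::case_when(
    tc == "-" ~ "gap_in_target",
    oc == "-" ~ "gap_in_offtarget",
    tc == oc ~ "match",
    TRUE ~ "mismatch"
  )
}

#' Align a target against a candidate off-target
#'
#' Optimal global alignment under affine-gap scoring with a deterministic
#' tie-break (prefer an aligned pair over a gap; among equal-scoring gap
#' placements the gap is placed as 3'-ward as possible), so results are
#' reproducible. With `lock_pam = TRUE` gaps never fall inside the target's
#' 3-nt PAM frame.
#'
#' @param target Target DNA string (23 nt in the standard pipeline).
#' @param offtarget Candidate off-target DNA string.
#' @param params An [alignment_params()] object.
#' @return A list of class `ot_aligned_pair` with `target_aln`,
#'   `offtarget_aln`, `diff_calls`, `n_mismatch`, `n_gap`, `score`.
#' @export
align_pair <- function(target, offtarget, params = alignment_params()) {
  assert_dna(target, "target")
  assert_dna(offtarget, "offtarget")
  if (nchar(target) > 40 || nchar(offtarget) > 40) {
    abort("sequences longer than 40 nt are not supported")
  }
  res <- align_pair_cpp(target, offtarget, params$match, params$mismatch,
                        params$gap_open, params$gap_extend, params$lock_pam)
  calls <- diff_calls(res$target_aln, res$offtarget_aln)
  structure(list(
    target_aln = res$target_aln,
    offtarget_aln = res$offtarget_aln,
    diff_calls = calls,
    n_mismatch = sum(calls == "mismatch"),
    n_gap = sum(calls %in% c("gap_in_target", "gap_in_offtarget")),
    score = res$score
  ), class = "ot_aligned_pair")
}

#' @export
print.ot_aligned_pair <- function(x, ...) {
  cat(x$target_aln, "\n")
  marks <- c(match = "|", mismatch = ".", gap_in_target = " ",
             gap_in_offtarget = " ")
  cat(paste(marks[x$diff_calls], collapse = ""), "\n")
  cat(x$offtarget_aln, "\n")
  cat(sprintf("mismatches: %d  gaps: %d  score: %g\n",
              x$n_mismatch, x$n_gap, x$score))
  invisible(x)
}

#' Distance filter on an aligned pair
#'
#' `TRUE` iff mismatches + gaps do not exceed `params$max_total_diff`
#' (default 9, the ceiling used when assembling negative candidate sets).
#'
#' @param ap An `ot_aligned_pair` from [align_pair()].
#' @param params An [alignment_params()] object.
#' @return Logical scalar.
#' @export
passes_distance_filter <- function(ap, params = alignment_params()) {
  stopifnot(inherits(ap, "ot_aligned_pair"))
  (ap$n_mismatch + ap$n_gap) <= params$max_total_diff
}

#' Align every record of a dataset
#'
#' Adds `target_aln`, `offtarget_aln`, `diff_string` (one character per
#' aligned column: `M` match, `X` mismatch, `D` gap in off-target, `I` gap in
#' target), `n_mismatch`, `n_gap` and `aln_score` columns.
#'
#' @param ds Off-target dataset.
#' @param params An [alignment_params()] object.
#' @return The aligned dataset tibble.
#' @export
align_dataset <- function(ds, params = alignment_params()) {
  ds <- validate_dataset(ds)
  if (nrow(ds) == 0) {
    return(mutate(ds, target_aln = character(0), offtarget_aln = character(0),
                  diff_string = character(0), n_mismatch = integer(0),
                  n_gap = integer(0), aln_score = numeric(0)))
  }
  code <- c(match = "M", mismatch = "X", gap_in_offtarget = "D",
            gap_in_target = "I")
  aps <- purrr::map2(ds$target_seq, ds$offtarget_seq,
                     function(t, o) align_pair(t, o, params))
  ds %>% mutate(
    target_aln = purrr::map_chr(aps, "target_aln"),
    offtarget_aln = purrr::map_chr(aps, "offtarget_aln"),
    diff_string = purrr::map_chr(aps, function(a)
      paste(code[a$diff_calls], collapse = "")),
    n_mismatch = purrr::map_int(aps, function(a) as.integer(a$n_mismatch)),
    n_gap = purrr::map_int(aps, function(a) as.integer(a$n_gap)),
    aln_score = purrr::map_dbl(aps, "score")
  )
}
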