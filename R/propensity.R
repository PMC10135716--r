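# Count-based mismatch/bulge propensity analysis. Positions are numbered
# 1..23 from the PAM-distal end (1..20 protospacer, 21..23 PAM). Position 21
# is the 'N' of the NGG PAM: any base there counts as a match. Analyses can
# be weighted by the normalized cleavage frequency (norm_activity), so that
# each off-target contributes in proportion to how often Cas9 was observed to
# act on it.

# Explode an aligned dataset into one row per aligned column:
# record, target_id, position (target-anchored), target_base, offtarget_base,
# call, weight.
aligned_long <- function(ds, weights = c("none", "read_count")) {
  weights <- match.arg(weights)
  ds <- validate_dataset(ds, require_aligned = TRUE)
  if (nrow(ds) == 0) abort("empty dataset")
  if (weights == "read_count" && !"norm_activity" %in% names(ds)) {
    abort("read_count weighting requires norm_activity; run normalize_read_counts()")
  }
  tc <- strsplit(ds$target_aln, "")
  oc <- strsplit(ds$offtarget_aln, "")
  lens <- lengths(tc)
  bad <- which(lens != lengths(oc) | lens == 0)
  if (length(bad) > 0) {
    abort(paste0("record(s) not properly aligned: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  w <- if (weights == "read_count") ds$norm_activity else rep(1, nrow(ds))
  tibble(
    record = rep(seq_len(nrow(ds)), lens),
    target_id = rep(ds$target_id, lens),
    target_base = unlist(tc),
    offtarget_base = unlist(oc),
    position = unlist(lapply(ds$target_aln, alignment_position_labels)),
    weight = rep(w, lens)
  ) %>%
    mutate(call = dplyr::case_when(
      .data$target_base == "-" ~ "gap_in_target",
      .data$offtarget_base == "-" ~ "gap_in_offtarget",
      .data$position == OT_PAM_N_POS ~ "match",   # PAM 'N': never a mismatch
      .data$target_base == .data$offtarget_base ~ "match",
      TRUE ~ "mismatch"
    ))
}

#' Per-position mismatch profile
#'
#' Fraction of records with a substitution at each target position. Gap
#' columns are excluded from the mismatch denominator and are profiled
#' separately by [gap_profile()]. With `weights = "read_count"` every record
#' contributes its normalized cleavage frequency instead of 1.
#'
#' @param ds Aligned off-target dataset (typically the positive records).
#' @param weights `"none"` (default) or `"read_count"`.
#' @return A tibble with `position`, `n_total` (weighted denominator),
#'   `n_mismatch`, `mismatch_fraction`, `weighted`.
#' @export
mismatch_profile <- function(ds, weights = c("none", "read_count")) {
  weights <- match.arg(weights)
  lng <- aligned_long(ds, weights)
  lng %>%
    filter(!.data$call %in% c("gap_in_target", "gap_in_offtarget")) %>%
    group_by(.data$position) %>%
    summarise(
      n_total = sum(.data$weight),
      n_mismatch = sum(.data$weight[.data$call == "mismatch"]),
      .groups = "drop"
    ) %>%
    mutate(mismatch_fraction = if_else(.data$n_total > 0,
                                       .data$n_mismatch / .data$n_total, 0),
           weighted = weights == "read_count") %>%
    arrange(.data$position)
}

#' Per-position gap (bulge) profile
#'
#' Fraction of records carrying a gap call at each target position; a gap in
#' the off-target is an RNA bulge, a gap in the target a DNA bulge, and both
#' are counted. Insertions are assigned to the position of the next target
#' base.
#'
#' @inheritParams mismatch_profile
#' @return A tibble with `position`, `n_total`, `n_gap`, `gap_fraction`,
#'   `weighted`.
#' @export
gap_profile <- function(ds, weights = c("none", "read_count")) {
  weights <- match.arg(weights)
  lng <- aligned_long(ds, weights)
  per_rec <- lng %>%
    group_by(.data$record, .data$position) %>%
    summarise(
      weight = .data$weight[1],
      has_gap = any(.data$call %in% c("gap_in_target", "gap_in_offtarget")),
      .groups = "drop"
    )
  per_rec %>%
    group_by(.data$position) %>%
    summarise(
      n_total = sum(.data$weight),
      n_gap = sum(.data$weight[.data$has_gap]),
      .groups = "drop"
    ) %>%
    mutate(gap_fraction = if_else(.data$n_total > 0,
                                  .data$n_gap / .data$n_total, 0),
           weighted = weights == "read_count") %>%
    arrange(.data$position)
}

#' Nucleotide-resolved mismatch propensity
#'
#' For every (position, target base) combination: the percentage of records
#' that retain the expected base, the distribution of substituting bases, and
#' the percentage carrying a gap. Percentages sum to 100 per combination.
#' Combinations never observed in the data are flagged
#' (`flagged = TRUE`, `n_total = 0`) and carry no statistics.
#'
#' @inheritParams mismatch_profile
#' @return A tibble with `position`, `target_base`, `n_total`,
#'   `no_mismatch_pct`, `sub_A`, `sub_C`, `sub_G`, `sub_T` (percent
#'   substituted by each base), `gap_pct`, `most_substituted`,
#'   `most_substituted_pct`, `tie`, `flagged`, `weighted`.
#' @export
nucleotide_mismatch_profile <- function(ds, weights = c("none", "read_count")) {
  weights <- match.arg(weights)
  lng <- aligned_long(ds, weights) %>%
    filter(.data$call != "gap_in_target")  # no target base to attribute
  positions <- sort(unique(lng$position))
  grid <- tidyr::expand_grid(position = positions,
                             target_base = c("A", "C", "G", "T"))
  stats <- lng %>%
    group_by(.data$position, .data$target_base) %>%
    summarise(
      n_total = sum(.data$weight),
      w_match = sum(.data$weight[.data$call == "match"]),
      w_gap = sum(.data$weight[.data$call == "gap_in_offtarget"]),
      sub_A = sum(.data$weight[.data$call == "mismatch" &
                                 .data$offtarget_base == "A"]),
      sub_C = sum(.data$weight[.data$call == "mismatch" &
                                 .data$offtarget_base == "C"]),
      sub_G = sum(.data$weight[.data$call == "mismatch" &
                                 .data$offtarget_base == "G"]),
      sub_T = sum(.data$weight[.data$call == "mismatch" &
                                 .data$offtarget_base == "T"]),
      .groups = "drop"
    )
  out <- grid %>%
    left_join(stats, by = c("position", "target_base")) %>%
    mutate(across(c("n_total", "w_match", "w_gap",
                    "sub_A", "sub_C", "sub_G", "sub_T"),
                  function(x) tidyr::replace_na(x, 0))) %>%
    mutate(flagged = .data$n_total == 0,
           denom = pmax(.data$n_total, 1e-300),
           no_mismatch_pct = 100 * .data$w_match / .data$denom,
           gap_pct = 100 * .data$w_gap / .data$denom,
           across(c("sub_A", "sub_C", "sub_G", "sub_T"),
                  function(x) 100 * x / .data$denom))
  subs <- as.matrix(out[, c("sub_A", "sub_C", "sub_G", "sub_T")])
  best <- apply(subs, 1, function(r) {
    if (all(r == 0)) return(c(NA, 0, FALSE))
    mx <- max(r)
    hits <- which(r >= mx - 1e-12)
    c(hits[1], mx, length(hits) > 1)  # alphabetical tie-break, tie flagged
  })
  out %>%
    mutate(
      most_substituted = c("A", "C", "G", "T")[as.integer(best[1, ])],
      most_substituted_pct = as.numeric(best[2, ]),
      tie = as.logical(best[3, ]),
      weighted = weights == "read_count"
    ) %>%
    select(-"denom", -"w_match", -"w_gap") %>%
    arrange(.data$position, .data$target_base)
}

#' Least mismatch-tolerant nucleotide per position
#'
#' Summarizes a [nucleotide_mismatch_profile()] table: per position, the
#' target base retaining the highest percentage of exact matches (the least
#' mismatch-tolerant base) and the base that most often substitutes it.
#' Positions where any of the four bases is unobserved are excluded
#' (insufficient data to rank all four). Ties are broken alphabetically and
#' flagged.
#'
#' @param pt Output of [nucleotide_mismatch_profile()].
#' @param protospacer_only Restrict to positions 1..20 (default `TRUE`; the
#'   PAM is ranked separately by [pam_census()]).
#' @return A tibble with `position`, `target_base`, `no_mismatch_pct`,
#'   `most_substituted`, `most_substituted_pct`, `tie`.
#' @export
summarize_least_tolerant <- function(pt, protospacer_only = TRUE) {
  stopifnot(all(c("position", "target_base", "no_mismatch_pct") %in% names(pt)))
  if (protospacer_only) pt <- filter(pt, .data$position <= OT_PROTOSPACER_LEN)
  complete_pos <- pt %>%
    group_by(.data$position) %>%
    summarise(ok = !any(.data$flagged), .groups = "drop") %>%
    filter(.data$ok) %>%
    pull(.data$position)
  pt %>%
    filter(.data$position %in% complete_pos) %>%
    group_by(.data$position) %>%
    arrange(dplyr::desc(.data$no_mismatch_pct), .data$target_base,
            .by_group = TRUE) %>%
    summarise(
      tie = sum(abs(.data$no_mismatch_pct - .data$no_mismatch_pct[1]) < 1e-12) > 1,
      target_base = .data$target_base[1],
      no_mismatch_pct = .data$no_mismatch_pct[1],
      most_substituted = .data$most_substituted[1],
      most_substituted_pct = .data$most_substituted_pct[1],
      .groups = "drop"
    ) %>%
    select("position", "target_base", "no_mismatch_pct",
           "most_substituted", "most_substituted_pct", "tie")
}

#' PAM motif census
#'
#' Tabulates the off-target PAM trinucleotides (alignment columns at target
#' positions 21..23) as motif classes with the variable first base collapsed
#' to `N` (NGG canonical; NGA and NAG are the common non-canonical motifs).
#' Fractions sum to 1.
#'
#' @inheritParams mismatch_profile
#' @return A tibble with `motif`, `n` (weighted count), `fraction`,
#'   `canonical`.
#' @export
pam_census <- function(ds, weights = c("none", "read_count")) {
  weights <- match.arg(weights)
  lng <- aligned_long(ds, weights) %>%
    filter(.data$position >= OT_PAM_N_POS, .data$call != "gap_in_target")
  pams <- lng %>%
    group_by(.data$record) %>%
    summarise(
      weight = .data$weight[1],
      pam = paste(.data$offtarget_base[order(.data$position)], collapse = ""),
      .groups = "drop"
    ) %>%
    filter(nchar(.data$pam) == 3, !grepl("-", .data$pam))
  if (nrow(pams) == 0) abort("no intact PAM columns found")
  pams %>%
    mutate(motif = paste0("N", substr(.data$pam, 2, 3))) %>%
    group_by(.data$motif) %>%
    summarise(n = sum(.data$weight), .groups = "drop") %>%
    mutate(fraction = .data$n / sum(.data$n),
           canonical = .data$motif == "NGG") %>%
    arrange(dplyr::desc(.data$fraction))
}
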