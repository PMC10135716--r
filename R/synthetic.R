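# Synthetic CIRCLE-seq-like data with planted, recoverable structure:
# per-target sets of off-targets carrying position-biased mismatches,
# occasional single-base bulges, read counts decaying with divergence, and a
# planted seed-region rule separating positives from negatives. Every
# downstream module can be validated against the planted parameters.

default_mismatch_probs <- function() {
  # U-shaped tolerance: high at the PAM-distal end (1-3), decaying through
  # the mid-guide, zero inside the planted seed (12-16), low PAM-proximal.
  c(0.25, 0.22, 0.18, 0.12, 0.10, 0.08, 0.07, 0.06, 0.06, 0.05,
    0.02, 0, 0, 0, 0, 0, 0.02, 0.02, 0.03, 0.03)
}

default_gap_probs <- function() {
  # bulges peak mid-guide and never fall in the planted seed
  c(0.001, 0.001, 0.001, 0.001, 0.001, 0.002, 0.004, 0.006, 0.008, 0.008,
    0.006, 0, 0, 0, 0, 0, 0.002, 0.002, 0.001, 0.001)
}

default_substitution_matrix <- function() {
  m <- rbind(
    A = c(0, 0.25, 0.50, 0.25),
    C = c(0.30, 0, 0.20, 0.50),
    G = c(0.50, 0.25, 0, 0.25),
    T = c(0.30, 0.20, 0.50, 0)
  )
  colnames(m) <- c("A", "C", "G", "T")
  m
}

#' Synthetic data generator configuration
#'
#' The defaults emulate the structure of a CIRCLE-seq + genome-candidate
#' study: a handful of target sites, ~20:1 negative:positive imbalance,
#' mismatch tolerance highest at the PAM-distal end and zero in the planted
#' seed (positions 12-16), bulges peaking mid-guide, ~11% non-canonical PAMs
#' dominated by NGA/NAG, and read counts decaying exponentially with total
#' divergence.
#'
#' @param n_targets Number of target sites (default 5).
#' @param n_pos_per_target Positive off-targets per target (default 70).
#' @param n_neg_per_target Negative candidates per target (default 1250).
#'   With the defaults, collapsing exact duplicates leaves ~5,000 unique
#'   pairs at ~20:1 imbalance.
#' @param mismatch_prob_by_position 20 per-position substitution
#'   probabilities for positives.
#' @param substitution_matrix 4x4 row-stochastic matrix of substitution
#'   preferences (zero diagonal).
#' @param gap_prob_by_position 20 per-position bulge probabilities.
#' @param pam_noncanonical_prob Probability an off-target PAM is
#'   non-canonical (default 0.11).
#' @param pam_nga_nag_share Share of non-canonical PAMs that are NGA or NAG
#'   (default 7/11).
#' @param readcount_base Expected read count of a perfect match (default
#'   1000).
#' @param readcount_decay Exponential decay of expected read count per unit
#'   divergence (default 0.7).
#' @param seed_region Positions whose differences define negatives (default
#'   12:16, the planted seed intolerance).
#' @param neg_background_mismatch_prob Per-position floor on the mismatch
#'   probability used for negative candidates (default 0): by default
#'   negatives are drawn from exactly the positives' mutation process plus
#'   the forced seed-region difference, so the planted seed rule is the only
#'   systematic class difference. A positive floor makes candidates more
#'   divergent (closer to genome-scan output) at the cost of adding a
#'   divergence shortcut between the classes.
#' @param seed Integer RNG seed.
#' @return A list of class `ot_generator_config`.
#' @export
generator_config <- function(n_targets = 5L, n_pos_per_target = 70L,
                             n_neg_per_target = 1250L,
                             mismatch_prob_by_position = default_mismatch_probs(),
                             substitution_matrix = default_substitution_matrix(),
                             gap_prob_by_position = default_gap_probs(),
                             pam_noncanonical_prob = 0.11,
                             pam_nga_nag_share = 7 / 11,
                             readcount_base = 1000,
                             readcount_decay = 0.7,
                             seed_region = 12:16,
                             neg_background_mismatch_prob = 0,
                             seed = 1L) {
  stopifnot(length(mismatch_prob_by_position) == OT_PROTOSPACER_LEN,
            length(gap_prob_by_position) == OT_PROTOSPACER_LEN)
  if (any(mismatch_prob_by_position < 0 | mismatch_prob_by_position > 1) ||
      any(gap_prob_by_position < 0 | gap_prob_by_position > 1) ||
      pam_noncanonical_prob < 0 || pam_noncanonical_prob > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(substitution_matrix) - 1) > 1e-8) ||
      any(diag(substitution_matrix) != 0)) {
    abort("substitution_matrix rows must sum to 1 with zero diagonal")
  }
  if (readcount_decay <= 0) abort("readcount_decay must be positive")
  if (length(seed_region) == 0 || any(seed_region < 1 | seed_region > 20)) {
    abort("seed_region must be protospacer positions (1..20)")
  }
  structure(list(
    n_targets = as.integer(n_targets),
    n_pos_per_target = as.integer(n_pos_per_target),
    n_neg_per_target = as.integer(n_neg_per_target),
    mismatch_prob_by_position = mismatch_prob_by_position,
    substitution_matrix = substitution_matrix,
    gap_prob_by_position = gap_prob_by_position,
    pam_noncanonical_prob = pam_noncanonical_prob,
    pam_nga_nag_share = pam_nga_nag_share,
    readcount_base = readcount_base,
    readcount_decay = readcount_decay,
    seed_region = as.integer(seed_region),
    neg_background_mismatch_prob = neg_background_mismatch_prob,
    seed = as.integer(seed)
  ), class = "ot_generator_config")
}

sample_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

substitute_base <- function(base, submat) {
  sample(colnames(submat), 1, prob = submat[base, ])
}

# Mutate a protospacer character vector in place; returns list(chars, n_diff)
mutate_protospacer <- function(chars, mm_probs, gap_probs, submat,
                               forced_positions = integer(0)) {
  orig <- chars
  n_diff <- 0L
  for (pos in seq_along(chars)) {
    if (runif(1) < mm_probs[pos]) {
      chars[pos] <- substitute_base(chars[pos], submat)
      n_diff <- n_diff + 1L
    }
  }
  # forced positions substitute away from the original base (the matrix has
  # a zero diagonal), guaranteeing a difference there
  for (pos in forced_positions) {
    chars[pos] <- substitute_base(orig[pos], submat)
    n_diff <- n_diff + 1L
  }
  # bulges: deletion (missing off-target base, RNA bulge) or insertion
  # (extra off-target base, DNA bulge) with equal probability
  events <- which(runif(length(chars)) < gap_probs)
  ins <- list()
  del <- integer(0)
  for (pos in events) {
    if (runif(1) < 0.5) del <- c(del, pos) else ins[[length(ins) + 1]] <- pos
    n_diff <- n_diff + 1L
  }
  out <- as.list(chars)
  for (pos in del) out[[pos]] <- character(0)
  for (pos in unlist(ins)) {
    out[[pos]] <- c(sample_base(1), out[[pos]])
  }
  list(seq = paste(unlist(out), collapse = ""), n_diff = n_diff)
}

# The variable 'N' base of the off-target PAM is inherited from the target
# (it is never counted as a difference); only the GG dinucleotide varies.
sample_pam <- function(cfg, n_base) {
  if (runif(1) >= cfg$pam_noncanonical_prob) {
    return(list(pam = paste0(n_base, "GG"), canonical = TRUE, n_diff = 0L))
  }
  if (runif(1) < cfg$pam_nga_nag_share) {
    tail2 <- if (runif(1) < 0.5) "GA" else "AG"
  } else {
    repeat {
      tail2 <- paste(sample_base(2), collapse = "")
      if (!tail2 %in% c("GG", "GA", "AG")) break
    }
  }
  list(pam = paste0(n_base, tail2), canonical = FALSE, n_diff = 1L)
}

#' Generate a synthetic off-target dataset
#'
#' Draws random 20-nt protospacers with NGG PAMs, then per target:
#' positive off-targets mutated according to the planted per-position
#' mismatch/bulge probabilities with read counts
#' `max(1, Poisson(base * exp(-decay * d)))` where `d` is the number of
#' differences; negative candidates built the same way but forced to carry at
#' least one difference inside the planted seed region, with read count 0.
#' Fully reproducible given `cfg$seed`.
#'
#' @param cfg An [generator_config()].
#' @return An off-target dataset tibble with attribute `planted` (the
#'   configuration) — see also [planted_truth()].
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "ot_generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  rows <- list()
  for (tgt in seq_len(cfg$n_targets)) {
    proto <- sample_base(OT_PROTOSPACER_LEN)
    pam_n <- sample_base(1)
    target_seq <- paste0(paste(proto, collapse = ""), pam_n, "GG")
    tid <- sprintf("T%02d", tgt)
    for (i in seq_len(cfg$n_pos_per_target)) {
      mut <- mutate_protospacer(proto, cfg$mismatch_prob_by_position,
                                cfg$gap_prob_by_position,
                                cfg$substitution_matrix)
      pam <- sample_pam(cfg, pam_n)
      d <- mut$n_diff + pam$n_diff
      rc <- max(1, rpois(1, cfg$readcount_base *
                           exp(-cfg$readcount_decay * d)))
      rows[[length(rows) + 1]] <- tibble(
        target_id = tid, target_seq = target_seq,
        offtarget_seq = paste0(mut$seq, pam$pam),
        read_count = rc, label = "positive"
      )
    }
    neg_mm <- pmax(cfg$mismatch_prob_by_position,
                   cfg$neg_background_mismatch_prob)
    for (i in seq_len(cfg$n_neg_per_target)) {
      n_forced <- 1L + stats::rbinom(1, 1, 0.3)
      forced <- sample(cfg$seed_region, n_forced)
      mut <- mutate_protospacer(proto, neg_mm,
                                cfg$gap_prob_by_position,
                                cfg$substitution_matrix,
                                forced_positions = forced)
      pam <- sample_pam(cfg, pam_n)
      rows[[length(rows) + 1]] <- tibble(
        target_id = tid, target_seq = target_seq,
        offtarget_seq = paste0(mut$seq, pam$pam),
        read_count = 0L, label = "negative"
      )
    }
  }
  ds <- bind_rows(rows)
  ds <- validate_dataset(ds)
  attr(ds, "planted") <- cfg
  ds
}

#' Analytic expectations under a generator configuration
#'
#' The planted per-position mismatch and gap probabilities and, per
#' (position, target base), the expected most-substituted base with its
#' conditional probability and margin over the runner-up — the ground truth
#' the propensity profiles should recover.
#'
#' @param cfg An [generator_config()].
#' @return A list of class `ot_planted_truth`: `positions` tibble
#'   (`position`, `mismatch_prob`, `gap_prob`) and `substitutions` tibble
#'   (`target_base`, `most_substituted`, `prob`, `margin`).
#' @export
planted_truth <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "ot_generator_config"))
  positions <- tibble(
    position = seq_len(OT_PROTOSPACER_LEN),
    mismatch_prob = cfg$mismatch_prob_by_position,
    gap_prob = cfg$gap_prob_by_position
  )
  sm <- cfg$substitution_matrix
  subs <- purrr::map(rownames(sm), function(b) {
    r <- sort(sm[b, ], decreasing = TRUE)
    tibble(target_base = b, most_substituted = names(r)[1],
           prob = r[[1]], margin = r[[1]] - r[[2]])
  })
  structure(list(positions = positions, substitutions = bind_rows(subs)),
            class = "ot_planted_truth")
}
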