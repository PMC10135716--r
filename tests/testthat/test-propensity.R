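# Build a small aligned dataset by hand so per-position expectations can be
# counted on paper: records differ from the toy target at known positions.
handmade_aligned <- function() {
  tg <- toy_target()
  mut <- function(seq, pos, base) { substr(seq, pos, pos) <- base; seq }
  offs <- c(
    rep(tg, 6),
    mut(tg, 3, "T"), mut(tg, 3, "T"),           # 2/10 mismatch at position 3
    mut(tg, 5, "G"),                            # 1/10 mismatch at position 5
    paste0(substr(tg, 1, 10), substr(tg, 12, 23))  # deletion at position 11
  )
  ds <- tibble::tibble(
    target_id = "T1", target_seq = tg, offtarget_seq = offs,
    read_count = c(100L, 80L, 60L, 40L, 20L, 10L, 50L, 30L, 20L, 10L),
    label = "positive"
  )
  align_dataset(normalize_read_counts(ds))
}

test_that("mismatch profile counts per-position substitution fractions", {
  al <- handmade_aligned()
  mp <- mismatch_profile(al)
  expect_equal(mp$mismatch_fraction[mp$position == 3], 0.2)
  expect_equal(mp$mismatch_fraction[mp$position == 5], 0.1)
  expect_equal(sum(mp$mismatch_fraction[!mp$position %in% c(3, 5)]), 0)
  # gap columns are excluded from the mismatch denominator
  expect_equal(mp$n_total[mp$position == 11], 9)

  # all-perfect dataset -> all zero
  perfect <- al[1:6, ]
  expect_true(all(mismatch_profile(perfect)$mismatch_fraction == 0))

  # a zero-weight record contributes nothing when weighting by read count
  two <- al[c(1, 7), ]
  two$norm_activity <- c(1, 0)
  wp <- mismatch_profile(two, weights = "read_count")
  expect_equal(wp$mismatch_fraction[wp$position == 3], 0)
})

test_that("the PAM 'N' position is never a mismatch", {
  tg <- toy_target()   # position 21 is 'A'
  ot <- tg
  substr(ot, 21, 21) <- "C"
  ds <- tibble::tibble(target_id = "T1", target_seq = tg, offtarget_seq = ot,
                       read_count = 5L, label = "positive")
  al <- align_dataset(normalize_read_counts(ds))
  mp <- mismatch_profile(al)
  expect_equal(mp$mismatch_fraction[mp$position == 21], 0)
})

test_that("gap profile locates bulges and equal weights match unweighted", {
  al <- handmade_aligned()
  gp <- gap_profile(al)
  expect_equal(gp$gap_fraction[gp$position == 11], 0.1)
  expect_equal(sum(gp$gap_fraction), 0.1)

  # gap-free dataset -> all zeros
  expect_true(all(gap_profile(al[1:6, ])$gap_fraction == 0))

  # equal weights reproduce the unweighted fractions
  aleq <- al
  aleq$norm_activity <- 0.5
  gpw <- gap_profile(aleq, weights = "read_count")
  expect_equal(gpw$gap_fraction, gp$gap_fraction)
})

test_that("nucleotide profile percentages conserve to 100 and flag absent bases", {
  al <- handmade_aligned()
  np <- nucleotide_mismatch_profile(al)
  seen <- np[!np$flagged, ]
  total <- seen$no_mismatch_pct + seen$sub_A + seen$sub_C + seen$sub_G +
    seen$sub_T + seen$gap_pct
  expect_true(all(abs(total - 100) < 1e-9))
  # position 3 is 'G' in the target, substituted by T in 2 of 10
  row3 <- np[np$position == 3 & np$target_base == "G", ]
  expect_equal(row3$no_mismatch_pct, 80)
  expect_equal(row3$sub_T, 20)
  expect_equal(row3$most_substituted, "T")
  # bases that never occur at a position are flagged
  expect_true(all(np$flagged[np$position == 3 & np$target_base != "G"]))

  # single matching record -> 100% retained
  one <- align_dataset(normalize_read_counts(toy_dataset()[1, ]))
  np1 <- nucleotide_mismatch_profile(one)
  expect_true(all(np1$no_mismatch_pct[!np1$flagged] == 100))
})

test_that("least-tolerant summary ranks bases and breaks ties alphabetically", {
  pt <- tibble::tibble(
    position = rep(c(1L, 2L), each = 4),
    target_base = rep(c("A", "C", "G", "T"), 2),
    n_total = c(rep(10, 4), rep(10, 4)),
    no_mismatch_pct = c(95.85, 88, 80, 70, 90, 90, 90, 90),
    most_substituted = "G", most_substituted_pct = 3.65,
    tie = FALSE, flagged = FALSE
  )
  s <- summarize_least_tolerant(pt)
  expect_equal(s$target_base[s$position == 1], "A")
  expect_equal(s$no_mismatch_pct[s$position == 1], 95.85)
  expect_equal(s$target_base[s$position == 2], "A")   # alphabetical tie-break
  expect_true(s$tie[s$position == 2])

  # a position with any unobserved base is excluded from the ranking
  pt2 <- pt
  pt2$flagged[2] <- TRUE
  pt2$n_total[2] <- 0
  expect_equal(summarize_least_tolerant(pt2)$position, 2L)

  # all positions flagged -> empty summary
  pt3 <- pt
  pt3$flagged <- TRUE
  expect_equal(nrow(summarize_least_tolerant(pt3)), 0L)
})

test_that("PAM census classifies motifs with the first base wildcarded", {
  tg <- toy_target()
  swap_pam <- function(seq, pam) paste0(substr(seq, 1, 20), pam)
  offs <- c(rep(tg, 89), rep(swap_pam(tg, "TGA"), 4),
            rep(swap_pam(tg, "CAG"), 3), rep(swap_pam(tg, "ATT"), 4))
  ds <- tibble::tibble(target_id = "T1", target_seq = tg, offtarget_seq = offs,
                       read_count = 1L, label = "positive")
  al <- align_dataset(normalize_read_counts(ds))
  pc <- pam_census(al)
  expect_equal(sum(pc$fraction), 1)
  expect_equal(pc$fraction[pc$motif == "NGG"], 0.89)
  noncanon <- sum(pc$fraction[!pc$canonical])
  expect_equal(noncanon, 0.11)
  expect_equal(sum(pc$fraction[pc$motif %in% c("NGA", "NAG")]), 0.07)

  # all canonical
  al1 <- align_dataset(normalize_read_counts(
    tibble::tibble(target_id = "T1", target_seq = tg, offtarget_seq = tg,
                   read_count = 1L, label = "positive")))
  pc1 <- pam_census(al1)
  expect_equal(pc1$fraction, 1)
  expect_equal(pc1$motif, "NGG")

  # empty dataset errors
  expect_error(pam_census(al[0, ]), "empty")
})

test_that("weighted counting equals unweighted counting on expanded replicas", {
  set.seed(31)
  ds <- generate_dataset(generator_config(n_targets = 2, n_pos_per_target = 25,
                                          n_neg_per_target = 5, seed = 31))
  ds <- dplyr::filter(ds, label == "positive")
  # force read counts to exact multiples of the per-target minimum (50), so
  # the expansion factors are exactly proportional to the weights
  ds$read_count <- 50L * (1L + as.integer(ds$read_count) %% 4L)
  ds <- dplyr::group_by(ds, target_id)
  ds <- dplyr::mutate(ds, read_count = replace(read_count, 1, 50L))
  ds <- dplyr::ungroup(ds)
  ds <- normalize_read_counts(ds)
  al <- align_dataset(ds)
  expanded <- align_dataset(weighted_expansion(ds))
  wp <- mismatch_profile(al, weights = "read_count")
  up <- mismatch_profile(expanded, weights = "none")
  expect_equal(wp$mismatch_fraction, up$mismatch_fraction, tolerance = 1e-10)
})
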