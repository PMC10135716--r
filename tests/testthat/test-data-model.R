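test_that("reading a toy table yields a validated dataset and rejects bad rows", {
  ds <- toy_dataset()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_offtarget_table(ds, path)
  back <- read_offtarget_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  expect_equal(length(unique(back$target_id)), 1L)

  # malformed read_count -> row-level error
  bad <- ds
  bad$read_count[2] <- -5
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path2)
  expect_error(read_offtarget_table(path2), "read_count")

  # missing column -> schema error naming it
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ds[, setdiff(names(ds), "label")], path3)
  expect_error(read_offtarget_table(path3), "label")

  # header-only file -> empty dataset
  path4 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ds[0, ], path4)
  expect_equal(nrow(read_offtarget_table(path4)), 0L)

  # rows with characters outside {A,C,G,T,N} are rejected with a warning
  bad2 <- ds
  bad2$offtarget_seq[1] <- sub("A", "X", bad2$offtarget_seq[1])
  path5 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad2, path5)
  expect_warning(got <- read_offtarget_table(path5), "rejected")
  expect_equal(nrow(got), 2L)
})

test_that("round trip read -> write -> read reproduces the dataset exactly", {
  ds <- generate_dataset(generator_config(n_targets = 2, n_pos_per_target = 5,
                                          n_neg_per_target = 10, seed = 4))
  attr(ds, "planted") <- NULL
  ds <- normalize_read_counts(ds)
  for (ext in c(".tsv", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_offtarget_table(ds, path)
    back <- read_offtarget_table(path)
    expect_equal(as.data.frame(back), as.data.frame(ds))
  }
})

test_that("read counts normalize per target by the maximum and idempotently", {
  ds <- tibble::tibble(
    target_id = c("A", "A", "A", "B", "B"),
    target_seq = toy_target(),
    offtarget_seq = c("ACGTACGTACGTACGTACGTAGG", "ACGAACGTACGTACGTACGTAGG",
                      "ACGTACGTACGTACGTACGTTGG", "CCGTACGTACGTACGTACGTAGG",
                      "GCGTACGTACGTACGTACGTAGG"),
    read_count = c(100L, 50L, 0L, 4L, 1L),
    label = c("positive", "positive", "negative", "positive", "positive")
  )
  nd <- normalize_read_counts(ds)
  expect_equal(nd$norm_activity, c(1, 0.5, 0, 1, 0.25))
  expect_equal(normalize_read_counts(nd)$norm_activity, nd$norm_activity)

  # single positive record
  one <- ds[4, ]
  expect_equal(normalize_read_counts(one)$norm_activity, 1)

  # all-zero target errors with its name
  dead <- ds
  dead$read_count <- 0L
  dead$label <- "negative"
  expect_error(normalize_read_counts(dead), "A")
})

test_that("deduplication collapses pairs and positive labels dominate", {
  tg <- toy_target()
  ds <- tibble::tibble(
    target_id = "T1", target_seq = tg,
    offtarget_seq = c(tg, tg, tg),
    read_count = c(30L, 0L, 10L),
    label = c("positive", "negative", "positive")
  )
  dd <- deduplicate_and_relabel(ds)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$label, "positive")
  expect_equal(dd$read_count, 30L)

  # no duplicates -> unchanged content
  clean <- toy_dataset()
  dd2 <- deduplicate_and_relabel(clean)
  expect_equal(nrow(dd2), 3L)
  expect_setequal(dd2$offtarget_seq, clean$offtarget_seq)

  # two identical negatives collapse to one
  negs <- clean[c(3, 3), ]
  expect_equal(nrow(deduplicate_and_relabel(negs)), 1L)

  # positives unchanged as a set; negatives a subset of input negatives
  ds2 <- generate_dataset(generator_config(n_targets = 2, n_pos_per_target = 20,
                                           n_neg_per_target = 50, seed = 9))
  dd3 <- deduplicate_and_relabel(ds2)
  pos_in <- unique(paste(ds2$target_id, ds2$offtarget_seq)[ds2$label == "positive"])
  pos_out <- paste(dd3$target_id, dd3$offtarget_seq)[dd3$label == "positive"]
  expect_setequal(pos_out, pos_in)
  neg_in <- unique(paste(ds2$target_id, ds2$offtarget_seq)[ds2$label == "negative"])
  neg_out <- paste(dd3$target_id, dd3$offtarget_seq)[dd3$label == "negative"]
  expect_true(all(neg_out %in% neg_in))
})

test_that("weighted expansion replicates positives by read-count ratio", {
  tg <- toy_target()
  mk <- function(counts) tibble::tibble(
    target_id = "T1", target_seq = tg,
    offtarget_seq = paste0(substr(tg, 1, 20),
                           c("AGG", "TGG", "CGG")[seq_along(counts)]),
    read_count = as.integer(counts),
    label = "positive"
  )
  expect_equal(nrow(weighted_expansion(mk(c(2, 1)))), 3L)       # 2 + 1
  expect_equal(nrow(weighted_expansion(mk(5))), 1L)             # single record
  got <- weighted_expansion(mk(c(10, 4, 2)))
  expect_equal(as.integer(table(got$read_count)[c("10", "4", "2")]),
               c(5L, 2L, 1L))                                   # ratios 5:2:1
})
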