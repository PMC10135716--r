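# Small in-code fixtures and a memoized trained model shared by the
# model/attribution tests (training is the expensive step; it runs once).

toy_target <- function() "ACGTACGTACGTACGTACGTAGG"   # 20-nt protospacer + AGG

toy_dataset <- function() {
  tg <- toy_target()
  mut <- function(seq, pos, base) {
    substr(seq, pos, pos) <- base
    seq
  }
  tibble::tibble(
    target_id = "T1",
    target_seq = tg,
    offtarget_seq = c(tg, mut(tg, 3, "T"), mut(tg, 5, "G")),
    read_count = c(100L, 50L, 0L),
    label = c("positive", "positive", "negative")
  )
}

# The desk-scale synthetic study shared by the model-level tests: generated
# conditions, preprocessing, split, and one trained model. Memoized in the
# test environment.
.study_cache <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  .study_cache$study <- run_study(seed = 11)
  .study_cache$study
}

# Small model configuration/datasets: quick to train, exercise every layer.
tiny_cfg <- function(...) {
  defaults <- list(conv_blocks = list(c(6, 3), c(8, 3)), lstm_units = 5,
                   head_dense_sizes = c(8, 4), batch_size = 16, epochs = 2,
                   lr = 1e-3, dropout = 0, seed = 7)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_tensors <- function(seed = 3, n_pos = 10, n_neg = 30) {
  ds <- generate_dataset(generator_config(n_targets = 2, n_pos_per_target = n_pos,
                                          n_neg_per_target = n_neg, seed = seed))
  ds <- normalize_read_counts(deduplicate_and_relabel(ds))
  encode_dataset(align_dataset(ds))
}

# Shared briefly-trained model for the attribution axioms.
attr_fixture <- function() {
  if (!is.null(.study_cache$attr)) return(.study_cache$attr)
  tens <- tiny_tensors(seed = 14, n_pos = 15, n_neg = 30)
  fit <- train_model(NULL, tens, tens, cfg = tiny_cfg(epochs = 3))
  rec <- tens$records[1, ]
  ap <- align_pair(rec$target_seq, rec$offtarget_seq)
  .study_cache$attr <- list(model = fit$model, pair = encode_pair(ap, tens$L),
                            ap = ap, tens = tens)
  .study_cache$attr
}
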