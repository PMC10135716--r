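---
title: "Modelling CRISPR/Cas9 off-target activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CRISPR/Cas9 off-target activity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

SpCas9 cleaves not only its intended 20-nt protospacer (adjacent to an NGG
PAM) but also genomic sites that resemble it. Genome-wide in vitro assays
such as CIRCLE-seq report, for each guide, the set of cleaved sites together
with read counts that proxy cleavage frequency; off-target search tools
supply the complementary set of PAM-adjacent near-matches for which no
cleavage was observed. `offtargetr` works with exactly this kind of table —
one row per (target, candidate) pair with a read count and a
positive/negative label — and provides three layers of analysis:

1. **Count-based propensity profiles**: where along the guide mismatches and
   DNA/RNA bulges are tolerated, per position and per target nucleotide,
   optionally weighted by normalized cleavage frequency.
2. **A multitask Siamese CNN–biLSTM** that simultaneously classifies
   candidates (cleaved vs not) and regresses the extent of cleavage
   activity.
3. **Gradient attribution** over the trained network (saliency, smoothed
   saliency, integrated gradients, expected gradients) to recover which
   positions and bases drive the predictions.

Everything below documents the modelling choices, their defaults, and the
limits of what the packaged synthetic validation shows.

# Data model and preprocessing

A dataset is a tibble with columns `target_id`, `target_seq` (23 nt =
protospacer + NGG PAM, written PAM-distal → PAM), `offtarget_seq` (raw
candidate sequence), `read_count`, `label`. Two cleaning steps mirror how
such datasets are assembled:

* `deduplicate_and_relabel()` collapses exact `(target_id, offtarget_seq)`
  duplicates. A positive label dominates a negative one for the same pair:
  experimental evidence of cleavage outweighs a predicted-inactive call.
* `normalize_read_counts()` scales read counts **per target** by that
  target's maximum, giving `norm_activity` in [0, 1]; negatives get 0. How
  the original read counts "were normalized" admits several readings
  (per-target sum, global scaling); per-target max-scaling was chosen
  because it bounds the regression response for every guide and makes
  activities comparable across guides with very different sequencing depth.
  The regression head is trained on this quantity.

`weighted_expansion()` materializes read-count weighting by replicating
positives proportionally to read count. The propensity functions instead use
`norm_activity` directly as a continuous weight — exactly equivalent for
proportional integer weights (there is a test asserting this equivalence)
and without the memory blow-up.

# Bulge-aware alignment

Cas9 tolerates DNA and RNA bulges; in sequence terms these are insertions
and deletions, visible only after alignment. `align_pair()` computes an
optimal global alignment under affine-gap scoring (Gotoh's three-state
dynamic program, implemented in C++):

* defaults `match = 2`, `mismatch = -1`, `gap_open = -2`, `gap_extend = -1`.
  The mild gap cost admits single-base bulges without fragmenting the
  alignment; all four values are arguments.
* **Deterministic tie-breaking.** Among equal-scoring alignments the
  diagonal (match/mismatch) state is preferred over gaps, and ambiguous gaps
  are pushed as far 3' (PAM-proximal) as the score allows. Downstream
  encodings depend on gap placement, so reproducible output is a contract,
  not a nicety.
* **PAM locking** (`lock_pam = TRUE`): gaps are forbidden inside the
  target's 3-nt PAM frame, so the candidate PAM always aligns gap-free to
  the target PAM and PAM columns stay interpretable in every downstream
  view. Whether bulges inside the PAM should ever be modelled is unclear;
  the lock is an argument, not an axiom.
* `passes_distance_filter()` applies the conventional candidate ceiling of
  at most 9 mismatches + gaps (configurable).

The aligner's optimality is tested against exhaustive enumeration of all
global alignments (short sequences) and against an independent
implementation of the same scoring scheme (longer sequences).

# One-hot image encoding

Each (gapped) sequence becomes a 5 × L binary matrix — rows A, C, G, T and
gap — with **front padding** by `N` to the common width L (default 26 = 23 +
up to 3 gap columns; longer alignments are rejected, never truncated). An
`N` column is all-zero, so padding carries no signal, and the dedicated gap
row lets the network see bulges. Columns are numbered from the PAM-distal
end (1..20 protospacer, 21..23 PAM); padding columns are numbered
negatively. Encoding is exactly invertible (`decode_image()`), and the
alphabet layout is a package constant so stored models remain portable.

# Propensity profiles

* `mismatch_profile()`: per position, the fraction of records whose
  candidate base differs from the target base. Gap columns are excluded
  from this denominator and profiled separately by `gap_profile()` — the
  two phenomena are reported in separate views. Insertions (gap in the
  target row) are assigned to the position of the next target base.
* Position 21 is the `N` of the NGG PAM: any base there counts as a match,
  by definition.
* `nucleotide_mismatch_profile()`: per (position, target base), the percent
  retained, the distribution over substituting bases, and the percent with
  a gap; these conserve to 100% per combination. Combinations never
  observed are flagged and carry no statistics; a position with any
  unobserved base is excluded from `summarize_least_tolerant()`, which
  reports the least mismatch-tolerant base per position with alphabetical,
  flagged tie-breaking.
* `pam_census()` tabulates candidate PAMs as motif classes with the first
  base wildcarded (NGG canonical; NGA/NAG the common non-canonical
  motifs).
* With `weights = "read_count"`, every record contributes its
  `norm_activity`, giving the cleavage-frequency-weighted variants.

# The multitask network

Two **weight-shared sister branches** read the target image and the
candidate image. Each branch applies two convolution + batch-normalization +
ReLU blocks along the position axis ("same" padding, odd kernels), then a
bidirectional LSTM over the positions. The two branch embeddings are
concatenated and feed two independent dense stacks: a classification head
(sigmoid probability that the candidate is a true off-target) and a
regression head (activity estimate, clipped to [0, 1] at prediction time).

**Loss.** Class-weighted binary cross-entropy (balanced heuristic
`N/(2 N_c)`, so a ~20:1 imbalance up-weights positives ~10×) plus
`reg_loss_weight` (λ, default 2e-4) times the mean squared error of the
regression head, computed **over positive samples only**: negatives have
activity 0 by construction and are masked out of the regression term (an
unmasked variant is a flag). The logged combined loss decomposes exactly as
`cls + λ·reg`; the tests assert this identity on the training report.

**Regularization.** An L2 weight penalty (default 5e-4) applies to the
dense-layer weights, implemented as a gradient-side penalty so that the
logged loss keeps its exact decomposition. The regression head's penalty is
scaled by λ: its loss gradients are λ-scaled, and a penalty calibrated
against the classification loss would otherwise dominate them and pin the
regression stack at zero (we observed exactly this collapse). Dropout on
the merged embedding and head hidden layers is available (`dropout`,
default 0).

**Open design points and how they were resolved.**

* *Branch readout*: the biLSTM contributes the hidden states of **every**
  position (`lstm_readout = "sequence"`, the default) rather than only the
  final states. The final-state readout compresses both sequences into a
  small vector before the heads ever see them; probing such embeddings
  showed they retain the class decision but lose the position-resolved
  mismatch evidence that the activity regression needs. `"final"` and a
  mean-pooled `"mean"` readout remain available.
* *Weight sharing*: the branches are true Siamese twins (identical
  parameter objects); a no-sharing variant is a flag.
* *Batch normalization* keeps running statistics with momentum 0.97
  (inference uses the running estimates). Lower momentum made the
  validation loss jitter batch-to-batch and triggered spurious
  learning-rate halvings.

**Training regimen** (`train_model()`): Adam (initial learning rate `lr`,
default 1e-4; the packaged study uses 1e-3), class weights, and
learning-rate halving whenever the validation combined loss fails to
improve for `patience` (default 5) consecutive epochs. The parameters of
the best-validation-loss epoch are kept. A single integer seed controls
initialization, shuffling and (if enabled) dropout masks; given the seed
and single-threaded BLAS, training is exactly reproducible, which the tests
rely on.

`grid_search()` performs the exhaustive sweep used to size the layers;
`repeated_evaluation()` re-splits, re-trains and re-evaluates with distinct
split seeds and reports mean ± sd per metric.

# Evaluation

`evaluate_model()` reports precision, recall, F1, MCC and Cohen's kappa at a
threshold (default 0.5), the precision–recall curve with its area computed
as **average precision** (step-wise summation — the trapezoid interpolates
optimistically on imbalanced data), the F1–MCC curve over an even threshold
grid (with the best-possible (1, 1) and worst-possible (0, −1) reference
points), and R² of the activity regression over the positive samples.
Degenerate denominators (e.g. no predicted positives at extreme thresholds)
yield 0 with a `degenerate` flag rather than an error, so threshold sweeps
never abort. Note the widely used conventions: recall = TP/(TP+FN) ("how
many actual positives are captured") and the standard MCC contingency form.

# Attribution

All methods differentiate a head's **pre-activation** output (pre-sigmoid
for classification — attribution through the sigmoid saturates) with respect
to the pixels of *both* input images, in inference mode, and return one
signed 5 × L map per branch:

* `gradient_saliency()`: absolute input gradient.
* `smoothed_saliency()`: the saliency averaged over `n` copies (default 25)
  perturbed with Gaussian noise of sd `sigma` (default 0.15 × the input
  range, which is 1 for one-hot images). With `n = 1, sigma = 0` it equals
  plain saliency exactly.
* `integrated_gradients()`: midpoint-rule path integral from a baseline to
  the input; the default baseline is the all-zero (all-`N`) image — the
  natural "no sequence" reference under this encoding. The completeness
  identity (attributions sum to `f(x) − f(baseline)`) is checked to 1e-2
  relative at 50 steps and tightens as steps grow. Reference-baseline
  integration is the package's stand-in for DeepLIFT-style backpropagation
  rules, whose exact rescale rules are not implemented.
* `expected_gradients()`: the Monte-Carlo SHAP-style estimator with
  baselines drawn from a background set and uniform path positions; with a
  single background it converges to integrated gradients.

`average_maps()` produces class-averaged maps; `sequence_view()` collapses
the alphabet axis to the occupied cell per column, alongside the aligned
bases and difference calls; `seed_region_ranking()` compares mean absolute
attribution inside a seed region against neutral positions.

# The synthetic data generator

`generate_dataset()` produces CIRCLE-seq-like fixtures with **planted,
analytically known structure** (`planted_truth()`), so every module can be
validated without external data:

* random 20-mer protospacers with NGG PAMs; positives are mutated with
  per-position substitution probabilities (default U-shaped: ~0.18–0.25 at
  PAM-distal positions 1–3, decaying through the mid-guide, **zero at the
  planted seed 12–16**, low PAM-proximal — the canonical mismatch-tolerance
  shape) and a row-stochastic substitution-preference matrix
  (transition-biased);
* single-base bulges (insertion or deletion, 50/50) with probabilities
  peaking mid-guide (~0.8% at positions 9–10) and zero in the seed;
* candidate PAMs are non-canonical with probability 0.11, of which 7/11
  are NGA/NAG — matching the reported shares of non-canonical motifs;
* read counts `max(1, Poisson(1000 · exp(−0.7 · d)))` where `d` counts all
  differences — the simplest monotone frequency–divergence model;
* negatives are **constructed**, not genome-sampled: they are drawn from
  exactly the positives' mutation process plus at least one forced
  substitution inside the seed region, with read count 0. The planted rule —
  "a seed difference abolishes cleavage" — is therefore the *only*
  systematic class difference and is what the classifier must discover. (An
  optional per-position background floor makes candidates more divergent,
  closer to genome-scan output, at the cost of adding a divergence shortcut
  between the classes; a genome-scan alternative exists via
  `enumerate_candidates()`.)

The packaged study (`study_config()`, `run_study()`) uses 5 targets × (70
positives + 1250 negatives) — about 5,000 unique pairs at ~20:1 imbalance
after duplicate collapse — an 80/10/10 stratified split, and a compact
network (conv 8×5 and 16×3, biLSTM 8 units/direction, heads 32/16, batch
256, lr 1e-3, 80 epochs). Training is run from two independent
initializations and the model with the lower validation loss is kept: at
this scale an occasional initialization optimizes poorly before the
learning-rate halvings freeze it, and the selection uses validation data
only. The sizes were fixed once so that the whole study, training included,
completes in minutes on one core while leaving the planted structure
comfortably learnable.

**What the generator does not emulate**: real genomic sequence composition
and repeat structure, cell-type chromatin effects, sequencing and library
artifacts, guide-specific activity scales, or any correlation between
neighbouring positions. Passing the packaged validation therefore shows the
*machinery* is correct — alignment optimality, encoding invertibility,
unbiased counting, a trainable and reproducible network, attribution axioms,
recovery of planted parameters — not that the defaults transfer to any
particular real dataset.

# Known limitations

* **Activity regression needs more positives than classification.** In the
  desk-scale study the classifier routinely reaches MCC ≈ 1 on the planted
  rule, but the regression head — which must effectively count and weigh
  mismatches through the concatenated branch embeddings — does not
  generalize past R² ≈ 0.4–0.5 with only a couple of hundred positive
  records, even when trained with the regression loss alone. Accurate
  activity regression with this architecture is a thousands-of-positives
  regime; the packaged study documents the gap honestly (the corresponding
  validation check is expected to fail at desk scale) rather than
  relabelling it.
* With λ = 2e-4 and [0, 1]-normalized activities, the regression term is
  orders of magnitude smaller than the classification term, so the shared
  trunk is shaped almost entirely by classification; the regression head
  learns on top of those features. Raising λ is a one-argument change if a
  dataset warrants it.
* The candidate scan is a brute-force surrogate suitable for kilobase-scale
  sequence, not a genome-scale search engine.
* Training is single-threaded by design for exact reproducibility; the
  implementation is sized for desk-scale studies, not GPU-scale datasets.
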