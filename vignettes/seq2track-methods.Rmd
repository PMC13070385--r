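---
title: "seq2track: model, training methodology and synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seq2track: model, training methodology and synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

`seq2track` predicts genomic assay tracks (ATAC-seq, ChIP-seq and similar
coverage signals) directly from DNA sequence. A model consumes a one-hot
encoded window of `input_length` bp (196,608 at full scale) and emits, for
every track, one non-negative rate per 128-bp bin over the centred
`crop_length` bp (114,688 bp, i.e. 896 bins). Counts in a bin are modelled
as Poisson with the predicted rate, which is the natural observation model
for read-count coverage.

## Architecture

The trunk follows the Enformer design: a convolutional stem at half the
trunk width (kernel 15, a residual width-1 convolution block, softmax
pooling), a six-stage convolutional tower whose widths grow exponentially
from half width to full width (each stage: batch-norm -> GELU -> kernel-5
convolution, a residual width-1 block, softmax pooling), a stack of
self-attention blocks with relative positional information, an optional
final width-1 convolution that doubles the channel width, and one linear
"head" per task set with a softplus output nonlinearity guaranteeing
strictly positive Poisson rates. Sequence length is halved by the stem and
by each tower stage, so `2^n_conv_blocks` must equal `bin_size`; with the
default 7 convolutional blocks the trunk emits one feature vector per
128 bp.

Three architectural switches reproduce the simplification study:

* `include_attention_linear` — the linear projection applied after the
  multi-head attention concatenation in every attention block. We interpret
  "removing a linear layer from the attention block" as removing this
  output projection (the feed-forward sublayer is retained); the switch
  makes the alternative interpretation a one-line change.
* `include_final_pointwise` — the final width-1 convolution. When absent,
  heads read the attention output directly (trunk width instead of twice
  the trunk width).
* `n_attention_blocks` — 11 in the baseline, 5 in the reduced variant.

At the published scale (channels 1536, 8 heads, key size 64, value size
192, relative-position feature size 192) the unablated architecture with
the 5313-track head used for pretraining counts 246,172,353 trainable
parameters; `count_parameters()` reports the per-component breakdown.

Two relative-position schemes are provided. `enformer_basis` is the
published fixed basis — exponential decays at geometrically spaced
half-lives, central masks of doubling width, and gamma densities tiling the
range, each paired with a sign-antisymmetric copy, projected per head — and
is the default at full scale. `simple_relative_bias` learns one bias per
head and relative distance directly; at desk scale (at most a few hundred
positions after pooling) this is cheaper and equally expressive, and it is
the small-configuration default.

Weight initialisation follows the PyTorch defaults (Kaiming-uniform with
`a = sqrt(5)` for dense and convolutional weights) and is fully determined
by the seed passed to `build_model()`.

### Normalisation at batch size 1

Training uses batch size 1 throughout, so batch-norm statistics over
batch x position reduce to statistics over the positions of the current
window. We compute them that way in both training and evaluation: there are
no running buffers, inference is deterministic, and train/eval activations
agree exactly. This is the one place the implementation deliberately
simplifies the published batch-norm bookkeeping; at batch size 1 the two
formulations coincide during training.

## Training recipe

The objective is the Poisson negative log-likelihood, `lambda - y*log(lambda)`
averaged over bins and tracks; the `log(y!)` term does not depend on the
model and is omitted from optimisation (a flag adds it for likelihood
reporting). Optimisation is AdamW (beta 0.9/0.999, eps 1e-8, decoupled
weight decay) with a piecewise-linear schedule: warm-up from 0 to the peak
over the first epoch, linear decay to 0 over the remaining epochs. Epoch
boundaries are defined in optimiser steps, so the schedule generalises to
any batch size. Windows are reshuffled each epoch with a seed derived from
the global seed and the epoch number. The full-scale defaults are peak
learning rate 3e-5, weight decay 1e-4, 10 epochs, batch size 1; these are
the values `train_config()` carries.

Two objective modes exist: multi-track (average NLL over all tracks) and
single-track (NLL of one selected track). The selected track may be the
only head output, or one column of a wider head — the latter is how the
track-count sweep fine-tunes a trained multi-track model on its track of
interest without replacing the head.

Fine-tuning loads a checkpoint, deletes the head(s), attaches a freshly
initialised head with the new task count and trains; the new checkpoint
records its parent. With `finetune_frozen`, gradient updates are restricted
to the head: every other weight is bit-identical afterwards (the test suite
checks the checksum), and when dropout is zero the trunk activations are
computed once per window and cached, which makes frozen fine-tuning
markedly cheaper — the desk-scale reflection of the memory/time savings
that motivate freezing on real hardware.

No gradient clipping is applied by default (a flag exposes it), and there
is no early stopping: runs last the configured 10 epochs.

### Desk-scale optimisation settings

The experiment drivers default to a peak learning rate of 1e-2 for
multi-task (pre)training and 3e-3 for the per-task arms, with the same
schedule. The full-scale recipe takes ~3.4e5 optimiser steps; a desk run
takes a few thousand, and the total parameter displacement an AdamW run can
achieve scales with steps x learning rate, so the peak must be larger by
roughly the step-count ratio for training to leave initialisation
meaningfully. The per-task arms use a gentler peak than the corpus runs
because a full warm-up/decay cycle at the corpus peak can destroy a
pretrained initialisation outright; both arms of every comparison share the
same setting, so the pairing is preserved. Trunk width at desk scale
defaults to 48 channels: motif
discovery from a few hundred windows is unreliable in narrower stems
(single runs frequently fail to leave the memorisation regime), while at 48
channels it is consistent. These are desk-preset choices; `train_config()`
itself keeps the published values.

## Homology-aware splitting

Cross-species windows are assigned to train/validation/test by mapped
overlap with the reference training and validation sets. PSL alignments
(21-column, as produced by BLAT/pslMap; forward strand) are read
block-wise; a window base counts as overlapping if any alignment block maps
it into the reference set, and each base counts once regardless of how many
alignments cover it (union semantics — the test suite checks equality with
a per-base brute-force oracle). The rule: more overlap with the training
set than the validation set sends a window to train, and vice versa. Equal
nonzero overlaps go to validation (conservative against leakage into
train); windows with no mapped overlap at all — the vast majority in
practice — are assigned by a seeded draw from configurable ratios, keyed by
the window id so the label does not depend on call order. Residual homology
(`homology_proportion`, the fraction of window bases mapping into the
reference training set) supports leakage-binned evaluation via
`homology_bins()`; the bin edges of the published supplementary analysis
are not stated, so they are left to the caller.

## Evaluation

The metric is the Pearson correlation coefficient, per track over the
pooled bins of all evaluated windows, then averaged (unweighted) over
tracks; a per-window-then-average variant is available for sensitivity
analysis. The printed formula in the source divides by the product of the
variances without a square root, which is not bounded by 1; we implement
the standard square-rooted definition. Constant vectors make the
correlation undefined; by policy such tracks score 0 with a warning rather
than crashing batch evaluation.

## The synthetic benchmark

`generate_world()` builds a miniature cross-species study: a reference
"species" with a large multi-task corpus for pretraining, plus related
species with small task sets, in the standard formats (FASTA genomes,
bedGraph tracks, BED occurrence annotations, PSL homology mappings, TSV
split tables).

The generative model: a vocabulary of `n_motifs` PWMs (Dirichlet rows,
concentration 0.1, i.e. sharp motifs of ~10-14 bits); genomes are i.i.d.
background at a species-specific GC content with motif instances planted
at ~16 occurrences per kb; each task weights `motifs_per_task` motifs
(log-normal weights around 3.5) and its per-bin rate is
`softplus(log(baseline) + sum of weight x Gaussian kernel)` with a
bandwidth of ~1.5 bins; counts are Poisson. Species share a configurable
fraction (default 0.75) of the reference vocabulary — with freshly drawn
task weights — and carry their own motifs and a shifted GC content, so
transfer is beneficial but not trivial. Exact duplicate segments copied
from the reference train/validation region into species genomes (with
their motif annotations) are emitted as single-block PSL alignments, a
transparent stand-in for real orthology that exercises the homology split
end to end.

The occurrence density and motif sharpness are deliberately at the high end
of what one would call realistic for regulatory DNA. They are set so the
benchmark carries recoverable signal at desk scale: with default settings
the true rate explains the counts at r ~ 0.8 (the Poisson ceiling). End to
end, *single-task* training from scratch under the fixed 10-epoch recipe is
deliberately marginal — de-novo motif discovery from one track's few
hundred occurrences either crystallises early or not at all, and held-out
correlations vary widely across initialisations and tasks. Multi-task
pretraining followed by fine-tuning is the reliable route to high held-out
correlation, which is precisely the methodology's thesis; the acceptance
suite asserts that ordering, not any absolute single-task level. What the
generator does **not** emulate: fragment-length and transposase-bias
structure of real ATAC-seq, mappability artefacts, reverse-strand motifs
(planting is forward-strand only), chromatin domain structure, and real
orthology (duplications are exact copies). Passing tests therefore
demonstrate that the implementation reproduces the methodology's
qualitative behaviour on data satisfying its own assumptions — not that
these settings reach any particular accuracy on real genomes.

### Preset problem sizes

The `desk` preset uses 4096-bp windows (2048-bp crop, 16 bins), 12 motifs,
40 pretraining tasks, 300 reference training windows and two extra species
with 3 tasks each. The `tiny` preset — the condition the end-to-end tests
run — uses 2048-bp windows (8 bins), 8 motifs, 24 pretraining tasks, 256
reference training windows and one extra species (32/6/14 windows expected
per split) with 2 tasks. The tradeoff-sweep tests subsample the reference
training windows (as the published preprocessing subsamples its corpora) to
32 per run, and sweep 1 and 16 additional tracks with 2 replicates.

## Experiment designs

* `run_architecture_comparison()` trains the five standard variants
  (baseline, no linear, no pointwise, simplified, 5-block simplified) with
  identical seeds and data order and records per-epoch validation Pearson
  plus parameter counts.
* `run_transfer_experiment()` pretrains once on the reference corpus, then
  runs the four arms (fine-tune, scratch, frozen fine-tune, frozen scratch
  control) per seed on one held-out-species task, and reports the
  percentage improvement of pretraining over scratch against the scratch
  denominator.
* `run_tradeoff_sweep()` trains on the track of interest plus N randomly
  sampled additional tracks (redrawn per replicate, fresh initialisation
  per replicate), then continues training on the single track of interest
  at a learning rate two orders of magnitude below the training peak,
  mirroring the published post-hoc fine-tuning, and records both
  track-of-interest and all-track means before and after. The sweep's
  output schema is sufficient to re-plot both curve families. Whether the
  inverted-U in the published track-count curves reappears at desk scale is
  recorded, not asserted — toy dynamics need not reproduce the peak's
  location.

## Numerical and policy choices

* Coordinates are 0-based half-open everywhere (BED/bedGraph convention);
  FASTA headers are truncated at the first whitespace.
* Bin statistic: sum of per-base signal (`mean` behind a flag).
* Reference strand only; no reverse-complement or shift augmentation.
* Grid-search ties break towards the smaller learning rate, then the
  smaller weight decay; duplicate grid values are dropped with a warning.
* PSL parsing rejects negative-strand alignments explicitly rather than
  silently mis-mapping them; the synthetic mapper only emits `+`.
* Checkpoints are a binary weights container plus a JSON sidecar (config,
  seed, epoch, parent, trunk checksum); loading verifies the checksum.
* All randomness flows through explicit seeds; derived streams (epoch
  shuffles, replicate draws, zero-overlap assignments) use a documented
  integer-hash derivation, so results are bit-reproducible on a fixed
  platform. Exact bit-reproducibility across BLAS implementations is not
  guaranteed.

## Known limitations

Training is pure R on one CPU: full-scale (196-kb window, 1536-channel)
training is out of reach by design — the full-scale configuration exists to
validate geometry and parameter accounting, and the methodology is
exercised at desk scale. The forward pass materialises im2col matrices, so
full-scale inference would also be memory-hungry. Dropout uses the global
RNG stream; two otherwise-identical runs differ if dropout is enabled and
the surrounding code consumes RNG draws differently. Batch sizes larger
than 1 average per-window normalisation statistics rather than pooling them
across the batch.
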