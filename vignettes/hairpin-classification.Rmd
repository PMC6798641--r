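---
title: "Classifying pre-miRNA hairpins from sequence and secondary structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pre-miRNA hairpins from sequence and secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Precursor microRNAs (pre-miRNAs) are ~60–120 nt RNAs that fold into a
characteristic stem–loop: two roughly complementary arms pair into a stem
closed by a short terminal loop. Genome-wide screens produce large numbers
of candidate hairpins, of which only a small minority are genuine
pre-miRNAs — typically a 7–8:1 excess of negatives. `premirnet` implements
a classifier that takes the raw sequence together with its dot-bracket
secondary structure and predicts whether the molecule is a pre-miRNA,
learning its own features rather than relying on hand-crafted ones
(k-mer frequencies, folding energies, melting temperatures and the like).

```{r setup}
library(premirnet)
```

## Inputs and encoding

Each record is a sequence over `{A,C,G,U}` plus a dot-bracket string of
equal length (`(` and `)` mark paired bases, `.` unpaired ones).
Structures can be read from RNAfold-style output (`read_rnafold()`),
computed by an external MFE folder (`fold_external()`), or by the built-in
Nussinov folder (`fold_nussinov()`), which maximises the number of nested
AU/GC/GU pairs subject to a minimum loop of 3 nt. The Nussinov folder is
a combinatorial surrogate, not a thermodynamic model: it keeps the
pipeline self-contained and is what the synthetic benchmarks use, but for
real data an MFE folder should be preferred. Its traceback is
deterministic (ties prefer pairing the leftmost 5' index), so the whole
pipeline is reproducible.

Sequence and structure are one-hot encoded position by position — four
channels `A,C,G,U` and three channels `(`, `.`, `)`:

```{r}
encode_sequence("ACGUU")$mat
encode_structure("(...)")$mat
```

Records are zero-padded on the 3' end to a common length (the dataset
maximum, capped at 180 nt by default). Zero rows lie outside both one-hot
alphabets, so padding never masquerades as data; a mask vector carries the
true lengths so that pooling and the recurrent layers ignore padding
exactly. Residues outside the alphabet (`N`, ambiguity codes) encode as
all-zero rows rather than being dropped or imputed.

## The network

Two convolutional branches (16 filters each, window 5, stride 1) scan the
sequence and the structure separately; each branch applies ReLU and
non-overlapping max-pooling of width 2. The pooled maps are concatenated
position-wise along the channel axis and fed to a bidirectional LSTM with
20 hidden units per direction. The LSTM cells use peephole gate
connections — the gates read the memory cell directly, in the standard
diagonal (elementwise) form — with the update order: input gate, forget
gate (both reading the previous cell state), candidate update, output
gate (reading the new cell state). The two final direction states
(2 × 20 values) pass through a dense ReLU layer of width 256 and a final
sigmoid unit giving the probability of being a pre-miRNA.

The recurrent sizes (20) and dense width (256) follow the published
architecture this package reimplements; the convolutional hyperparameters
(16 filters, window 5, pool 2) are this package's defaults, chosen small
enough for CPU training, and all are adjustable through `model_config()`.

Three regularisers address overfitting, mirroring the reference protocol:

* **Batch normalisation** after the max-pooling, after the BLSTM, and
  after the dense ReLU. Batch variance uses the `n − 1` (sample) form
  with an epsilon of 1e-5; at prediction time the batch statistics are
  replaced by running estimates maintained as an exponential moving
  average (momentum 0.99), since a "total mean over all batches" is only
  defined once training ends. Normalisation statistics are computed over
  valid (unpadded) positions only.
* **Dropout** (p = 0.5) on the same three outputs, in training mode only.
* **L2 weight decay** (λ = 1e-4, unstated in the reference and therefore
  a package default) on the two dense weight matrices only.

The full forward and backward passes are implemented from first
principles (R orchestration over compiled kernels for the recurrence,
convolution and normalisation); a finite-difference gradient check in the
test suite holds the analytic gradients to a relative error of 1e-4.

## Loss and class imbalance

Training uses focal loss by default. With `p_y` the predicted probability
of the true class,

$$L = (1 - p_y)^\gamma \,(-\alpha_y \log p_y), \qquad
  \alpha_y = \begin{cases}\alpha & y = 1\\ 1-\alpha & y = 0,\end{cases}$$

with γ = 2 and α = 0.25. Note the convention: α weights the *positive*
class, so α = 0.25 nominally down-weights the minority — these are the
original focal-loss defaults, and the focusing term $(1-p_y)^\gamma$ is
what actually shifts training effort to the rare hard examples. At γ = 0
the loss reduces exactly to α-weighted cross-entropy (a property test
asserts this to 1e-12). The class-weight alternative (`weighted_ce`, 0.9
for positives, 0.1 for negatives) and plain cross-entropy are available
through `loss_config()` for comparison. Predicted probabilities are
clamped to `[1e-7, 1 − 1e-7]` before the logarithm; batches are reduced
by the mean.

## Training protocol

`train_config()` defaults to the reference protocol: Adam (β₁ = 0.9,
β₂ = 0.999, ε = 1e-8) at learning rate 0.001, mini-batches of 128,
300 epochs, no early stopping (an optional patience knob exists but is
off: the reference protocol trains a fixed budget). 10% of the data is
held out as a test set and the remaining 90% feeds stratified five-fold
cross-validation (`cross_validate()`), aggregated by unweighted fold
means. The published protocol is ambiguous between a 10%/90% and an
80%/20% split; this package defaults to 10%/90% and exposes
`test_fraction`. All randomness — splitting, initialisation (Glorot for
dense/convolutional weights, orthogonal recurrent blocks, forget-gate
bias 1), shuffling, dropout — derives from a single seed, and
single-threaded runs are bit-reproducible.

A trailing mini-batch of size 1 cannot be batch-normalised; the trainer
merges it into the previous batch.

## Synthetic data: what it does and does not show

`simulate_hairpins()` generates labelled datasets with the statistical
shape of a pre-miRNA screen: positives are built hairpins — a random 5'
arm of 18–30 bp, a 4–10 nt loop, the arm's reverse complement with a 5%
per-position mutation rate, and 5–15 nt unstructured flanks (total
~50–100 nt); negatives default to i.i.d. random sequences with lengths
drawn from the positive length model, at 7.4 negatives per positive, the
imbalance of the curated benchmark corpus. Harder decoys are available:
dinucleotide-shuffled hairpins (identical dinucleotide counts, Euler-path
shuffle) and mononucleotide-composition-matched draws, because real
negative sets (tRNA, snoRNA, exonic fragments) are themselves structured
and a purely random benchmark overstates performance.

The default sizes (500 positives / 3,700 negatives) keep a full
scaled-down training — 50 epochs — to a few CPU-minutes; the test suite
and the acceptance script use exactly these conditions. Passing them
shows the implementation learns and generalises under imbalance on data
matching its assumptions; it does not certify performance on curated
genomic data, whose negatives are far harder than any of the synthetic
decoy models.

## Evaluation

`metrics_report()` computes sensitivity, specificity, PPV, F-score,
g-mean (√(SE·SP)), AUROC (rank-based with midrank ties) and AUPR
(step-wise interpolation, i.e. average precision) at the 0.5 decision
threshold; a score exactly at the threshold is called positive (the
boundary side is unspecified in the reference). Metrics with zero
denominators are reported as 0 and flagged. `relative_improvement()`
implements the benchmark-table arithmetic (percent over the best
competing method, two decimals), and `benchmark_table()` ships the
published per-method results and per-dataset counts those comparisons are
computed from.

## Numerical and design notes

* Nussinov DP is O(n³) with the traceback preferring the leftmost
  pairable 5' index; wobble GU/UG pairs are allowed.
* Max-pooling ties keep the earliest window position; a trailing window
  remainder is dropped.
* The reference text writes the peephole terms as full matrices; the
  diagonal form implemented here is the standard reading of that
  notation, and a `peephole = FALSE` switch gives a plain LSTM.
* Whether the reference's dense head had one or two layers is ambiguous;
  this package uses ReLU(256) followed by the sigmoid unit, matching the
  stated "hidden nodes in the FC layer: 256".
* Dropout masks, shuffles and initial weights are drawn from R's RNG;
  the compiled kernels are deterministic, so fixed-seed runs are
  bit-identical on one thread. Multi-threaded BLAS may relax bit
  equality.

## Limitations

* The built-in folder maximises pair counts, not free energy; real
  pre-miRNA structures from RNAfold can differ substantially.
* The synthetic generator models hairpin geometry and composition, not
  miRBase sequence statistics; absolute metric values on synthetic data
  are optimistic. In particular, because the default synthetic screen is
  close to separable, focal loss and plain cross-entropy both train to
  near-ceiling sensitivity there, and their difference (reported by the
  acceptance script as `focal_minus_ce_se`) sits within one or two test
  examples of noise — the imbalance-handling benefit of focal loss shows
  on hard data, not on clean synthetic decoys.
* Published benchmark numbers on the curated human/cross-species/new
  datasets require those datasets; this package reproduces the published
  tables' arithmetic and the behaviour of the method on synthetic data,
  not the curated-data results themselves.
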