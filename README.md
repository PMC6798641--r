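# premirnet

Classification of precursor microRNA (pre-miRNA) hairpins from an RNA
sequence and its dot-bracket secondary structure, for people screening
candidate stem-loops (e.g. from small-RNA-seq or genome scans) who need a
classifier that learns its own features instead of relying on hand-crafted
ones.

Pre-miRNAs are ~60–120 nt stem-loops, and genuine ones are heavily
outnumbered by decoy hairpins (about 7.4 non-pre-miRNAs per pre-miRNA in
the curated benchmark corpus). `premirnet` implements a cascaded
convolutional–recurrent classifier for this task:

* the sequence (one-hot over `A,C,G,U`) and the structure (one-hot over
  `(`, `.`, `)`) each pass through a convolutional branch
  (conv → ReLU → max-pool);
* the two branches are concatenated position-wise and scanned by a
  bidirectional peephole LSTM (20 hidden units per direction);
* a batch-normalised dense layer (256 ReLU units) and a sigmoid unit
  output P(pre-miRNA);
* training uses Adam (batch 128, learning rate 0.001) and **focal loss**

  L = (1 − p_y)^γ · (−α_y · log p_y),  γ = 2, α = 0.25,

  which down-weights abundant easy negatives so the minority class is
  learned; class-weighted and plain cross-entropy are available for
  comparison. Dropout (p = 0.5), batch normalisation and L2 weight decay
  regularise the network.

Performance is reported with the standard suite: sensitivity (SE),
specificity (SP), PPV, F-score, g-mean = √(SE·SP), AUROC and AUPR, at a
0.5 decision threshold.

The package is self-contained: it reads FASTA and RNAfold-style structure
files, but also ships a Nussinov base-pair-maximisation folder (so no
external folding binary is needed) and a seeded synthetic hairpin
generator that reproduces the 7.4:1 imbalance regime for end-to-end
testing. The entire network — forward pass, backpropagation, Adam, batch
norm, focal loss — is implemented in the package (R + compiled kernels);
there is no deep-learning framework underneath.

## Worked example

Simulate a labelled screen (120 hairpins, 4 decoys each, 5% stem
mutations), train for 40 epochs, and evaluate on the held-out test split:

```r
library(premirnet)

ds  <- simulate_hairpins(synthetic_params(n_pos = 120, imbalance_ratio = 4,
                                          seed = 7))
enc <- encode_dataset(ds)
cfg <- train_config(epochs = 40, batch_size = 64, seed = 7)
sp  <- split_dataset(enc, cfg)

fit <- train_network(enc[setdiff(seq_along(enc$id), sp$test)],
                     model_config(), cfg)
evaluate_model(fit, enc[sp$test])
#> # A tibble: 1 × 7
#>      se    sp   ppv f_score g_mean auroc  aupr
#>   <dbl> <dbl> <dbl>   <dbl>  <dbl> <dbl> <dbl>
#> 1 0.833     1     1   0.909  0.913 0.979 0.946
```

Of the 12 test positives, 10 are recovered (SE 0.83) with no false
positives among the 48 decoys (SP and PPV 1.0); the ranking is
near-perfect (AUROC 0.98). Early in training the imbalanced classes bias
the model toward calling everything negative; sensitivity appears once
the focal term has shifted effort to the positives, so short-budget runs
should watch the trace. `predict(fit, newdata)` returns a tibble of `id`, `.prob`,
`.pred`; `tidy(fit)` gives the per-epoch trace; `autoplot(fit)`,
`plot_roc()` and `plot_pr()` draw the training and ranking curves;
`cross_validate()` runs the stratified five-fold protocol.

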