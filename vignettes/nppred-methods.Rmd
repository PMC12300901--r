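---
title: "Predicting neuropeptides with nppred: models, descriptors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting neuropeptides with nppred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neuropeptides (NPs) are neuron-derived signalling peptides — typically short
(tens of residues), processed from precursor proteins, released in a
regulated manner and acting through receptors. Distinguishing genuine NPs
from other peptides by sequence alone is a binary classification problem
with well-documented compositional signal: NPs tend to be shorter, enriched
in G, P, F, S and R, depleted in hydrophobic/aliphatic residues, and carry
characteristic short motifs. `nppred` implements a complete pipeline for
this task: descriptor computation, feature construction and selection, three
complementary classifiers combined by hard majority vote, dataset hygiene
(redundancy and leakage control), evaluation, and a seeded synthetic data
generator so every stage is testable without external downloads.

## The classifier

Three voters are trained on the same labelled training set and combined by
hard majority vote (three voters, two classes — no ties):

* an RBF-kernel SVM (C = 19, gamma = 0.125) on the min-max normalized
  descriptor matrix (the normalization under which the published kernel
  width is meaningful at this dimensionality);
* an extremely randomized trees model (900 trees, random split points) on
  the raw descriptor matrix;
* a small CNN over skip-gram k-mer embeddings: two 1-D convolutions (64 and
  32 filters, kernel 3), each followed by max pooling (size 2), a 32-unit
  ReLU dense layer, dropout 0.3, a sigmoid output, trained with Adam
  (learning rate 1e-4) and binary cross-entropy for up to 100 epochs with
  early stopping (patience 10) on a stratified 10% validation split.

The hard vote yields the reported label and a vote fraction in
{0, 1/3, 2/3, 1}. Because four score levels make a coarse ROC, the
*continuous* ensemble score defaults to the mean of the three calibrated
voter scores; the vote fraction is selectable (`score_mode = "vote"`).
SVM scores are Platt-style sigmoid calibrations fitted on seeded
out-of-fold decision values — we do not use libsvm's internal
`probability = TRUE` machinery because its cross-validation cannot be
seeded from R, which would break the package's reproducibility contract.

The wider six-model pool of `default_specs()` (adding KNN with k = 9 and
inverse-distance weights, a pruned decision tree, a 300-tree random forest,
and XGBoost with 150 rounds, depth 5, eta 0.03, subsample 0.6) is provided
for benchmarking; only SVM, extra trees and the CNN enter the shipped
ensemble.

## Descriptor families

`featurize()` concatenates seven handcrafted families in a fixed, persisted
order (875 columns with the default configuration):

1. **AAC** (`mer1..mer20`): residue fractions.
2. **Pseudo amino acid composition** (117 columns): Chou-style type-1
   composition with sequence-order correlation factors over the
   standardized property triplet hydrophobicity / hydrophilicity /
   side-chain mass (`PAAC1..23`, lambda = 3, weight = 0.05); a parallel
   two-property variant at lambda = 2 (`PsePC1..22`); a series
   (product-correlation) variant (`PseSC1..26`); and amphiphilic blocks for
   hydrophobicity and hydrophilicity separately (`APAAC1..46`). The block
   dimensionalities pin these choices: 20 + lambda, 20 + 2, 20 + 2*lambda
   and 2 * (20 + lambda) respectively.
3. **CTD** (147 columns): composition, transition and five-point
   distribution percentiles over three-group recodings for seven
   physicochemical properties (Dubchak convention): normalized van der
   Waals volume, charge, hydrophobicity, polarity, secondary structure,
   solvent accessibility, and polarizability as the conventional seventh,
   so 7 x 3 = 21 matches `CTDC1..21`.
4. **Quasi-sequence-order** (52 columns): coupling numbers `tau_d`
   (lag = 3) and QSO values (weight = 0.1) for two residue distance
   matrices. The Grantham matrix is computed from the published
   composition/polarity/volume components (mean pairwise distance
   normalized to 100). The second matrix slot — filled by the
   Schneider–Wrede matrix in the original descriptor definition — holds a
   **constructed** physicochemical distance (euclidean over the
   standardized Chou triplet) because the published values were not
   available to transcribe; it is named `qso_physchem` and must not be
   read as the Schneider–Wrede table.
5. **Scale-based physicochemical descriptors** (76 columns): sequence
   means of Z-scales, VHSE, MS-WHIM and T-scales (transcribed from the
   literature) and of Cruciani-, FASGAI-, ProtFP-, ST-style and
   BLOSUM62-derived sets. The latter five are *reconstructions*:
   principal-component (FASGAI: varimax-rotated) summaries recomputed from
   the AAindex collection or from BLOSUM62, at the published
   dimensionalities. Plus: aliphatic index (Ikai), Geary autocorrelations
   (4 properties x lags 1–3; defined 0 for constant properties), lag-1
   auto- and cross-covariances, Boman index (Radzicka–Wolfenden energies,
   proline undetermined in the source and set to 0), net charge at pH 7 and
   isoelectric point (Henderson–Hasselbalch with the Bjellqvist pK set by
   default, EMBOSS selectable; pI by bisection), Guruprasad instability
   index, and Eisenberg hydrophobic moments at 100° (helix) and 160°
   (sheet).
6. **k-mers** (457 columns): all 400 overlapping dipeptide frequencies
   (frequencies, not counts, for length invariance) and raw occurrence
   counts of a fixed, curated list of 57 NP-associated 3-mers.
7. **Conformational propensities** (`tango1..tango6`): six per-sequence
   values (aggregation, amyloid, turn, helix, helical aggregation,
   beta-strand). The reference implementation of these six propensities is
   an external closed-source program; the default `"surrogate"` mode
   averages per-residue propensity scales instead — Chou–Fasman turn,
   helix and sheet parameters plus documented constructed combinations
   (e.g. aggregation = standardized mean of Kyte–Doolittle hydropathy and
   sheet propensity). `"zero"` disables the block at stable width;
   `"external"` reads a per-record table. The surrogate keeps the schema
   stable without a binary dependency but is *not* the original
   statistical-mechanics model.

A 982-descriptor total is sometimes quoted for this descriptor battery,
but it cannot be reconstructed from the per-family dimensionalities above,
which sum lower; the engine therefore treats the registry width as
configuration-derived (875 by default) rather than forcing a constant.

## Composite logistic features

A composite feature is the linear predictor (logit) of a logistic
regression fitted on a named set of raw descriptors, exported as a new
column. `logistic1` ships with its published component set: AAC of Phe
(`mer5`), dipeptide compositions of LR, RF and FN (`kmer195`, `kmer285`,
`kmer92`), the serine series-mode pseudo-composition term (`PseSC16`) and
net charge. Coefficients are data-fit artifacts trained on the user's
training partition and stored in the model bundle. Fits use hand-coded
IRLS with a fixed mild ridge (1e-4 on standardized inputs) — always on,
for numerical stability, and acting as the fallback under perfect
separation. Slots `logistic2..15` are configurable and disabled until the
user supplies component lists, which were never published.

## Feature selection

`relieff_scores()` implements standard ReliefF: min-max scaled features,
Manhattan-distance neighbor search, k = 10 neighbors by default, exhaustive
iteration over all records (deterministic; a seed is only consumed when a
subset of iterations is requested). `correlation_screen()` reports all
feature pairs with |r| above a threshold (0.8 default) and counts
n(n-1)/2 total pairs. Because it was never stated whether the final models
consumed a selected subset or the full matrix, selection is off by default
(`n_select = NULL`) and both paths are wired.

## Dataset preparation

`combine_and_subtract()` implements exact-sequence set algebra
(union of training sources minus all test sequences, label conflicts are
errors). `redundancy_filter()` is a faithful greedy incremental
longest-first clustering at 90% identity, with identity defined as matched
positions of the optimal global alignment divided by the shorter sequence
length (the convention of the standard clustering tool; the source never
defines identity). No word-filter speedups are used — at the few thousand
sequences typical here, full dynamic programming via Biostrings is
affordable. `leakage_screen()` searches each test sequence against the
training set with affine-gap Smith–Waterman (BLOSUM62, gap 11/1) and a
Karlin–Altschul E-value (lambda = 0.267, K = 0.041, database-size scaled);
an external aligner can reproduce the exact historical protocol, but the
built-in screen keeps the pipeline dependency-free.

## Evaluation

`np_metrics()` computes ACC, Sn, Sp, Precision, MCC and F1 by the standard
confusion-count formulas; empty denominators yield 0 and are flagged.
`roc_auc()` uses the rank statistic (ties mid-ranked; equal to the
trapezoid over the full threshold sweep) with a seeded percentile
bootstrap CI (1000 replicates by default). `cross_validate()` builds
seeded stratified folds and **pools** fold predictions (the alternative,
averaging per-fold metrics, was not stated in the source; pooling uses
every prediction exactly once and is the package's documented choice).
All label-dependent fitting — composites, standardizer, selection, all
three voters, and by default also the skip-gram embedding — happens inside
each training fold.

## Synthetic data: what it emulates, and what it does not

`default_np_spec()` encodes the class-conditional structure reported for
curated NP training data: positives average 24 residues, negatives 27
(Poisson lengths, floor 4); positives are enriched (multiplier 2 before
renormalization) in G, P, F, S, R and negatives in V, T, M, C, K, I, L;
30% of positives carry one curated 3-mer motif spliced at a random
position. Residue draws are i.i.d., so the fixtures carry composition,
length and motif signal but no grammar, no precursor structure, no
cleavage-site context and no homology families. Passing the end-to-end
tests therefore demonstrates that the pipeline recovers planted
composition/motif structure — not that it attains any particular accuracy
on real neuropeptide collections, which require the original curated
datasets. The null control (`null_control = TRUE`) equalizes the two
classes and must drive 10-fold CV accuracy to chance; this guards against
information leaks anywhere in the pipeline.

Default problem sizes (400 peptides per class, 10-fold CV) were chosen as
the smallest round sizes at which the planted signal is comfortably
recoverable and class-balanced folds remain well-populated.

## Numerical and implementation choices

* Skip-gram embeddings (120-d, window 5, 5 negatives, 5 epochs, unigram^0.75
  negative table, linear learning-rate decay) and the CNN are implemented
  in compiled code (RcppArmadillo) with hand-written backpropagation and a
  private Mersenne-Twister stream — single-threaded and bit-reproducible
  for a fixed seed. Inference has no active stochastic layers.
* The CNN pads/truncates token grids to `max_len`. The default adapts to
  the training corpus (its maximum token count, capped at 100, floor 12):
  all-zero padding rows beyond the corpus maximum carry no information and
  only cost convolution work. Truncation removes C-terminal tokens.
* Tree-model predictions are invariant to monotone feature rescaling;
  SVM/KNN are made scale-robust by a min-max normalizer fitted on the
  training ranges and persisted inside the model. Seeds for every stochastic stage are mandatory arguments and are
  recorded in the bundle manifest, which deliberately contains no
  timestamp so identical seeds reproduce it byte-for-byte.
* Degenerate inputs: constant features get ReliefF weight 0 and are
  reported as undefined-r by the correlation screen; Geary correlation of
  a constant property is 0 by convention; CTD distribution values of an
  absent group are 0; homopolymers have all sequence-order correlation
  terms equal to 0.
* ReliefF ties in `select_top()` break by schema order; k-mer enrichment
  ties break lexicographically.

## Known limitations

* The conformational block is a scale-average surrogate, not the original
  aggregation model; treat `tango1..6` as coarse propensity summaries.
* Five of the nine multidimensional scale sets are AAindex/BLOSUM
  reconstructions, not the published factor tables; their sequence means
  are internally consistent and documented, but numerically different from
  implementations shipping the original tables.
* The built-in E-value is a Karlin–Altschul approximation with fixed
  gapped-BLOSUM62 parameters, adequate for leakage screening, not a
  replacement for a full search tool on large databases.
* On the synthetic fixtures the CNN is the weakest voter: i.i.d.-residue
  sequences carry mostly compositional signal, which the handcrafted
  descriptors capture more directly than a motif-oriented convolutional
  model. The majority vote is then carried by the SVM and extra-trees
  voters; on real peptide collections with conserved local motifs the CNN
  branch is expected to contribute more.
* Composite features `logistic2..15` are empty slots by design.
```
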