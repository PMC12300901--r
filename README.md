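# nppred — ensemble neuropeptide prediction from sequence

`nppred` classifies peptides as **neuropeptides (NPs)** or
**non-neuropeptides** from primary sequence alone. Neuropeptides — short,
neuron-derived signalling peptides acting through receptors — carry strong
compositional signal: they are shorter on average, enriched in G, P, F, S
and R, depleted in aliphatic/hydrophobic residues, and carry characteristic
short motifs. The package is aimed at computational peptide-discovery work:
screening candidate sequences ahead of experimental validation, and
benchmarking sequence-based NP classifiers under controlled conditions.

## The model

A record is a validated peptide sequence over the 20 canonical residues
(length ≥ 4). Each sequence is mapped to a descriptor vector
**x** ∈ ℝ^875 spanning eight families: amino acid composition (AAC),
pseudo amino acid composition (PAAC/PsePC/PseSC/APAAC, λ = 3, w = 0.05),
CTD (composition/transition/distribution over 7 three-group properties),
quasi-sequence-order descriptors (lag = 3, w = 0.1, two residue distance
matrices), 76 scale-based physicochemical indices (Z-scales, VHSE, MS-WHIM,
T-scales, aliphatic/Boman/instability indices, net charge, pI, hydrophobic
moments, Geary autocorrelations, …), 400 dipeptide frequencies, 57 curated
3-mer motif counts, and six conformational propensities. Composite
*logistic features* append the fitted logit
β₀ + Σ βᵢ·xᵢ of a logistic regression over named components
(`logistic1` = {AAC(F), 2-mer(LR), 2-mer(RF), 2-mer(FN), PseSC16, charge}).

The classifier is a **hard majority vote** over three voters trained on the
same data:

| voter | input | configuration |
|---|---|---|
| SVM | min-max-normalized descriptors | RBF kernel, C = 19, γ = 0.125 |
| Extra trees | raw descriptors | 900 trees, random splits |
| CNN | 120-d skip-gram k-mer embedding grid | conv 64 → pool → conv 32 → pool → dense 32, dropout 0.3, Adam 1e-4, early stopping |

With three voters and two classes the vote is never tied; the continuous
ensemble score (for ROC/AUC) is the mean of the three calibrated voter
scores. Supporting modules provide ReliefF feature weighting with a Pearson
redundancy screen, dataset algebra with greedy 90%-identity redundancy
filtering and a Smith–Waterman/E-value train–test leakage screen,
confusion-matrix metrics (ACC, Sn, Sp, Precision, MCC, F1), ROC/AUC with
bootstrap CIs, stratified k-fold cross-validation, class-conditional
composition analytics (group percentages, positional frequencies, dipeptide
log-odds), and a seeded synthetic peptide generator encoding the NP/non-NP
class structure so the whole pipeline is testable offline.

See `vignettes/nppred-methods.Rmd` for the full model description, every
tunable parameter, and the design decisions (including which residue scale
tables are literature transcriptions and which are documented
reconstructions).

## Worked example

```r
library(nppred)

# a labelled synthetic dataset: 60 NPs vs 60 non-NPs
ds <- generate_peptides(default_np_spec(n_pos = 60, n_neg = 60), seed = 7)

model <- fit_ensemble(ds, seed = 42)       # SVM + extra trees + CNN
pred  <- predict_ensemble(model, ds)
pred
#> # A tibble: 120 × 7
#>   id    label vote_fraction score_svm score_et score_cnn score_ensemble
#>   <chr> <int>         <dbl>     <dbl>    <dbl>     <dbl>          <dbl>
#> 1 pos1      1         1             1    0.702     0.501          0.734
#> 2 pos2      1         0.667         1    0.879     0.500          0.793
#> 3 pos3      1         0.667         1    0.788     0.499          0.762
#> # i 117 more rows

np_metrics(confusion_counts(ds$label, pred$label))
#> # A tibble: 1 × 10
#>     ACC    Sn    Sp Precision   MCC    F1    TP    TN    FP    FN
#>   <dbl> <dbl> <dbl>     <dbl> <dbl> <dbl> <int> <int> <int> <int>
#> 1     1     1     1         1     1     1    60    60     0     0
```

Each row gives the per-voter scores, the vote fraction (0, 1/3, 2/3 or 1)
and the majority label (1 = neuropeptide). Training-set accuracy of 1 on
this small separable fixture just shows the pipeline wiring; honest
performance estimates come from `cv_ensemble()` (stratified 10-fold CV with
all fitting inside each fold), e.g. pooled ACC/AUC on the default 400 + 400
synthetic conditions as recomputed by the acceptance script below.

A shell interface mirrors the workflow
(`simulate`, `prep`, `featurize`, `select`, `train`, `predict`, `evaluate`,
`analyze`):

```sh
Rscript inst/scripts/nppred simulate --output sim --seed 3 --n-pos 100 --n-neg 100
Rscript inst/scripts/nppred train --input sim/synthetic.fasta --model bundle --seed 4
Rscript inst/scripts/nppred predict --input sim/synthetic.fasta --model bundle --output pred.tsv
```

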