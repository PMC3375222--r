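# sumosite

Sequence-based prediction of protein **sumoylation sites** — lysines that
accept a covalent SUMO (small ubiquitin-like modifier) attachment. Most,
but not all, substrates carry the core consensus motif **ψKxE** (ψ a large
hydrophobic residue V/I/L/M/F, K the modified lysine, x anything, E
glutamate), and roughly a quarter of experimentally confirmed sites fall
outside it, so motif matching alone both over- and under-predicts. This
package is for computational biologists who want a trainable, inspectable
predictor and a reproducible evaluation harness rather than a web-server
black box.

## Method

Every lysine in a protein is represented by the window of 2n+1 = 25
residues centered on it; positions beyond the termini are filled with an
artificial 21st letter `O`, giving the alphabet `ACDEFGHIKLMNPQRSTVWYO`.
Windows are turned into fixed-length feature vectors under one of eight
schemes:

| scheme | idea | dimension |
|---|---|---|
| `binary` | one-hot per non-center position | 21·2n = 504 |
| `cksaap` | counts of k-spaced residue pairs, k = 0..4 | 441·5 = 2205 |
| `pssm` | PSI-BLAST profile row per window position | 20·25 = 500 |
| `knn` | D_p/D_n ratios of mean BLOSUM62 distance to k nearest positive vs negative references, k ∈ {1,3,5,7,9,15} | 6 |
| `six` / `nine` | one-hot over reduced physicochemical alphabets | 144 / 216 |
| `zscales` | five physicochemical descriptors per position | 120 |
| `hydrobinary` | `binary` plus raw hydrophobicity at offsets −1..+2 around the K | 504 + 4 = 508 |

A soft-margin SVM with RBF kernel exp(−γ‖u−v‖²) — solved by an internal
SMO implementation, no external SVM dependency — separates positives from
negatives. Class imbalance (≈1:25 in curated data) is handled by seeded
subsampling of negatives to 1:10. Performance is reported as sensitivity
Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy, Matthews
correlation

MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

and ROC/AUC over all decision-score thresholds, under stratified 10-fold
or leave-one-out cross-validation with repeated negative resampling
(mean ± sd). Predictions are called at three operating thresholds on the
SVM margin: low −0.2, medium 0, high +0.2 (nested call sets).

Dataset construction mirrors curated-corpus practice: candidate extraction
of every lysine, greedy redundancy filtering so no two retained 25-mers
share ≥ 40% positional identity, and a seeded synthetic-proteome generator
(planted ψKxE sites, configurable non-consensus fraction and imbalance)
that makes the whole pipeline testable with no downloads.

## Worked example

```r
library(sumosite)

pro   <- generate_proteome(n_pos = 60, nonconsensus_frac = 0, seed = 42)
ds    <- build_candidate_set(pro$proteins, pro$truth[pro$truth$label == 1, ])
ds
#> fragment_dataset: 60 positives, 1571 negatives (window 25)

train <- sample_negatives(ds, ratio = 10, seed = 42)
cv    <- kfold_cv(train, "hydrobinary", C = 8, gamma = 1/508,
                  folds = 10, seed = 42)
#> 10-fold CV  Sn 100.0%  Sp 99.5%  Ac 99.5%  MCC 0.973  AUC 1.000
```

The planted consensus signal is recovered almost perfectly: all 60
positives score above the medium cutoff and 3 of 600 sampled negatives
are false positives. Training a final model and scoring a query protein:

```r
enc   <- encode_dataset(train, "hydrobinary")
model <- train_model(enc$x, enc$y, C = 8, gamma = 1/508, scheme = "hydrobinary")
model
#> RBF-SVM (151 SVs, C = 8, gamma = 0.001969, scheme = hydrobinary)

q  <- data.frame(id = "Q1", sequence = "MKAVKWEAAAAKLE")
qs <- build_candidate_set(q, data.frame(protein_id = character(),
                                        position = integer()))
s  <- decision_scores(model, encode_dataset(qs, "hydrobinary")$x)
data.frame(position = qs$position, score = round(s, 3),
           low = classify(s, "low"), medium = classify(s, "medium"),
           high = classify(s, "high"))
#>   position  score low medium high
#> 1        2 -3.283   0      0    0
#> 2        5  0.175   1      1    0
#> 3       12  0.067   1      1    0
```

K5 sits in a textbook `V-K-W-E` consensus context and is called at the low
and medium thresholds; K2 (`M-K-A-V`, no +2 glutamate) is rejected; K12
(`A-K-L-E`) has the acidic +2 but no hydrophobic −1 and lands just above
the medium cutoff — exactly the borderline the three nested thresholds are
for.

The same workflows are scriptable via the CLI wrapper
(`inst/scripts/sumosite`): subcommands `simulate`, `build`, `train-eval`,
`predict`, `sweep`.

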