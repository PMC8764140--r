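# kcrcontact

Contact-aware feature encoding for lysine-crotonylation (Kcr) site
prediction in proteins.

Most Kcr predictors describe a candidate site by the residues *linearly*
adjacent to it — a window of half-width *n* (a segment of 2*n*+1
residues) centered on the lysine.  In the folded protein, however,
residues far away in sequence can sit right next to the site in space.
`kcrcontact` brings that spatial neighborhood into the feature space via
predicted residue–residue contact maps (tables of residue index pairs
with a contact probability, thresholded at 0.80):

* **RRC** (residue–residue composition, 20 dims): amino-acid
  composition P(a) = n(a)/D over the window *plus* the residues
  predicted to contact it;
* **RRPC** (residue–residue pair composition, 400 dims): the
  distribution of ordered residue-pair types (res(i), res(j)), i < j,
  among the thresholded contacts touching the window.

Around these it implements the full supervised protocol needed to
compare them against classical encoders under identical conditions:

* sequence encoders: AAC, AAPC (P(a,b) = n(a,b)/(D(D−1))), binary
  one-hot, CKSAAP (k = 1, 2, 3), EAAC, EGAAC, PSSM windows;
* chi-square (p ≤ 0.05 retention) and information-gain feature
  selection, fitted on the training split only;
* stratified 80/20 split, random undersampling of the training majority
  class to exactly 1:1 (test left imbalanced);
* grid-searched classifiers with stratified 5-fold CV: RBF SVM
  (C ∈ {2^0..2^10}, γ ∈ {2^-10..2^0}), random forest (1400–2400 trees),
  SGD logistic regression (cutoff 0.5);
* metrics: Sn, Sp, Acc, MCC, Recall, Precision, F1, ROC/AUC
  (Mann–Whitney rank form);
* a synthetic-data generator with independently switchable sequence-
  and contact-level planted signal, so the whole pipeline is testable
  without external data;
* I/O for FASTA, site-label tables, 6-column contact-prediction tables,
  PSI-BLAST ASCII PSSMs, and lossless CSV feature matrices.

It is aimed at method developers working on PTM site prediction who
want a reproducible, fully seeded reference implementation of the
contact-aware encoders and their evaluation harness.

## Worked example

Simulate a dataset whose positive sites carry both a sequence motif and
planted contact enrichment, then train and evaluate the contact-aware
RRPC pipeline:

```r
library(kcrcontact)

cfg <- synth_config(n_proteins = 120, seed = 42)
d   <- generate_dataset(cfg)

run <- run_pipeline(list(
  data = d, encoders = "rrpc", classifier = "rf",
  grid = data.frame(num_trees = c(1400, 1600)), seed = 7))
#> [kcrcontact] 120 proteins, 989 sites (91 positive)
#> [kcrcontact] encoded 989 samples x 400 dimensions (rrpc)
#> [kcrcontact] split: 791 train / 198 test
#> [kcrcontact] undersampled train: 73:73 (pos:neg)
#> [kcrcontact] fit rf: best num_trees=1400
#> [kcrcontact] test: Acc=0.914 AUC=0.898 MCC=0.614

run
#> <kcr_run> rrpc + rf
#>   120 proteins; 989 sites; train 791 (balanced 146) / test 198
#> <kcr_eval>  cutoff = 0.5
#>   counts: TP=15 FP=14 TN=166 FN=3
#>   Sn        0.8333
#>   Sp        0.9222
#>   Acc       0.9141
#>   MCC       0.6143
#>   Recall    0.8333
#>   Precision 0.5172
#>   F1        0.6383
#>   AUC       0.8975
```

Reading the report: of the 198 imbalanced test sites, the classifier
recovers 15 of the 18 true Kcr sites (Sn 0.83) while keeping 166 of 180
negatives (Sp 0.92); AUC 0.90 means a random positive outscores a
random negative 90% of the time.  Swapping `encoders = "aac"` into the
same config drops the AUC to near chance when the sequence channel is
off — the spatial signal is only visible to the contact-aware encoders.

The same stages are available piecewise — `read_fasta()`,
`read_contact_table()`, `build_feature_matrix()`,
`chi_square_select()`, `undersample_balance()`, `kcr_fit()`,
`kcr_evaluate()` — and from the shell via the thin wrapper
`inst/scripts/kcrtool` (subcommands `simulate`, `encode`, `select`,
`train`, `evaluate`, `run`).

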