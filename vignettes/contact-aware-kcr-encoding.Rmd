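---
title: "Contact-aware feature encoding for Kcr site prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-aware feature encoding for Kcr site prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lysine crotonylation (Kcr) is a post-translational modification whose
experimentally verified sites are scarce relative to the number of
unmodified lysines (roughly 1:10 in curated datasets).  Classical
predictors encode a candidate site by the residues linearly adjacent to
it: a window of half-width $n$ around the lysine, i.e. a segment of
length $2n+1$.  But a folded protein also places residues that are far
away in sequence directly next to the site in space.  Predicted
residue–residue contact maps (pairs $(i, j)$ with a contact probability)
make that spatial neighborhood available without solved structures, and
`kcrcontact` turns it into two feature encoders:

* **RRC** (residue–residue composition): amino-acid composition of the
  window *plus* the residues predicted to contact it — 20 dimensions;
* **RRPC** (residue–residue pair composition): the distribution of the
  400 ordered residue-pair types among the contacts that touch the
  window.

Around those sit the standard encoders (AAC, AAPC, binary one-hot,
CKSAAP, EAAC, EGAAC, PSSM windows), feature selection, imbalance
handling, three grid-searched classifiers, and a seven-metric evaluation
panel, so the contact-aware encoders can be compared against the linear
ones under one protocol.

## Encoders

All feature dimensions use the fixed alphabetical amino-acid order
`ACDEFGHIKLMNPQRSTVWY`.  Window positions that fall outside the protein
are padded with `-`; pads and unknown residues (`X`) are excluded from
every composition count, numerator and denominator alike.  This is the
one place where the classical AAC definition $P_x(k) = n_x(k)/n$ is
ambiguous under padding: we normalize by the number of residues actually
counted, so every composition vector is a proper distribution and the
definition coincides with the textbook one for interior sites.

* **AAC** — $P(a) = n(a)/D$ over the $D$ real residues; 20 dims.
* **AAPC** — ordered pairs of *distinct positions*:
  $P(a,b) = n(a,b) / (D(D-1))$; 400 dims.  The $D(D-1)$ denominator is
  exactly the count of ordered position pairs, which is why we count all
  of them rather than adjacent dipeptides.
* **Binary** — one-hot per position; pads and `X` give zero blocks.
* **CKSAAP** — for each gap $k \in \{1,2,3\}$ (configurable), pairs at
  positions $(p, p+k+1)$, normalized by the number of valid pairs at
  that gap.
* **EAAC / EGAAC** — AAC (or its five-group physicochemical variant) in
  every sliding sub-window of size 5 (configurable; the size is a
  convention, not a derived quantity).
* **PSSM** — the profile rows at the window's positions, zero rows at
  pads.

### Contact thresholding and qualification

A predicted contact is treated as real when its probability is
**strictly greater** than the threshold (default 0.80, following the
convention of reading "higher than 0.8" strictly).  A thresholded
contact *qualifies* for a site's window when at least one endpoint lies
among the window's covered positions.

* For **RRC**, each qualifying contact with exactly one endpoint inside
  contributes the residue at its *outside* endpoint, appended at the
  tail of the segment; duplicate positions are appended once, and
  both-endpoints-inside contacts append nothing (their residues are
  already in the window).  With an empty thresholded map RRC therefore
  reduces *exactly* to AAC — an identity the test suite asserts
  elementwise.
* For **RRPC**, every qualifying contact $(i, j)$, $i<j$, contributes
  the ordered pair $(\mathrm{res}(i), \mathrm{res}(j))$ — smaller
  sequence index first.  Counts are normalized by the number of
  contributing contacts; no qualifying contacts gives the all-zero
  400-vector, keeping the dimension fixed.  The normalization constant
  is our choice (none is canonical): it makes RRPC a distribution
  comparable across sites with different contact counts, at the price of
  erasing the count itself.  Both-inside contacts do count for RRPC —
  they are genuine spatial pairs in the window's neighborhood.

## Feature selection

* **Chi-square**: per dimension, observed = class-wise sums of the
  (nonnegative) feature values, expected = class priors × total sum,
  $\chi^2 = \sum_i (n_i - np_i)^2/(np_i)$ with one degree of freedom;
  dimensions with $p > \alpha$ (default 0.05, uncorrected) are dropped.
  The class-sum construction is the standard way to apply the
  goodness-of-fit statistic to continuous nonnegative features.
* **Information gain**: each dimension is discretized into two
  equal-frequency bins at the training median (parameter-free and
  stable; configurable), and the gain
  $H(\mathrm{class}) - H(\mathrm{class}\mid \mathrm{bin})$ in bits is
  ranked descending.  The keep rule is gain $> 0$, with a `top_k`
  override, since no canonical deletion threshold exists.

Both selectors are *fitted on the training split only*; applying a
stored selection is a pure column subset, so no test information leaks
into the choice of dimensions.  If a selection keeps no dimension the
package raises an error rather than silently falling back.

## Protocol and classifiers

The evaluation protocol is: stratified 80/20 split (test left
imbalanced), random undersampling of the training majority class to an
exact 1:1 ratio, selection fitted on the balanced training matrix,
grid-searched classifier with stratified 5-fold cross-validation, and
scoring of the held-out test set.

* **SVM** (RBF): $C \in \{2^0,\dots,2^{10}\}$,
  $\gamma \in \{2^{-10},\dots,2^0\}$.
* **Random forest**: tree count in $\{1400, 1600, \dots, 2400\}$.
* **Logistic regression**: minibatch SGD on the cross-entropy loss
  (batch 32, learning rate $0.1/(1+0.01\,\mathrm{epoch})$, tolerance
  $10^{-4}$ on the epoch loss, at most 1000 epochs); no grid.

Open choices we fixed: the grid-search objective is mean validation AUC
(accuracy available as an option); ties go to the first grid point in
iteration order ($C$ ascending then $\gamma$ ascending; tree count
ascending); features are z-standardized (training statistics) for the
SVM and logistic regression but not the random forest, because RBF
kernels and gradient steps are scale-sensitive while trees are not.
SVM scores are the Platt-free map $\sigma(d)$ of the decision value
$d$ — monotone, deterministic, in $[0,1]$, and its 0.5 cutoff coincides
with the SVM decision boundary (libsvm's internal probability
calibration uses randomized cross-validation, which would break exact
reproducibility).  A score **at or above** the cutoff (default 0.5) is
called positive.

Metrics follow the conventional panel: Sn, Sp, Acc, MCC, Recall,
Precision in the complement form $1-\mathrm{FP}/(\mathrm{TP+FP})$
(identical to $\mathrm{TP}/(\mathrm{TP+FP})$), and F1 in the form
$1-(\mathrm{FP+FN})/(2\mathrm{TP+FP+FN})$ (identical to
$2\mathrm{TP}/(2\mathrm{TP+FP+FN})$); the identities are property-tested
over random count vectors.  Any metric with a zero denominator is
reported as 0 and flagged, keeping reports total and machine-readable.
AUC is computed from the rank statistic with tie averaging, so it equals
the Mann–Whitney probability that a random positive outscores a random
negative.

## What the synthetic generator emulates

Real Kcr data (curated sites plus an external contact predictor's
output) cannot ship with a package, so `generate_dataset()` builds data
with the same *structure*: a few hundred proteins (default 250, lengths
120–250), lysines at proteome-like frequency (~4%), site labels at the
configured imbalance (default 1:10), per-protein 6-column contact tables
with probabilities in $[0,1]$, and optional PSSM files (synthetic
log-odds of local composition — a stand-in, clearly not an evolutionary
profile).

Two independent, separately switchable signal channels distinguish
positive sites:

* a **sequence motif tilt** (window residues near positive sites
  re-drawn from E/D with probability 0.25 by default) that linear
  encoders can detect; and
* **contact enrichment**: four planted contacts per positive site from
  the window to a designated residue type (`L`), emitted with
  probability in $[0.85, 0.98]$ — above the 0.8 threshold — that only
  the contact-aware encoders can detect.

Background contacts exist with probability
$0.08\,e^{-(\mathrm{sep}-3)/20}$ and carry Beta(1, 3) probabilities:
mostly low-confidence, with an occasional high-confidence background
contact, as contact predictors produce.  Planted endpoints avoid the
windows of *other* candidate sites where the local density allows
(falling back to unrestricted anchors in crowded regions): RRPC
normalizes per contact, so without this the planted signal would bleed
into same-protein negative windows and the spatial channel would not be
a clean benchmark.  That cleanliness is deliberately idealized — real
contact neighborhoods overlap — so a pass on this benchmark shows the
pipeline *recovers a spatial signal when one exists*, not that real Kcr
data carries one this strong.  Likewise the generator does not model
homology between proteins, compositional biases beyond the planted
ones, or predictor-specific error structure.

The planted-contact benchmark used by the test suite and the acceptance
script runs at 200 proteins (~1,600 sites), with the random forest at a
reduced one-point grid (1,400 trees); the suite checks RRPC test AUC
$\ge 0.9$ and AAC $\le 0.65$ on contact-only data, and chance-level AUC
($[0.4, 0.6]$) for both on null data.  Unit tests use 25–60 proteins.

## Degenerate inputs and numerical choices

* Contact tables: pairs are canonicalized to $i<j$; symmetric
  duplicates merge keeping the maximum probability; self-contacts and
  out-of-range probabilities are errors, not clamped.
* All-pad or all-`X` composition blocks are zero blocks; an entirely
  padded segment is an error.
* Equal-frequency binning with constant features yields a single bin
  and zero gain; tiny negative gains from floating-point cancellation
  are clamped to 0.
* `%.17g` formatting makes feature-matrix CSVs round-trip doubles
  exactly; contact probabilities are written with 10 significant
  digits.
* Every random draw (generation, splitting, undersampling, folding,
  classifier seeds) happens under an explicit seed inside a scoped RNG
  so a rerun reproduces reports byte for byte and the caller's RNG
  state is never disturbed.

## Limitations

* RRPC discards the number of qualifying contacts; a count-preserving
  variant might carry additional signal.
* The chi-square construction treats feature values as pseudo-counts;
  for features that are not sums this is a convention, not a statistic
  with exact nominal levels.
* The SGD logistic regression is deliberately plain (no regularization
  beyond early stopping); with many more dimensions than samples the
  SVM or random forest is the better default.
* The generator's planted spatial signal is idealized (see above);
  performance numbers on it say nothing quantitative about real Kcr
  datasets.
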