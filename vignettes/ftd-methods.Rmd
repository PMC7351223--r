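---
title: "Feature temporal dynamics in building wastewater: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature temporal dynamics in building wastewater: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted LC-MS metabolomics of wastewater collected directly at single
buildings produces a feature table: for every feature — an (m/z, retention
time) pair measured in negative ionization mode — an ion intensity per sample.
Sampling the same buildings repeatedly over months turns each feature into a
day-indexed trajectory, its *feature temporal dynamics* (fTD). `ftdkit`
implements the analysis chain for such studies: instrument-drift correction
and filtering, a stability taxonomy, clustering and probabilistic modeling of
fTDs, pairwise similarity and anticorrelation screens, building
classification from single-day profiles, grouping of features around
important anchors, and putative adduct-based annotation. A synthetic-study
generator with complete ground truth supports validation of every stage.

## Preprocessing

Stages run in a fixed order on a raw table containing study, pooled-QC and
solvent-blank injections over two run-order batches:

1. **Binary log transform.** Observed positive intensities become
   log2 values; zeros and missing cells stay missing (`NA`). "Not observed"
   and "observed at zero" are deliberately distinct states until the fill
   step.
2. **Pooled-QC CV filter** (`cv_max = 0.3`). A pooled QC aliquot is chemically
   identical at every injection, so a feature whose QC coefficient of
   variation (SD/mean) exceeds 0.3 is not reproducibly measurable and is
   removed. The CV is computed on the log2 scale with the population SD
   (divisor n); a `ddof` argument switches to the sample convention. The
   scale and divisor conventions are choices — both are documented here
   because the filter boundary depends on them.
3. **Run-order drift correction.** Each study intensity X is corrected to
   X' = X (R / C), with R the feature's mean over all QC injections of the
   batch and C the mean of the two run-order-flanking QC injections (before
   the first or after the last QC, the single nearest QC value is used — the
   simplest consistent edge rule). The correction is applied on the log2
   scale by default, following the stage order above; a raw-scale variant is
   available (`preprocess_params(correction_scale = "raw")`) since a
   multiplicative correction is arguably more natural before the log. For a
   drift that is locally linear in run order the flanking-mean estimate of C
   is exact at the midpoint between QCs, and the correction flattens the
   drift exactly; tests construct this case. The correction leaves each
   feature's global QC mean unchanged.
4. **Blank subtraction and half-minimum fill.** The per-feature mean blank
   intensity is subtracted from every study value; values that become
   negative, and originally missing values, are filled with half the minimum
   of the feature's remaining observed values in that building. After this
   stage no value is negative or missing.
5. **Cross-building sum filter** (`min_sum_log = 100`, strict: a feature
   summing to exactly 100 is removed) and **replicate averaging** (replicate
   injections of one building-day collapse to their mean, giving one column
   per day).

## Stability taxonomy

Per building, each feature's through-time mean, SD and median of log2
intensity are computed over days (population SD by default, `ddof`
switchable). Labels are a total function of (SD, median):

* SD < 2 → **stable**; SD ≥ 2 → **unstable**;
* among unstable: SD > 3.5 → **Class 2** (large, frequent excursions);
* otherwise median < 14 → **Class 1** (low baseline, occasional spikes);
* otherwise → **Class 3** (mid-level, irregular moderate jumps).

The 2 / 3.5 / 14 cutoffs are in log2-intensity units and separate the modes
of the empirical SD and median distributions in this kind of data; for other
instruments or matrices they should be re-tuned (`stability_params()`).
Between-building screens use the Kruskal-Wallis test (tie-corrected) over
per-day intensities grouped by building with Benjamini-Hochberg correction at
Q < 1e-5 — a deliberately stringent threshold that isolates only the most
building-discriminating features — and weekday/weekend contrasts use
two-sided Mann-Whitney tests at Q < 0.05, either Saturdays vs Wednesdays or
weekends vs all weekdays. Features constant across groups receive p = 1
rather than an undefined value.

## Temporal clustering and the cluster GP

fTDs are z-normalized through time (mean subtracted, divided by the
population SD), putting every feature on a comparable deviation scale.
Zero-SD features have no defined z-score; they are flagged and excluded from
clustering and similarity rather than silently mapped to zeros.

K-means (Euclidean, k = 100 by default) groups the z-series per building.
`stats::kmeans` with 10 random restarts is used; k-means++ seeding is not
available in base R and restarts serve the same robustness purpose. Cluster
ids are relabeled by decreasing size so "cluster 1" is always the largest,
and centers are recomputed as member means (an invariant the tests check).
If the default algorithm fails on degenerate geometry (duplicate series, k
near the number of distinct rows), a MacQueen fallback initialized at
distinct observed rows is used; k equal to the number of distinct series
returns the exact zero-inertia solution.

Each cluster center is fit with Gaussian-process regression using an RBF
kernel with unit signal variance and a **0.125-day (3-hour) length scale**.
The day-to-day correlation under this kernel is e^-32 ≈ 0: the model encodes
the assumption, supported by diurnal wastewater studies, that information
decays within hours, so one sampled day cannot predict the next. The
cluster's mean member SD enters as homoscedastic observation noise: its
square is added to the training-covariance diagonal along with a jitter
alpha = 1e-4. This "noise" reading of the constant kernel term was a genuine
design choice: adding a constant covariance term to the prior instead would
correlate arbitrarily distant time points and the posterior would not revert
to the prior away from data, contradicting the intended mean-reversion
behavior. With the noise reading, the posterior mean reverts to 0 and the
posterior SD to 1 (the prior) within one day of the last observation — a
property the tests verify against a closed-form oracle at 1e-8. Sample
autocorrelation of cluster centers (lag 0 = 1) provides the model-free
counterpart: it drops toward zero at lag one.

The **mixing experiment** quantifies what downstream (aggregated) sampling
would destroy: the observed per-day series is averaged with k simulated
streams — either Gaussian draws matching each feature's observed marginal
moments or independent day-permutations of the observed series (both offered
because the appropriate null for "another building" is genuinely ambiguous;
the damping conclusion is method-agnostic) — and the sum of pairwise
Euclidean distances between cluster centers is tracked as k grows. Averaging
shrinks i.i.d. day-to-day deviations by 1/sqrt(k+1), so distinctive
single-day excursions vanish with tens of streams.

## Similarity and anticorrelation

All similarity runs on shared-day-aligned, z-normalized series — only the
day intersection of all buildings enters, so distances are comparable across
buildings. Euclidean cutoffs 1.5 (high stringency) and 2.82 (low stringency)
define "similar" pairs; for series of length n the exact identity
d² = 2 n (1 − r) links distance to the Pearson correlation r under the
population-SD z-convention, so these cutoffs are correlation thresholds in
disguise (with n = 16, d = 2.82 corresponds to r ≈ 0.75). Three comparison
kinds exist: all pairs within a building (n(n−1)/2 records), all cross-pairs
between two buildings, and each feature against itself across buildings.
Identity pairs are excluded from all-to-all summaries. The delta-mz/delta-rt
histograms of sub-cutoff pairs are restricted to pairs separated by more
than 30 s in retention time, since co-eluting adducts and isotopologues
trivially share dynamics.

The anticorrelation screen keeps pairs with r < −0.6; optionally only those
whose *stationary* properties are indistinguishable — a Mann-Whitney test on
the two features' pre-normalization log2 day intensities, BH-corrected
across tested pairs, must give Q > 0.05. The screen runs on pre-z-norm
intensities because "statistically indistinguishable distributions" is
vacuous on z-scores, which all have mean 0 and SD 1. A stricter
all-buildings screen intersects pairs with r < −0.2 in every building.

## Building classification

Single-day feature profiles (all features' log2 intensities for one
building-day) are classified one-vs-rest by L1-regularized logistic
regression and by a 1000-tree random forest. The protocol: 50 independent
full-data shuffles; each split 75:25 into train/test without stratification;
standardization fitted on the training split only and applied to the test
split (the tests verify the scaler's statistics equal the train statistics
exactly — no leakage); the L1 penalty chosen per model by internal 3-fold
cross-validation over a decreasing log-spaced grid; held-out one-vs-rest
ROC AUC per class, with a class missing from a test split recorded as
missing, never zero. The overall AUC is the mean over classes, then
mean ± SD over shuffles.

**Important features** must satisfy both persistence criteria: a nonzero
L1-LR coefficient in at least 40 of the 50 models, and mean random-forest
importance strictly above 0.005. RF importances are impurity-decrease values
normalized per model to sum to 1, so the 0.005 threshold reads as "more than
0.5% of the total importance budget"; raw `randomForest` Gini decreases are
not normalized, so the package normalizes them to keep the threshold
meaningful. When the shuffle count is scaled down (as in the test suite),
the persistence threshold scales proportionally (80% of models).

## Grouping and co-clustering

Important features act as anchors: every feature within Euclidean distance
1.5 of an IF belongs to that IF's group; group sizes are counted with
multi-membership, but each feature is finally assigned only to the largest
group containing it (ties broken by lexicographic IF id — an arbitrary
but determinism-critical rule). Groups must strictly exceed a per-building
minimum size; the default thresholds are 20/20/5 for buildings 1-3, with the
alternative 15/8/3 set available in `grouping_params()` — both sets are in
circulation for this analysis and the package deliberately preserves the
choice rather than resolving it. Grouped features are embedded by classical
(metric) MDS on the Euclidean distance matrix (`stats::cmdscale`), which is
deterministic — no seed sensitivity — with Kruskal stress-1 reported; an
iterative stress-majorization MDS would add stochasticity without changing
the neighborhood structure the plot is read for.

Cross-building co-clustering intersects K-means memberships from pairs and
triples of clusters in distinct buildings; an intersection is kept iff it
holds strictly more than 5 features and its members span strictly more than
30 s of retention time (again suppressing trivially co-eluting sets).

## Putative annotation

Negative-mode features are annotated by primary-mass lookup. For each rule in
{[M]−, [M−H]−, [M+Cl]−, [M−H−H2O]−, [2M−H]−, [M−2H+Na]−, [M−2H+K]−,
[M+(1-3)13C−H]−} the implied neutral mass is M = (mz − delta)/multiplicity
with exact monoisotopic constants (proton 1.0072765, Cl 34.9688527, H2O
18.0105646, Na 22.9897693, K 38.9637065, 13C−12C 1.0033548); the algebra
inverts to below 1e-9 Da. Compounds within 5 ppm are level-3 matches;
an external fragmentation confirmation upgrades a feature to level 2;
no match leaves it level 4. Candidates are ranked by (fragmentation
confirmation, adduct priority, ascending ppm error, name); the adduct
priority order — deprotonation first, then water loss, chloride, the 2M
dimer, Na/K exchange, 13C isotopologues, bare radical anion — is a
documented heuristic of observation likelihood in negative ESI, and is
configurable. Implausible labels (R-groups, polymers, exotic elements) are
removed by a packaged substring blocklist. The packaged compound table
(~100 curated entries with masses computed from formulas) is a deliberately
small stand-in for the public databases (HMDB, ChEBI, LIPID MAPS, MetaCyc);
parsing those in full is out of scope, and any table with the same columns
can be supplied.

## The synthetic study generator

`generate_study()` emulates the statistical structure of a three-building,
three-month study on the raw scale, with ground truth for every planted
element. Defaults: 16 shared sampling days (dense first three weeks, then
weekly-ish, Saturdays included), 4 extra days per building, 3 replicate
days × 2 replicates, 300 features, 60% stable, unstable class mix
0.35/0.30/0.35, 5 dynamic groups of 6-12 features, 5 adduct pairs, 9
building markers at ±4 log2 units, 30 weekday-elevated features (+1.5 log2)
in building 1, 5 QC-CV violators, 10 blank-level features, QC every 6
injections, multiplicative drift spanning 1/1.25 to 1.25 per batch, blank
background at log2 = 8, measurement noise 0.5 log2 units. Base intensities
lie in log2 ≈ 10-26. These values were chosen once as realistic for
negative-mode wastewater data of this design and are not tuned thereafter.

What it does **not** emulate: chromatography and ionization physics, isotope
envelope intensity ratios, correlated (non-spherical) noise, missingness
mechanisms beyond blank-level censoring, and matrix effects. Passing tests
therefore demonstrate correctness of the algorithms under a faithful
statistical null, not instrument-level realism; headline percentages
computed on synthetic data (e.g. the fraction of similar pairs) are
properties of the generator, not of any real building.

## Numerical choices and problem sizes

* Population SD (divisor n) everywhere a convention is needed; `ddof` flags
  expose the alternative.
* Strict inequalities follow the stated thresholds exactly (SD < 2 stable;
  sum > 100 kept; intersection > 5; rt span > 30 s; importance > 0.005;
  "at least 40" models inclusive).
* All randomness flows through explicit integer seeds; per-stage and
  per-shuffle seeds derive from a master seed by fixed offsets, so every
  report is bit-reproducible.
* Degenerate inputs fail loudly (no QC samples, empty day intersection,
  constant series for ACF/correlation, features unobservable in a building)
  rather than returning silent NAs.
* The test suite and acceptance script run the full method at reduced
  problem sizes chosen for quick iteration on one CPU: 300-feature studies,
  20-50 cluster K-means, 8-20 classifier shuffles with 200-300 trees in
  tests (50 shuffles × 1000 trees in the acceptance script), 3 repetitions
  of the marker-recovery experiment. Thresholds are never relaxed to
  compensate.

## Known limitations

Run-order correction on the log2 scale is an approximation when the true
drift is multiplicative on raw intensities (the generator's model); it
removes most but not all drift there, and the raw-scale option exists for
that case. The Kruskal-Wallis screen treats days as exchangeable replicates
within a building, ignoring temporal autocorrelation — defensible here
precisely because the data show day-to-day correlations near zero, but not
for densely sampled systems with memory. The annotation stage reports
*putative* identities only: a 5-ppm primary-mass match cannot distinguish
isomers, and the packaged table's coverage is intentionally narrow.
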