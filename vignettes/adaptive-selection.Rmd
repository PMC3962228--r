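---
title: "Adaptive and static compound selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive and static compound selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptsel)
```

## The problem

Measuring an endpoint (boiling point, soil sorption, aquatic toxicity, ...)
for every compound in a chemical inventory is rarely affordable. Experimental
design for QSAR asks: which small subset of compounds should be tested so
that a regression model trained on that subset predicts the rest well — and
keeps predicting well when the dataset shifts slightly or contains a
structurally atypical compound?

`adaptsel` implements two families of answers and the statistical machinery
to compare them:

* **static designs** pick the whole training set at once from a fixed
  representation of the chemical space (principal components of the
  descriptor matrix): Kennard-Stone maximin selection, D-Optimal design with
  Fedorov exchanges, a space-filling grid design, most-descriptive-compound
  (MDC) similarity selection, and uniform random selection as the baseline;
* **adaptive (stepwise) designs** alternate between refining the space
  representation with the endpoint values measured so far and selecting the
  next batch in the refined space: DescRep (descriptor refinement +
  representativeness selection) and PLS-Optimal (PLS latent variables +
  D-Optimal selection).

## Data representation

Descriptor tables are min-max normalized to $[0,1]$ per column rather than
autoscaled: group-count descriptors (E-State-like sums per chemical group)
are zero for most compounds, so a Gaussian assumption behind autoscaling is
untenable. Constant columns map to all zeros and are *kept*, so column
indices stay stable across data partitions. Normalization ranges are always
fitted on the design partition only and applied to validation compounds with
clipping into $[0,1]$; the choice is conventional and leakage-free.

PCA search spaces are computed on the normalized matrix **without
centering** by default (the uncentered cross-product decomposition), which
keeps the sparse-descriptor origin meaningful; a `centered` flag exposes
ordinary PCA since either convention is defensible for the search space.
Five components are the default search-space dimensionality; the
space-filling design uses three because its cell count grows as $b^a$ in the
bin count $b$ and axis count $a$.

All pairwise distances are Euclidean, collected in a distance matrix `DM`
normalized by its maximum so entries live in $[0,1]$.

## DescRep

Each cycle has two phases.

**Descriptor refinement.** Every descriptor $i$ receives the score
$S_i = |r(x_i, y)|$, the absolute Pearson correlation with the endpoint
*over the measured compounds only*. After picking the top-scoring
descriptor $x$, every remaining score is down-weighted by
$S_i \leftarrow S_i\,(1 - M_{ix})^3$, where $M$ is the absolute
descriptor–descriptor correlation matrix; the cubic power suppresses
redundant descriptors smoothly and annihilates perfect correlates. Five
descriptors (default) span the next search space. Two implementation
decisions are worth recording:

* $M$ is computed over the whole design set, not just the measured
  compounds. It is property-independent, and at the 5–10-compound stage a
  measured-only estimate of a 200×200 correlation matrix would be mostly
  noise.
* Scores use absolute correlations: an anticorrelated descriptor is equally
  informative for a linear model.

**Compound selection.** Every unselected compound $x$ carries a priority
score, the product over selected compounds $i$ of correction factors
$CF_{xi} = 1 - (1 - DM_{xi})^{exp}$, measuring how poorly $x$ is covered by
the current selection. The exponent adapts to the local density each cycle:
with $d_k$ the distance from the dataset's most central compound to its
$k$-th nearest neighbour ($k$ = compounds already selected + batch size),
$exp = \ln \lambda / \ln(1 - d_k)$, so exactly those $k$ neighbours satisfy
$(1-DM)^{exp} \ge \lambda$. The threshold default is $\lambda = 0.75$;
reported behaviour is insensitive over 0.5–0.9. $d_k$ is clamped into
$[10^{-9}, 1-10^{-9}]$ before the logarithms, so degenerate neighbourhoods
(duplicates, or a schedule covering the whole set) yield a very sharp or
very flat kernel instead of an infinite exponent.

The batch minimizing the total priority score over all compounds is
selected. All candidate combinations are enumerated while
$\binom{\text{candidates}}{\text{batch}} \le 20{,}000$; beyond that a greedy
completion adds one compound at a time, each minimizing the resulting
total. The greedy route is a documented approximation — exhaustive
enumeration over hundreds of candidates is combinatorially infeasible — and
the exhaustive route is used by all small oracle checks.

The initial seed comes from k-means on the principal-component space,
restarted 15 times from randomly drawn data points; the restart with the
lowest total within-cluster pairwise distance wins, and each cluster
contributes its medoid. Because the seed is never empty, the first
non-seed selection needs no special rule: the seed always plays the role of
the preselected set in the priority scores.

One sentence of the source method description (how the exponent is
"determined as the value for which ...") does not parse to a unique rule;
the closed form above is the most literal reading and is pinned by a direct
arithmetic test ($\lambda = 0.75$, $d_k = 0.5 \Rightarrow exp \approx
0.415$). Priority scores are recomputed from scratch each cycle rather than
carried over, because the refined descriptor space (and hence `DM`) changes
every cycle.

## PLS-Optimal

PLS-Optimal replaces the descriptor refinement with a PLS regression fitted
on the measured compounds: all design-set compounds are projected onto the
first five latent variables (ranked by covariance with the endpoint, unlike
variance-ranked PCA), and the D-Optimal Fedorov exchange extends the
selection with the current compounds as fixed design points. The seed is
the same k-means seed as DescRep, which keeps the two stepwise methods
comparable from cycle one; the latent-variable count falls back gracefully
(with a warning) when the measured set is too small to support five.

## Static selectors: concrete rules

* **Kennard-Stone** starts at the most central compound (minimum distance
  sum) and repeatedly adds the compound with the largest distance to its
  nearest selected neighbour. All ties in the package break toward the
  lowest compound index, which makes every deterministic selector
  bit-reproducible and gives Kennard-Stone the prefix property.
* **D-Optimal** maximizes $\det(F^\top F)$ with $F$ the selected rows of
  the score matrix plus an intercept column (standard for information
  matrices; configurable off). Ten random restarts of the Fedorov
  single-point exchange are the default; exchange gains use the rank-two
  determinant-ratio update, and each accepted swap's determinant is
  recomputed exactly, so trajectories are exactly non-decreasing.
* **Space filling** scans $b = 1, 2, \dots$ and keeps the smallest $b$
  whose non-empty cells can host the requested selection; each cell
  contributes the compound nearest its center, and surplus cells are
  dropped in order of population (ties by cell index). Bin edges come from
  per-axis data ranges with a right-closed final bin, so every compound
  falls in exactly one cell.
* **MDC** follows the reciprocal-rank instantiation of Hudson et al.:
  $score_i = \sum_j w_j / r_{ij}$ with $r_{ij}$ the rank of $i$ in $j$'s
  nearest-neighbour list, weight update
  $w_j \leftarrow w_j (1 - 1/r_{cj})$ after picking $c$, and $w_c = 0$.
  The source method description defers the exact functional form to the
  literature; this instantiation is isolated in one function so alternates
  can be swapped in.

## Evaluation protocol

`make_splits()` draws repeated 84/16 design/validation partitions (250 by
default — with that fraction each compound appears in 210 design sets on
average, and two random design sets share about two thirds of the data).
For every split, method and sample size, a PLS regression is fitted **on
all normalized descriptors** of the selected compounds — never on the
selection search space — with the latent-variable count chosen by five-fold
cross-validated $Q^2$ (pooled PRESS over fold-wise TSS against the
training-fold mean; ties within $10^{-8}$ go to the smaller count, and the
count is additionally capped by the fold rank so five-compound selections
stay well-posed). Models are scored on the validation partition by RMSE and
the observed-predicted Pearson correlation; constant predictions are
flagged and their correlation recorded as 0.

Method comparisons use the exact paired sign test: wins are trials where
one method's RMSE is strictly lower, ties are dropped, and the win count is
referred to Binomial($m$, 1/2), two-sided.

Sample-size schedules follow 5, 7, 10, 15, 20, 25, 30, 40 cumulative
compounds; static selections restart from scratch at each size while
adaptive selections are nested along the schedule.

## Structural disruptors

A structural disruptor is a compound that hijacks the leading principal
components: appended to the dataset, it sits at least five standard
deviations from the central 97% of compounds on PC1 or PC2 (trimmed mean
and SD), and shifts the component loadings. `detect_disruptor()` reports
the trimmed-SD distance, the affected component, and the loading rotation
$1 - |\cos\theta|$ per component; the boolean verdict rests on the 5-SD
rule alone because no quantitative threshold for "the principal properties
changed" exists — the loading shift is reported, not thresholded. The
trim needs at least 34 compounds to be meaningful.

`make_disruptor()` builds such a row for the synthetic harness: it
displaces the column-mean compound along a direction spanned by the
least-variable non-constant descriptors (a compound carrying chemical
groups essentially absent elsewhere), doubling the displacement until
detection fires and then bisecting back so the final row sits just past
the requested magnitude rather than arbitrarily far out. Crucially, the
criterion is evaluated on the *extended, re-normalized* table — the same
coordinates in which an extended dataset is subsequently analysed —
because re-normalization compresses exactly the columns the disruptor
dominates, and a row calibrated in the base table's ranges would lose most
of its extremity the moment it joins the dataset. Re-normalization also
bounds how far out a single compound can sit along few columns, so the
direction starts at 10% of the descriptors and widens automatically until
the 5-SD criterion is reachable: it takes a sizeable share of the
group-count block for one molecule to rotate the leading components of a
large table. In the benchmark the disruptor
row is appended to every design partition before normalization and
selection — it can be selected, and then contributes its (truth-model)
endpoint value to training — but never enters validation scoring. Whether
the original study re-ran validation with the extended sets wholesale is
not stated; appending to the design side only isolates the effect on
*selection*, which is the question of interest, and is configurable by
passing the row explicitly.

## Synthetic data

The generator emulates the statistical shape of the study's descriptor
tables rather than any chemistry: two dense continuous descriptors
(correlated Gaussians, default correlation −0.6, mimicking the
solubility/lipophilicity pair) plus 200 sparse non-negative group-count
descriptors that are zero with probability 0.9 and otherwise
$|\mathcal{N}(0,1)|$ (any heavy-tailed non-negative draw would do). The
endpoint is a weighted sum over a small driver set — by default the two
dense descriptors and three sparse ones with weights (1, −0.7, 0.5, 0.5,
0.5) — plus Gaussian noise with SD 0.5, roughly a third of the signal SD:
measurement noise typical of a curated physicochemical endpoint. An
optional mild quadratic term exercises the nonlinear regime.

What the generator does *not* emulate: real descriptor block correlation
structure (fragment co-occurrence), integer-valued counts, multiple
overlapping activity mechanisms, or assay heteroscedasticity. Benchmark
conclusions on synthetic data therefore demonstrate that the machinery
reproduces the *directional* findings (error decreasing in sample size,
stepwise methods at or below the random baseline with significant paired
wins, small outlier deltas for the stepwise family), not the study's
numerical curves, which depend on real descriptor programs and datasets.

Problem sizes used by the shipped checks were chosen to make the full
statistical protocol cheap to re-run: 300 compounds with 50 trials for the
performance comparison, 20 trials for the paired disruptor comparison, and
150 compounds with 25 replicates for driver recovery. The driver-recovery
check uses a clean recovery regime — two equal-magnitude independent
drivers among 50 descriptors, noise SD 0.2, schedule 5, 20, 40 — because
recovering *specific* descriptors is only a well-posed expectation once the
measured set is large enough that sample correlations separate signal from
the spurious correlations of near-empty sparse columns; with five or seven
measured compounds a sparse column with a single non-zero entry routinely
reaches $|r| \approx 1$ by chance.

## Numerical conventions collected

* Ties: always the lowest compound (or cell) index.
* Constant columns: normalized to zeros; correlation contributions 0;
  self-correlation in $M$ kept at 1.
* Degenerate spaces: an all-identical point cloud yields an all-zero `DM`
  with a warning; rank-deficient PCA returns the available components with
  a warning.
* `d_k` clamped to $[10^{-9}, 1 - 10^{-9}]$ before $\ln$; batch
  enumeration switches to greedy above 20,000 combinations; Fedorov
  exchanges accept only exact determinant increases (rank-two screening,
  exact recomputation).
* All randomness flows from the global RNG; `run_benchmark()` derives one
  sub-seed per trial from it, so one `set.seed()` pins an entire grid.

## Known limitations

* The exhaustive batch criterion is exact only below the combination cap;
  large batches use the greedy completion.
* MDC's scoring follows one concrete reading of the cited scheme; other
  faithful variants exist.
* PLS models come from `mixOmics`; selections of fewer than four compounds
  rely on leave-one-out component choice and are inherently unstable — the
  benchmark reports, rather than hides, that instability via the SD curves.
* The sign test drops ties, which is standard but discards information when
  two deterministic methods coincide on many trials.
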