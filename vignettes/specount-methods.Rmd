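---
title: "Methods: spectral-count differential proteomics with specount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count differential proteomics with specount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specount)
```

## The problem

Label-free shotgun proteomics quantifies a protein in a sample by its
*spectral count* — the number of tandem-MS spectra matched to its peptides.
Spectral counts are non-negative integers, heavily right-skewed,
overdispersed, and zero-rich: a protein absent from (or below the detection
limit of) a sample simply contributes 0. `specount` implements an analysis
chain for two-group comparisons of such data, at the scale of a typical
clinical discovery cohort (two groups of roughly 14 and 16 subjects, a few
hundred quantified proteins): presence filtering, a permutation-calibrated
differential statistic, unsupervised structure (correspondence analysis,
hierarchical and K-medians clustering), supervised panel discovery
(nearest shrunken centroids), a combined panel score with ROC evaluation,
and over-representation analysis.

## Presence filter

A protein is retained when it is detected (count > 0) in at least half the
subjects of at least one group; for odd group sizes "half" rounds up, so a
group of 5 requires 3 detections. The filter removes proteins seen too
sporadically to support any group-level statement, and the surviving set is
also the natural background for enrichment testing.

## The spectral index

For protein counts $c$ in groups $A$ and $B$ with per-group means
$m_A, m_B$, relative abundances $r_A = m_A/(m_A+m_B)$, $r_B = 1-r_A$, and
detection fractions $f_A, f_B$ (share of samples with a non-zero count), the
spectral index is

$$\mathrm{SI} = r_A f_A - r_B f_B \in [-1, +1].$$

SI couples *how much more abundant* a protein is with *how consistently it
is detected*: it equals $+1$ exactly when detection is universal in $A$ and
absent in $B$, $-1$ in the mirror case, and $0$ for balanced abundance.
Conventions fixed by this package:

* group means, not pooled sums, define $r_A$ — unequal group sizes
  (14 vs 16) must not bias the index;
* when both groups are all-zero, $\mathrm{SI} = 0$ and $r_A = r_B = 0$;
* no per-sample depth normalization is applied by default (an optional
  total-count scaling exists in the generator for stress-testing, not in the
  statistic).

## Permutation significance

Group labels are reassigned uniformly at random (without replacement,
preserving group sizes) and SI is recomputed for every protein; 10,000
permutations is the default. When the requested number of permutations is at
least the number of distinct assignments $\binom{n}{n_A}$, the null switches
to exhaustive enumeration, making small-cohort results exact. The default
*global* mode pools all permuted SI values into a single null and declares a
protein significant when its observed SI falls strictly outside the central
95% band (type-7 empirical quantiles); one threshold for the whole
comparison matches how a single confidence level is applied to a comparison,
and pooling makes the band estimate stable even at modest permutation
counts. A per-protein mode is retained for users who want
protein-specific nulls. Empirical p-values use the add-one estimator
$p = (1 + \#\{|\mathrm{SI}^\ast| \ge |\mathrm{SI}|\})/(n_{null}+1)$, which
cannot return 0. Under a fixed seed the whole computation is deterministic.

No parametric count model (negative binomial or otherwise) and no further
multiple-testing correction is applied: the permutation band *is* the error
control, and its realized two-sided type-I error on null data is verified by
simulation in the acceptance suite.

## Correspondence analysis

Classical CA of the raw count table: with $P$ the table divided by its grand
total, row/column masses $r, c$, the standardized residuals
$S = D_r^{-1/2}(P - rc^{\top})D_c^{-1/2}$ are decomposed by SVD; principal
coordinates are mass-standardized singular vectors scaled by singular
values, axis inertia is the squared singular value, and total inertia equals
Pearson's $\chi^2/N$. CA operates on raw counts (it is defined for count
tables); three axes are reported by default. The SVD sign ambiguity is fixed
by forcing the largest-magnitude sample coordinate on each axis positive, so
repeated runs and permuted inputs give reproducible signs. All-zero rows or
columns are dropped with a warning; a zero grand total is an error.

## Clustering

**Transform.** Distances for expression clustering are computed on
$\log_2(\text{count}+1)$, z-scored per protein across samples
(`transform_counts()`). Raw spectral counts are dominated by a few abundant
proteins; the log stabilizes variance and the z-score makes the distance
reflect *profile shape*. The original study does not state its heatmap
transform; this is the conventional choice and is flagged as a package
decision.

**Hierarchical.** Agglomerative clustering with distance
$1 - \text{Pearson correlation}$ and average linkage, on rows, columns, or
both (a "two-dimensional" clustering as in expression heatmaps). A
zero-variance item has no defined correlation; its distance is set to the
maximum (1) with a warning. The merge tree is produced by `stats::hclust`,
the field's canonical implementation.

**K-medians.** Lloyd-style alternation of L1 assignment and coordinate-wise
median updates, with `k = 2` and 50 random restarts by default; ties in
assignment go to the lowest cluster index, and a cluster emptied during
iteration is re-seeded at the point farthest from its center. The best
restart by total L1 objective wins, and everything is deterministic under
the seed. Agreement with known groups is scored under the better of the two
cluster-to-group mappings (`match_partition_to_labels()`), since cluster
identities are arbitrary.

## Nearest shrunken centroids

For protein $i$ and class $k$: overall centroid $\bar x_i$, class centroid
$\bar x_{ik}$, pooled within-class SD $s_i$, fudge $s_0 = \mathrm{median}(s_i)$,
$m_k = \sqrt{1/n_k - 1/n}$, and standardized offsets

$$d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k\,(s_i + s_0)}, \qquad
d'_{ik} = \mathrm{sign}(d_{ik})\,\max(|d_{ik}| - \Delta,\, 0),$$

with shrunken centroids $\bar x'_{ik} = \bar x_i + m_k (s_i + s_0) d'_{ik}$.
Classification minimizes
$\delta_k(x) = \sum_i (x_i - \bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$.
Features are $\log_2(\text{count}+1)$ (no z-score: the model standardizes
internally through $s_i + s_0$).

**Choosing $\Delta$.** Leave-one-out cross-validation over a 30-point grid
from 0 to $\max|d_{ik}|$, choosing the error-minimizing $\Delta$ with ties
broken toward the largest (sparsest) value. One refinement proved necessary:
at strong planted effects the LOO error curve is 0 over a long stretch of
$\Delta$, and the unconstrained tie-break collapses the model to a single
protein, from which no 3-protein panel can be selected. `min_nonzero`
restricts the tie-break to deltas whose fit retains at least that many
nonzero-score proteins; the pipeline sets it to the requested signature
size. This mirrors the two-step structure of the original analysis, where
cross-validation retained a 28-protein model *before* the top-3 cut.

**Signature selection.** Candidates must (i) carry a non-zero shrunken
discrimination score $\max_k |d'_{ik}|$ and (ii) be significant in the
paired spectral-index result; they are ranked by score and truncated to the
requested size (3 by default). "Discrimination score" is not defined in the
source study; $\max_k |d'_{ik}|$ is this package's operationalization. Each
member receives a direction sign (+1 if up in the positive class, judged by
the sign of its SI) so panels mixing up- and down-regulated proteins remain
coherent.

**Combined score.** Each signature protein's raw counts are z-scored across
all samples, multiplied by the member's direction sign, and summed per
sample. Raw counts (not logs) are z-scored by default — the minimal reading
of "normalize across subjects, then sum" — with a `log_scale` flag.
Zero-variance members contribute 0 with a warning.

**ROC.** Every distinct score is swept as a threshold; AUC is the
trapezoidal area, which equals the tie-corrected Mann–Whitney U statistic
(both are computed and compared in the test suite); the reported operating
point maximizes Youden's $J = \text{sens} + \text{spec} - 1$, ties resolved
toward higher sensitivity.

## Over-representation analysis

For a hit list against a background (by default, all proteins surviving the
presence filter — the defensible universe when no external database ships
with the package), each category's observed overlap is compared with draws
of `length(hits)` proteins from the background without replacement.
Empirical p-values use the add-one estimator and are converted to FDR by
Benjamini–Hochberg; a category is significant when it has at least 3
overlapping members *and* FDR < 5%. The permutation p converges to the
hypergeometric upper tail, and the acceptance suite checks agreement within
three Monte-Carlo SDs at 10,000 draws.

## The synthetic world

`generate_counts()` produces datasets with known truth at the scale of the
motivating study: 394 proteins, groups of 14 and 16, 75 differential
proteins (60 up in group A, 15 in group B), and a 3-protein signature with
strong effects. The generative model:

* protein baselines $\mu_p \sim \text{log-normal}(\log 10,\, 1)$ —
  median ~10 spectra with a long right tail, as in real BALF tables;
* per-sample depth factors $d_i \sim \text{log-normal}(0,\, 0.15)$;
* counts $\sim \text{NB}(\mu_p d_i \cdot \text{shift},\ \text{size} = 2)$ —
  strongly overdispersed;
* a differential protein with log2 fold change $L$ is shifted
  $2^{+L/2}$ in its up group and $2^{-L/2}$ in the other, so the group-mean
  ratio is exactly $2^L$;
* half the moderate differential proteins (configurable) are
  *presence/absence* archetypes: the down group keeps its cells with
  probability $2^{-L}$ at unshifted abundance — same mean ratio, but the
  effect is carried by detection asymmetry, which is what SI rewards;
* an optional flat technical dropout zeroes cells independently.

**Calibration choices, and why.** Two defaults were calibrated so that the
acceptance properties are meaningful statements about the method rather
than artifacts of the generator (dispersion and dropout rates of the real
data are unknowable from the publication):

* *Flat dropout defaults to 0.* An abundance-independent dropout zeroes
  cells with counts in the thousands, which real spectral-count tables do
  not show — MS missingness concentrates at low abundance. On log2 features
  a single such zero inflates a strong protein's pooled SD enough to halve
  its shrunken-centroid score, so at any appreciable flat rate the identity
  of the "top 3 discriminators" becomes a lottery. Zeros in the default
  world instead arise where they belong: low-abundance baselines and
  planted presence/absence patterns (~9% of all cells; most down-group
  cells of presence-archetype proteins).
* *Signature proteins are strong, abundance-archetype, effectively
  exclusive* (log2 FC 10, i.e. the down-group mean sits below the detection
  floor). This emulates a pus-derived diagnostic marker — abundant in
  infected lavage, essentially undetected otherwise. The strength is not
  cosmetic: with 75 true effects at $n = 30$, the maximum NSC score among
  ~30 presence-archetype competitors overlaps the score distribution of any
  moderately planted signature, and "recover the 3 strongest planted
  proteins" stops being well-posed. A green recovery test therefore
  establishes that the selection machinery finds a *dominant* panel — not
  that a weak panel would be found in noisy data (it would not, and no
  method at this sample size could).

**What green tests do not establish.** The generator does not emulate
instrument batch effects, peptide-level inference errors, shared-peptide
ambiguity, or abundance-dependent missingness; samples are independent
given their group. Passing tests validate the statistical machinery against
this stated world, not clinical performance on real lavage fluid.

## Numerical conventions

* Empirical quantiles: type 7 (linear interpolation), everywhere.
* Permutation and enrichment p-values: add-one estimator, never 0.
* Tie comparisons in p-value counting use a $10^{-12}$ guard so that exact
  ties in floating point count as "at least as extreme".
* K-medians assignment ties: lowest cluster index; CV delta ties: largest
  delta (optionally constrained, see above); Youden ties: higher
  sensitivity.
* TSV outputs write numerics at 17 significant digits, so read/write
  round-trips are lossless; count cells are bit-exact integers.
* One pipeline seed deterministically derives independent per-stage seeds,
  so adding a stage never perturbs earlier stages' randomness.

## Known limitations

* The spectral-index formula is the package's normative definition
  (range, exclusivity, and balance properties as documented); variants in
  the literature that pool rather than average counts will differ on
  unbalanced designs.
* The global null band assumes proteins are exchangeable enough to share a
  threshold; per-protein mode exists but needs far more permutations for
  comparable resolution.
* Flat dropout is available but crude; an abundance-dependent detection
  curve would be more faithful and is left to future work.
* Configuration files are JSON only.
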