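---
title: "Muscle synergy analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsynergy)
```

## The model

`emgsynergy` analyzes multi-muscle surface EMG under the muscle-synergy
hypothesis: the recorded activity of $m$ muscles over $t$ time samples,
arranged as a non-negative matrix $M$ ($m \times t$), is modeled as a
small number $n$ of fixed muscle weighting components recruited by
time-varying temporal patterns,

$$M = W C + e,$$

with $W \ge 0$ ($m \times n$), $C \ge 0$ ($n \times t$) and residual
$e$. Columns of $W$ are the synergies; for all comparisons between
subjects and groups they are scaled to unit Euclidean norm (the inverse
factor is absorbed into $C$, leaving the reconstruction unchanged —
NMF is only defined up to this diagonal rescaling).

The package covers a complete two-group comparison: preprocessing,
per-subject factorization with model-order selection, within-group
clustering into representative synergies, between-group matching,
sparseness quantification, and the detection of fractionated or merged
synergies. A synthetic generator with known ground truth provides the
validation surface for every stage.

## Preprocessing

`emg_envelope()` converts raw EMG to linear envelopes: per channel,
demeaning, 40 Hz high-pass filtering (motion-artifact rejection),
full-wave rectification, and 15 Hz low-pass filtering, all with
4th-order Butterworth designs. Filters are applied forward–backward
(zero phase; the effective order doubles) — the standard choice for
envelopes, where phase lag would shift burst timing — with reflective
edge padding of three filter lengths. Residual negative ripple after
low-pass filtering is clipped at zero so the output is a valid NMF
input. A signal must be longer than the padding (27 samples at these
settings) or an error is raised.

`time_normalize()` linearly interpolates each channel over the trial's
analysis window onto 200 equally spaced points, inclusive of both ends,
making trials of different durations comparable movement cycles.

`assemble_subject()` keeps the first five trials in recorded order,
concatenates them along time ($t = 1000$), then scales each muscle row
by its maximum over the concatenated matrix and afterwards to unit
variance, so every muscle is weighted equally in the factorization.
Both factors are retained (`scale_max`, `scale_sd`) so envelopes can be
mapped back to original units. A muscle with constant (typically
all-zero) activity cannot be variance-scaled and is reported as an
error rather than silently dropped.

## Factorization and order selection

`nmf_fit()` minimizes the squared Frobenius error by multiplicative
updates (the classical algorithm for this problem), with a $10^{-12}$
floor inside the update ratios to protect against division by zero when
a factor collapses. Iteration stops after 1000 iterations or when the
relative error decrease falls below $10^{-6}$; the error trace is
returned and is non-increasing. Factors are initialized uniform on
$(0,1]$.

Because the objective is non-convex, `nmf_best_of()` repeats the fit
from 50 random restarts (the convention for this analysis) and keeps
the highest-VAF solution. Restart $r$ of master seed $s$ uses the
deterministic sub-seed $f(s, r)$ (a fixed multiplicative hash kept
below $2^{31}$), so every result is bitwise reproducible.

Goodness of reconstruction is the variance accounted for,

$$\mathrm{VAF} = 100 \left( \frac{\sum_{ij} M_{ij} (WC)_{ij}}
{\lVert M \rVert_F \, \lVert WC \rVert_F} \right)^2,$$

i.e. 100 times the squared *uncentered* Pearson correlation of the
flattened matrices. `select_order()` evaluates candidate orders
$n = 1..m$ and selects the smallest with VAF strictly above 90% (the
threshold is a percentage; 0.9 on the 0–1 scale). By default the whole
VAF curve is evaluated for reporting; `full_curve = FALSE` stops the
scan at the first passing order when only the selection is needed. If
the threshold is never reached the maximum order is returned with a
flag and a warning.

## Representative synergies and matching

Within each group, every subject's unit-normalized weight columns are
pooled (`pool_group()`) and clustered with Ward's method on Euclidean
distances (`ward_cluster()`, `stats::hclust(method = "ward.D2")`). The
cluster count is chosen by the gap statistic over $h = 2..20$: $B =
500$ reference datasets are sampled uniformly within the per-dimension
bounds of the pooled vectors (not renormalized — they live in the
data's bounding box; a `renormalize_ref` toggle exists), each clustered
with the same Ward procedure, and

$$\mathrm{Gap}(h) = \tfrac{1}{B}\sum_b \log W_b(h) - \log W(h),$$

with $W(h)$ the Tibshirani within-cluster dispersion
$\sum_r D_r / (2 n_r)$ ($D_r$ = sum of pairwise squared distances in
cluster $r$). The reference spread $sd(h)$ carries the finite-$B$
correction $\sqrt{1 + 1/B}$ (toggleable). The selected $h^*$ is the
smallest $h$ with $\mathrm{Gap}(h) \ge \mathrm{Gap}(h+1) - sd(h+1)$;
if the rule never fires the upper bound is returned with a flag.

Clusters are summarized by their centroids — the mean of member vectors,
renormalized to unit norm for all similarity computations, while the
raw mean is kept for reporting. A cluster is *subject-invariant* if it
contains synergies from at least $\lceil$ group size / 3 $\rceil$
distinct subjects; only these centroids enter the between-group
analysis, which suppresses idiosyncratic or split clusters.

`match_groups()` pairs the two groups' centroid sets by the injective
assignment maximizing the total scalar product, solved exactly by
depth-first search with an upper-bound prune (equivalent to exhaustive
enumeration, and verified against it in the tests). Pairs below
SP 0.75 are demoted to unmatched.

`compare_temporal()` is deliberate plumbing rather than a statistical
parametric mapping implementation: it compares matched temporal
patterns pointwise with a two-sample t trajectory and controls the
familywise error over the 200 time points by max-statistic label
permutation, returning supra-threshold time clusters.

## Sparseness, fractionation, merging

Synergy selectivity is quantified with the Hoyer sparseness

$$\varphi = \frac{\sqrt{n} - \lVert w \rVert_1 / \lVert w \rVert_2}
{\sqrt{n} - 1}, \qquad n = 16,$$

which is exactly 1 for a one-hot vector and exactly 0 for a uniform
one, and is invariant to positive scaling and component permutation.
Per subject, $\varphi$ is averaged over that subject's synergies; the
per-subject means are compared between groups. `direction_gate()` runs
this comparison (Mann–Whitney) and routes the pipeline: significantly
sparser older group → fractionation analysis; significantly less
sparse → merging; otherwise both, exploratorily.

Fractionation asks whether a parent centroid $w^{(i)}$ of one group is
a non-negative combination of fragment centroids of the other:
$w^{(i)} \approx \sum_k m_k f^{(k)}$, $m_k \ge 0$, fitted by
non-negative least squares (`pracma::lsqnonneg`) on unit vectors. The
search runs over *every* fragment subset of size ≥ 2; a candidate
passes when the coefficients surviving the 0.2 threshold number at
least two and the reconstruction's scalar product with the parent is at
least 0.75. Among passing candidates the highest reconstruction SP is
reported (ties toward fewer fragments); all candidate fits are retained
in a diagnostics table, so the full-basis fit can be inspected
alongside the best subset. `detect_merging()` is the exact mirror with
the group roles swapped. Both directions can be forced in the pipeline
regardless of the gate.

## Group statistics

`mann_whitney()` computes $U$ from midranks; the two-sided p-value is
exact (from the null $U$ distribution) when both samples have at most
10 observations and no ties, otherwise a normal approximation with tie
and continuity correction — the switch is reported in the result. The
test suite verifies the exact path against brute-force enumeration of
all label assignments and the two paths against each other (within
0.02 for $n \le 8$). `cohens_d()` reports the pooled-SD standardized
mean difference as a magnitude plus a direction flag. No
multiple-testing correction is applied by the comparison table.

## The synthetic generator

`simulate_dataset()` emulates a two-group developmental study at the
scale of a small cohort: 13 + 8 subjects, 16 muscles, 5 trials of 200
points, envelope noise SD 0.05. Ground-truth templates are built from
disjoint dominant muscle blocks (a random partition of the muscles,
standing in for functional muscle groupings) plus a diffuse leakage
component bisected to reach a target sparseness (default 0.5, a
field-typical level), with a faint baseline so no channel flatlines.
Activation profiles are single Gaussian bursts with staggered centers
across the cycle, emulating sequenced proximal-to-distal recruitment;
trials jitter the burst timings and subjects jitter the weights
(clipped at zero, renormalized). Envelope noise is truncated-Gaussian
(clipped at zero), preserving non-negativity without multiplicative
complexity. The older group's template set is derived by *fractionating*
selected parents: the parent's dominant muscles are partitioned into
two balanced disjoint supports with 10% shared leakage, giving fragment
pairs that are each sparser than their parent and reconstruct it at
SP ≥ 0.9 with mixing coefficients ≥ 0.3 (comfortably above the 0.2
detection threshold). Everything derives deterministically from one
master seed.

What the generator does *not* emulate: biomechanically realistic
kinematics or muscle-model EMG, inter-muscle crosstalk,
amplitude-dependent (multiplicative) noise, electrode or skin
artifacts, and trial-to-trial amplitude drift. Passing recovery tests
therefore demonstrates correctness of the algorithms under the stated
modular model, not performance on arbitrary real recordings.

### Identifiability and the recovery fixtures

With 16 muscles, the smallest order whose VAF exceeds 90% equals the
generating $k$ only when the synergies are well separated in muscle
space: a rank-$(k{-}1)$ fit can merge two similar templates at little
cost to the uncentered correlation. Dropping one of $k$ near-orthogonal
components costs a residual energy fraction of roughly $(1 - s)/k$
($s$ = their scalar product), so for $k = 8$ the 90% threshold demands
nearly disjoint supports. The recovery fixtures therefore use the
block-structure sparseness at which $k$ disjoint dominant groups fit
into 16 muscles (0.6 at $k = 3$ up to 0.86 at $k = 7, 8$), with
compact bursts. At the default template sparseness of 0.5 the selected
order lands at $k$ or $k - 1$; the subject-invariance filter
nevertheless recovers the exact planted template counts, because the
merged vectors vary across subjects while the true templates form
tight, well-supported clusters.

### Problem sizes in the shipped tests

The suite runs the full 13 + 8 pipeline with 3–5 restarts, a capped
candidate order (10–12), 50–100 gap-statistic references and 20-seed
replications for the stochastic recovery checks; these sizes keep the
whole suite in the minutes range on a single core while leaving every
recovery margin wide (e.g. 20/20 seeds for the group-sparseness
difference, 0 misses / 0 false positives for planted splits). The
defaults of the exported functions (50 restarts, $B = 500$, full VAF
curve) reflect analysis practice, not the test configuration.

## Numerical choices and degenerate inputs

- Multiplicative updates carry a $10^{-12}$ denominator floor;
  candidate subsets whose NNLS fit is identically zero get SP 0 rather
  than NaN.
- All-zero vectors are rejected wherever a normalization or $\varphi$
  is required (constant channels, zero centroids, zero samples in the
  VAF).
- Assignment ties in `match_groups()` resolve toward the
  lexicographically first enumeration (depth-first order); coefficient
  ties in the fractionation search resolve toward fewer fragments.
- The gap statistic requires at least $\max(h) + 1$ vectors; the
  pipeline trims the $h$ range to the pooled vector count when groups
  are small. Reference counts below 10 are accepted with a warning.
- Exact Mann–Whitney switches to the normal approximation the moment
  ties appear, since the exact null distribution assumes none.

## Known limitations

- Systematic under-selection by one order (at template sparseness
  around 0.5) means pooled vectors can contain subject-specific merged
  synergies; at some seeds these form a duplicate representative
  cluster that passes the subject-invariance filter and can then
  masquerade as a fractionation contributor. Inspecting the
  diagnostics table (coefficients concentrated on one fragment plus a
  near-duplicate) exposes these cases.
- The VAF > 90% rule is a convention, not an optimum; alternative
  order-selection rules (elbow, cross-validation) are out of scope.
- The temporal comparison is a permutation test with max-statistic
  correction, not random-field-theory SPM; cluster p-values beyond the
  familywise threshold are not computed.
- Sparseness comparisons operate on the standardized (per-muscle
  unit-variance) space in which the factorization runs; $\varphi$
  values are therefore not directly comparable to those computed on
  unstandardized envelopes.
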