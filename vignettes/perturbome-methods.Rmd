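---
title: "Methods: decomposing pairwise perturbation interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing pairwise perturbation interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model behind the package, the
choices made where the method leaves room, and what the validation on
synthetic screens does and does not establish.

## The geometric model

A perturbation is the displacement vector from the control (DMSO)
centroid to the treated state in a normalized feature space.  For a drug
pair with single vectors $\vec a$, $\vec b$ and observed combination
$\vec c$, the package solves the least-squares projection of $\vec c$
onto the plane spanned by $\vec a$ and $\vec b$ — the $2\times2$ normal
equations with Gram matrix
$\left(\begin{smallmatrix} a\!\cdot\!a & a\!\cdot\!b\\ a\!\cdot\!b & b\!\cdot\!b\end{smallmatrix}\right)$
— and writes

$$\vec c = \alpha \vec a + \beta \vec b + \gamma \hat n,
  \qquad \hat n \perp \vec a,\ \hat n \perp \vec b,\ \gamma \ge 0 .$$

$\alpha = \beta = 1,\ \gamma = 0$ is exact superposition, i.e.
non-interaction.  Deviations of $\alpha$ below/above 1 mean drug A's
contribution was shrunk/stretched by the presence of B (a directed
interaction pointing at A), symmetrically for $\beta$; $\gamma > 0$ is an
emergent phenotype attributable to neither drug.  Because $+\gamma$ and
$-\gamma$ describe the same emergent type, the 27 sign-pattern subspaces
of $(\alpha-1, \beta-1, \gamma)$ (1 point, 6 lines, 12 surfaces, 8
volumes) merge into 18 interaction classes: 2 undirected, 8
uni-directional, 8 bi-directional (`enumerate_interaction_classes()`).

Assumptions worth stating: the readout is treated as approximately
additive on the normalized scale (superposition is meaningful);
replicate-mean single vectors are precise enough to serve as the plane
(their residual error attenuates $\alpha,\beta$ slightly toward 0, an
ordinary errors-in-variables effect); and interactions are scored from a
single combination measurement, so all per-pair uncertainty must come
from the non-interaction cloud.

Degenerate geometry — Gram condition number above $10^8$, i.e. (near)
collinear singles — raises a typed error carrying the 1-D projection as
a diagnostic.  A residual below $10^{-10}\max(1, \lVert c\rVert)$ snaps
$\gamma$ to exactly 0 so that superposition is reported cleanly.

## Significance: D_P, D_I and the non-interaction cloud

Both significance statistics are Mahalanobis distances computed in a PCA
space retaining the smallest number of components that explain 90% of
the reference variance (`variance_target`, configurable).  The PCA is
fitted on the *reference* population only — control displacement vectors
for single-perturbation strength ($D_P$), the non-interaction cloud for
combinations ($D_I$) — because the question is always "how far outside
the reference variation does this point lie".  A ridge of $10^{-8}$ is
added to the reduced covariance; genuinely singular covariances warn.

Strength: $D_P$ of the replicate-mean vector against batch control
variation, strong if $D_P > 7$ in at least one batch.  Combination
vectors use their single measurement.

The non-interaction cloud for a pair takes all pairwise sums of the two
drugs' replicate vectors and perturbs each sum once per control well of
the combination's plate, so the cloud carries replicate *and* intra-plate
variation; its size is exactly $n_A n_B n_{\text{ctrl}}$.  The control
perturbation has two variants.  The default multiplies each sum
element-wise by the control well's profile expressed as a ratio to the
plate control median (ratios near 1); an additive variant adds the
control well's deviation from the plate control mean.  The multiplicative
form follows the natural reading of "multiplying by the controls"; the
additive form is exactly Gaussian under a Gaussian noise model, which is
why the chi-square calibration experiment below uses it.  Both are
exposed via `cloud_mode`.

A combination is significant if $D_I > 3$.  Under the superposition
null, $D_I^2$ should follow a $\chi^2_k$ law with $k$ the retained
components.  The calibration experiment verifies this with a cloud built
from 3000 control wells with anisotropic feature variances (so the PCA
truncation is non-trivial, $k = 4$ of 6 dimensions) and 2000 null
combinations drawn from the generating law; the Kolmogorov–Smirnov test
accepts the $\chi^2_4$ law.  The design deliberately makes control
variation dominate: with a handful of replicates the cloud's covariance
estimate is built from few independent draws, and $D_I$ is then
conservative rather than exactly chi-square distributed — which is
acceptable for a screening statistic but would confound a calibration
test.

## Effect-size thresholds and the calling rule

Significance alone is not enough: a pair must also exceed drug-specific
effect-size thresholds estimated from the *non-significant* pairs.  Per
drug, the $\alpha/\beta$ band is the median $\pm\,2$ MAD of its
non-significant coefficients, with the MAD taken raw (constant 1, so
that values $\{0.8, 0.9, 1.0, 1.1, 1.2\}$ give a MAD of exactly 0.1 and
a band of $[0.8, 1.2]$); the $\gamma$ threshold is the largest $\gamma$
among its non-significant pairs.  A pair uses each drug's own band for
its coefficient and the larger of the two $\gamma$ thresholds — the
pairing rule is a package decision, as is the fallback to globally
pooled thresholds for drugs with fewer than `min_pairs = 5`
non-significant pairs.  A significant pair whose coefficients all stay
inside their bands is conservatively called non-interaction.

One arithmetic consequence deserves emphasis.  For Gaussian coefficient
noise of scale $\sigma$, a raw MAD is $0.674\,\sigma$, so the 2-MAD band
is $\pm 1.35\,\sigma$ and a genuinely *unchanged* coefficient of a pair
that passed the $D_I$ gate falls outside its band about 18% of the time.
The rule is therefore excellent at detecting planted modulations (a
deviation three times the noise scale is essentially never missed) but
the full class triple of a significant pair acquires spurious extra
modulations at roughly that per-coefficient rate.  The synthetic
recovery experiment consequently scores *recovery of the planted
modulations* — every planted directed or emergent edge must be found —
which the pipeline achieves for at least 95% of planted pairs at
effect-to-noise 3 and above; the coefficient RMSE decreases
monotonically as noise shrinks.  Exact-triple agreement is lower for
classes containing unchanged coefficients, for the reason above, and
this is a property of the 2-raw-MAD calling rule itself, not of the
implementation.

## Preprocessing decisions

**Aggregation.** Per-well medians over cells, robust to heavy-tailed
single-cell variation (the generator's `heavy_tails` option exercises
this).

**Median polish.** Per plate and feature, an additive
`overall + row + column + residual` fit (Tukey's algorithm, row sweeps
first, tolerance $10^{-6}$, 100 iterations; `stats::medpolish` supplies
the sweeps).  The polished value is `overall + residual`.  Single-row or
single-column plates degrade to a one-way polish with a warning.  Note
that on plates where *most* wells carry strong, heterogeneous effects,
row/column medians absorb treatment signal and the polish injects noise
rather than removing it; the recovery experiments therefore simulate
screens without plate artifacts and skip the polish, while the polish
itself is validated separately by exact recovery of planted additive
row/column effects on a 16×24 grid.

**Scaling.** Per feature and batch, values are clipped at the 0.5th and
99.5th percentiles and mapped linearly onto [0, 1].  The symmetric pair
is the package's reading of an asymmetric-looking specification
("99.5/0.05"); both bounds are configurable.  Zero-spread features map
to 0.5 and are flagged.

**Feature filter.** Four ordered stages, (i)–(iii) per batch with a
feature kept only if it passes in all batches: (i) intra-plate CV (mean
over plates of sd/mean across a plate's control wells) and inter-plate
CV (CV across per-plate control means) both below 0.2; (ii) mean
between-replicate Pearson correlation at least 0.2 — computed per
feature by correlating replicate $i$ against replicate $j$ across drugs
and averaging, the standard reproducibility reading (correlating a
single feature's scalar values "within a drug" is undefined); features
with no variance across drugs yield NA and are passed on to stage (iii),
where a constant feature necessarily dies; (iii) at least one
perturbation with a Bonferroni-significant control-relative z-score
($P < 0.05$ over all feature × perturbation tests); (iv) greedy
redundancy pruning: while any retained pair has $|\rho| > 0.8$, the
member of the currently most-correlated pair with the smaller maximal
$|z|$ is removed (ties by feature name).  Every removal records its
stage; re-running the cascade on its own output is a no-op.

**Perturbation filter.** Wells need ≥ 30 cells; single drugs ≥ 3 valid
replicate wells.  Stability regresses the well cell count, normalized by
the same-plate DMSO median count (making the slope threshold
dimensionless — the functional form is a package decision), on the
temporal replicate order; a drug fails only if the slope exceeds 0.05
*and* the relative max–min count difference reaches 30%.  Single time
points are marked "not assessed" and pass.

## Network assembly and characterization

Directed edges (positive/negative) point at the modulated drug and are
admissible only when that drug is strong; emergent edges are undirected
and always admissible.  This yields 1 possible link per weak–weak pair,
2 per weak–strong and 3 per strong–strong, hence
$M_{\max} = w(w-1)/2 + 2ws + 3s(s-1)/2$ and sparseness
$=$ edges$/M_{\max}$, also reported within/between core and periphery.

Core–periphery detection scores nodes by the dominant eigenvector of
the adjacency matrix (the minimal-residual rank-one fit $A \approx
cc^{\mathsf T}$) and thresholds the ranking at the split maximizing the
Pearson correlation between the adjacency and the ideal core–periphery
pattern; complete graphs, where that correlation is undefined, fall back
to raw mismatch minimization.  Significance compares the observed fit
against degree-preserving configuration-model rewirings (1000 by
default).

Label-swap randomization re-runs the calling pipeline with each
combination AB compared against two distinct singles C, D drawn from
outside the combination, re-using the observed thresholds.  A single
global permutation cannot satisfy the non-membership constraint on an
all-pairs design — whatever drug A maps to is A's partner in some
combination — so the resampling is per combination and per iteration,
seeded.  On screens where combinations are true superpositions of their
own singles, randomized labels inflate negative and emergent calls
(a mismatched plane both shrinks the in-plane coefficients and leaves a
large residual), reproducing the expected direction of the z-scores.

## Interactome metrics

Module localization: for each target, the shortest-path distance to the
nearest other target of the same drug; Glass'
$\Delta = (\langle d_s\rangle - \mu_{\text{random}})/\sigma_{\text{random}}$
against 10,000 (seedable) random modules of the same size, by default
sampled uniformly — a degree-binned option exists because drug targets
are biased toward hubs.  The largest-connected-subgraph size is z-scored
against the same null.  Separation
$s_{AB} = \langle d_{AB}\rangle - (\langle d_{AA}\rangle + \langle d_{BB}\rangle)/2$
with shared proteins contributing zero; singleton modules take diameter
0 by convention, and unreachable targets are excluded from means with a
reported count (rare when analysis is restricted to the largest
component).  The auxiliary cross-distances are the mean over all
cross-pairs and the minimum cross-pair distance.  Annotation similarity
is $2/\min(n_i)$ over shared terms; Tanimoto is set-bit intersection
over union with $0/0 \equiv 0$, flagged.

## The synthetic generator

`simulate_screen()` emulates the structure of a pairwise morphological
screen: 384-well plates (16×24) with DMSO control wells, six replicate
wells per single drug doubling as the temporal plating order, one well
per combination, additive row/column plate effects, Poisson cell counts
and isotropic Gaussian per-cell noise around well means (a t(3) option
for heavy tails).  Combination well means realize
$\alpha \vec a + \beta \vec b + \gamma \hat n$ with $\hat n$ drawn
uniformly on the unit sphere of the orthogonal complement.  Defaults —
12 drugs of which 3 strong, 20 features, effect norms 0.5 (strong) and
0.03 (weak), cell noise s.d. 0.08, 60 cells per well, 64 control wells
per plate — were chosen once so that strong drugs sit near twice the
$D_P$ cutoff and weak drugs safely below it, the regime the strength
statistic is meant to separate.  The control-well count matters: the
control covariance must be estimated in the retained PCA space, and
desk-scale screens with very few controls make $D_P$ erratic.

What the generator does *not* emulate: segmentation or staining
artifacts, uneven illumination, cell-subpopulation structure, feature
distributions with hard bounds, or correlated (non-isotropic) cell
noise.  Passing the recovery experiments therefore shows the estimator
chain is correct under its own model, not that real screens meet that
model.

Problem sizes used by the validation suite (the package's own choices):
the recovery experiment uses 22 drugs of equal effect norm 0.3 in 15
dimensions, 100 planted pairs from a 10-archetype catalogue spanning
uni-directional, bi-directional and emergent classes, with the remaining
131 all-pairs combinations left as non-interactions to calibrate the
thresholds; noise levels 0.16/0.08/0.04 for the RMSE curve; the
chi-square calibration uses 3000-control clouds and 2000 null draws; the
localization monotonicity experiment uses 120-node preferential-
attachment graphs, module size 8, $\lambda \in \{0, 0.5, 1\}$ over 20
seeds; core–periphery recovery uses the 10/50 planted graph with block
densities 0.8/0.3/0.02 over 20 seeds.

`simulate_interactome()` grows preferential-attachment graphs and plants
target modules by neighbour-growth with locality $\lambda$ ($\lambda=1$
connected, $\lambda=0$ uniform) and optional shared-protein overlap
$\omega$; Glass' $\Delta$ decreases monotonically in $\lambda$.

## Known limitations

- The 18-class taxonomy is exposed as-is; any coarser grouping of
  classes into fewer display types is left to the user.
- Interaction magnitudes are not used as edge weights; the network is
  deliberately unweighted and the stringent two-gate calling rule is
  tuned for presence/absence.
- The exact-triple classification rate of the 2-raw-MAD band rule is
  bounded away from 1 for classes with unchanged coefficients (see
  above); widening the band or switching to a scaled MAD trades this
  against sensitivity and is left to the user via `mad_k`.
- $D_I$ is conservative when clouds are built from few replicates; the
  chi-square law holds in the control-dominated regime.
- Median polish assumes most wells on a plate are near-inert; saturated
  plates of strong effects violate this.
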