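---
title: "Comparing automated and corrected segmentations: metrics, statistics, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing automated and corrected segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segsim)
```

## The problem

Deep-learning autosegmentation tools produce templates that clinicians
review and correct slice by slice. The practical value of such a tool is the
time it saves, yet tools are usually optimized and reported with spatial
similarity metrics — above all the volumetric Dice similarity coefficient —
that need not track correction time at all. A large thoracic-cavity
correction workflow is the motivating setting: an automated lung
segmentation is corrected by a human, and we want to know which of several
auto-vs-corrected similarity metrics best predicts the minutes spent
correcting.

`segsim` implements the full metric panel on pairs of co-registered 3D
binary masks, the nonparametric statistics relating the panel to correction
times and clinical covariates, and a synthetic phantom generator that lets
every stage be validated without clinical data.

## Masks and geometry

A `binary_mask` is a 3D lattice of 0/1 voxels with a physical spacing
$(s_x, s_y, s_z)$ in mm; axis 3 is the axial (slice) axis. All distances are
computed in mm from the spacing alone. Rotational or shear components of a
NIfTI affine are deliberately ignored (with a warning flag): both masks of a
pair live on the same grid, so a shared rigid transform cannot change any
inter-mask distance. Pairs on different grids are rejected, never resampled
— resampling would silently change the raw pixel-count metrics.

Non-binary source volumes are binarized at a threshold (default 0.5, i.e.
anything positive in a 0/255 or probability map becomes foreground); this is
a package convention, stated here because deposited masks do not always
document their handling of intermediate values.

## The metric panel

Write $A$ for the auto mask, $B$ for the corrected reference, and $|\cdot|$
for voxel counts.

**Volume overlap.** Volumetric Dice $\mathrm{DSC} = 2|A \cap B| / (|A| +
|B|)$ and Jaccard $J = |A \cap B| / |A \cup B|$, linked by $\mathrm{DSC} =
2J/(1+J)$. Both are 1 at perfect overlap and 0 at none. When both masks are
empty the 0/0 form is resolved to 1 (perfect agreement on absence) so batch
runs stay total; one empty mask gives 0. The false negative volume
$\mathrm{FNV} = |B \setminus A|$ counts voxels the human had to add; it is
directional and reported in raw voxels, matching how such panels are
tabulated (an mm³ value is `FNV * prod(spacing)`).

**Surfaces.** Boundary voxels are foreground voxels with a face-adjacent
(6-connectivity) background neighbour; the lattice border counts as
background so structures clipped by the field of view keep a surface. Two
boundary representations are exposed because the literature is ambiguous
about which underlies reported surface-Dice values:

* *face-surfel*: one element per exposed voxel face, weighted by face area
  (mm²) — the representation with genuine surface-area semantics under
  anisotropic spacing, and the default for the surface DSC;
* *voxel-center*: one element per boundary voxel — the "every point in
  surface A" reading, and the default for Hausdorff and average surface
  distances.

The surface DSC at tolerance $\tau$ counts the area of each surface lying
within $\tau$ mm of the other surface:
$$\mathrm{DSC}_\tau = \frac{W_A\{d \le \tau\} + W_B\{d \le \tau\}}{W_A + W_B},$$
non-decreasing in $\tau$ and equal to 1 for identical masks at any $\tau \ge
0$. The default panel computes $\tau \in \{0, 4, 8, 10\}$ mm. A guard of
$10^{-9}$ mm is added to $\tau$ in the comparison so exactly coincident
surfels are never lost to floating-point noise; on integer-spacing lattices
this cannot reclassify any non-coincident pair.

The percentile Hausdorff distance pools the directed nearest-neighbour
distances of both directions into one multiset, sorts it, and returns the
requested percentile — the maximum at $p = 100$, with $p \in \{100, 99, 98,
95\}$ in the default panel. The pooled (single-ordering) convention is
implemented rather than the max-of-directed-percentiles variant, directly
following the sorted-pooled description of the metric; percentiles use
linear interpolation between closest ranks (R quantile type 7) so values are
bit-reproducible. The average surface distance is the average of the two
*directed* mean distances, not the mean of the pooled multiset — the two
differ whenever the surfaces have unequal element counts, and the
two-directed-means convention is the one implemented, verbatim from the
metric's definition.

**Path lengths.** The added path length (APL) is the number of edge pixels
of the corrected segmentation absent from the auto segmentation's edge,
summed over axial slices: a proxy for the contour length a human redraws.
Edges are 2D per-slice (4-connectivity, slice border = background), and
membership is exact pixel-index coincidence — the definition is a set
difference, not a distance criterion, so no tolerance band is applied. The
false negative path length (FNPL) removes edge pixels created by *shrinking*
edits: a corrected edge pixel lying strictly inside the auto volume can only
exist because auto voxels were erased, so FNPL counts corrected edge pixels
neither on the auto edge nor inside the auto foreground, and FNPL ≤ APL
always. Both are raw pixel counts; a 3D-boundary variant is available behind
`mode = "boundary3d"` for sensitivity analysis but the slice-wise 2D
convention is the default and the reported one, matching the slice-wise way
corrections are actually drawn.

Nearest-distance computation is an exact all-pairs minimum in compiled code.
At this package's problem sizes (boundary sets up to ~10⁴ elements) the
O(nm) compiled search is fast, exact, and free of the approximation
subtleties of sampled distance transforms; the test suite checks it against
an independent all-pairs implementation in plain R on hundreds of random
lattices.

## The statistics layer

All tests are two-sided and nonparametric, with a Shapiro–Wilk gate that
*logs* (rather than silently branches on) the non-normality that motivates
rank-based tests at α = 0.05:

* **Spearman** rank correlation: Pearson correlation of mean-ranked data;
  p-values by exact enumeration of all $n!$ permutations for $n \le 10$
  (feasible and reproducible) and the $t$ approximation above that. The
  switch point is fixed so p-values never depend on the environment.
* **Mann–Whitney U** (2 groups): exact null distribution when $n_1 n_2 \le
  400$ with no ties, otherwise the normal approximation with tie and
  continuity corrections; the reported U is $\min(U_1, U_2)$.
* **Kruskal–Wallis** (≥ 3 groups): tie-corrected H with a chi-square
  p-value; pairwise Mann–Whitney post-hoc tests run only when the omnibus is
  significant, with Bonferroni adjustment $\min(1, m\,p)$ within that one
  family of $m$ pairwise comparisons.

Missing values are dropped pairwise per test and the per-test n recorded,
since cohort subgroups legitimately differ in size. `associate_panel()`
applies this battery to a metric panel: Spearman of every metric against
correction time ranked by $|\rho|$ (similarity metrics correlate negatively
with time, error metrics positively), plus the appropriate two-group or
multi-group test for each categorical covariate against time and each
metric. Constant columns are excluded and flagged rather than propagating
undefined correlations.

Spearman measures monotone, not linear, association; it is nevertheless the
appropriate choice here because correction times are strongly right-skewed
and the question is ordinal ("do worse cases take longer"), not affine.

## The synthetic cohort generator

`make_pair()` derives an auto mask from a reference phantom (ellipsoid, box,
or a two-lobe shape that mimics paired lungs) by removing spherical blobs
(regions the autosegmentation missed — the human must add them), appending
blobs outside the reference (auto false positives — the human erases them),
and optionally dilating/eroding the whole auto mask. Blobs are spheres in
*mm* space, so with anisotropic spacing they span fewer slices than in-plane
pixels, as real lesions do. A truth ledger records exactly which voxels
differ, giving every metric a ground-truth target (with no boundary shift,
FNV equals the ledger's removed-voxel count exactly).

`make_cohort()` writes NIfTI pairs, a manifest, and a case table whose
correction times follow
$$t_i = \exp\big(\log(\beta_0 + \beta_1 d_i) + \varepsilon_i\big), \qquad
\varepsilon_i \sim \mathcal N(0, \sigma^2),$$
where $d_i$ is a chosen driver metric (APL by default). Lognormal noise
keeps times positive and right-skewed, matching the observed non-normality
of correction-time distributions. Defaults — 64×64×32 voxels at (1, 1, 3)
mm, $\beta_0 = 5$ min, $\beta_1 = 0.015$ min per APL pixel, $\sigma = 0.25$
— place desk-scale cohorts in the 5–50 minute range typical of thoracic
correction workflows. All randomness is driven by explicit seeds and cohorts
are bit-reproducible.

Two samplers define the edit-structure distribution across a cohort.
`default_spec_sampler()` varies blob counts and radii freely.
`fixed_volume_spec_sampler()` holds the *total* edit volume per case fixed
while the blob count varies (equal-radius spheres splitting a volume
budget): in that regime volume-overlap metrics see nearly the same error in
every case while path-length metrics grow with the number of localized
edits, which is precisely the mechanism claimed to make APL a better
correlate of correction time than volumetric Dice. The acceptance suite
generates a 200-case cohort in this regime with APL-driven times and checks
that the association report ranks APL's $|\rho|$ above volumetric Dice's.

What the generator does **not** emulate: real lung anatomy or CT
intensities, spatially correlated correction behaviour, inter-observer
variability, or the specific error modes of any particular network. A
passing recovery test therefore shows the pipeline recovers a known
generative structure — not that any particular metric will dominate on a
given clinical dataset.

## Numerical choices and degenerate inputs

* Quantiles/IQRs: linear interpolation (type 7) everywhere.
* Empty masks: volume metrics use the conventions above; surface metrics
  are undefined and raise a classed error (`compare_masks()` converts this
  to `NA` plus a warning code so batch runs continue); APL/FNPL are defined
  for empty masks (an empty corrected mask has zero edge pixels).
* Comparability: identical dimensions and spacing within 1e-5 relative
  tolerance, enforced before any metric.
* Panel invariants (similarities in [0, 1], distances ≥ 0, FNPL ≤ APL) are
  asserted on every row before it is returned or written.
* Batch problem sizes: the bundled tests and examples run cohorts of 200
  cases at 64×64×32 and smaller grids for unit fixtures; these sizes keep
  full-panel computation to well under a second per case while producing
  boundary sets large enough to exercise the compiled distance kernel.

## Limitations

* Metrics are lattice-based; no sub-voxel surface interpolation or meshing,
  so surface areas are staircase approximations of smooth anatomy.
* The percentile-Hausdorff and surface-DSC conventions implemented are the
  pooled-multiset and (by default) area-weighted-surfel readings; published
  values computed under other conventions (max-of-directed percentiles,
  unweighted voxel counts) will differ slightly. Both boundary modes are
  exposed so the sensitivity can be measured.
* The statistics layer reproduces the analysis *structure*; clinical
  conclusions require clinical data, which the synthetic generator does not
  attempt to imitate beyond the monotone metric–time link.
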