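# segsim — spatial similarity metrics for 3D segmentation masks

`segsim` compares an automatically generated binary segmentation ("auto")
against a manually corrected reference ("corrected") on the same voxel grid,
for workflows that ask not just *how similar* an autosegmentation is but
*how much work it takes to fix*. It is aimed at medical-image analysts
evaluating autosegmentation tools — e.g. thoracic-cavity or organ-at-risk
segmentations corrected slice-wise by a clinician.

## The metric panel

For auto mask $A$ and corrected mask $B$ (voxel counts $|\cdot|$, surfaces
$S_A$, $S_B$, directed nearest-surface distances $d$):

| Metric | Definition | Units |
|---|---|---|
| Volumetric DSC | $2\|A \cap B\| / (\|A\| + \|B\|)$ | – |
| Jaccard index | $\|A \cap B\| / \|A \cup B\|$ (DSC $= 2J/(1+J)$) | – |
| Surface DSC at $\tau$ | $(W_A\{d \le \tau\} + W_B\{d \le \tau\}) / (W_A + W_B)$, area-weighted surfels | – |
| Percentile Hausdorff | percentile of the pooled directed nearest-distance multiset (100 = max) | mm |
| Average surface distance | mean of the two directed mean distances | mm |
| Added path length (APL) | corrected edge pixels not on the auto edge, per axial slice | pixels |
| False negative path length | APL minus edge pixels created by shrinking edits | pixels |
| False negative volume | $\|B \setminus A\|$ | pixels |

A nonparametric statistics layer (Shapiro–Wilk gate, Spearman with exact
small-n permutation p-values, Mann–Whitney U, Kruskal–Wallis with Bonferroni
post-hoc) relates metric panels to correction times and covariates, and a
synthetic phantom-cohort generator makes the whole pipeline testable without
clinical data. See the vignette in `vignettes/segmentation-similarity.Rmd`
for conventions and rationale.

## Worked example

```r
library(segsim)

# a synthetic pair: reference phantom plus localized auto errors
p <- make_pair(perturbation_spec(n_add_blobs = 2, n_erase_blobs = 1, seed = 7))
row <- compare_masks(p$auto, p$corrected, case_id = "demo")
round(unlist(row[c("volumetric_dsc", "surface_dsc_0mm", "hd95_mm",
                   "asd_mm", "apl_px", "fnv_px")]), 4)
#> volumetric_dsc surface_dsc_0mm        hd95_mm         asd_mm
#>         0.9950          0.9673         0.0000         0.0878
#>         apl_px          fnv_px
#>        52.0000        215.0000
```

The auto mask misses two blob-shaped regions and adds one false-positive
blob: volumetric Dice barely notices (0.995) while the added path length
(52 edge pixels to redraw) and false negative volume (215 voxels to add)
quantify the correction work directly.

A cohort-level run, ending in the metric-vs-time association report:

```r
co  <- make_cohort(40, fixed_volume_spec_sampler(), time_model_spec(), seed = 1)
res <- batch_panel(co$manifest)            # one metric row per case + summary
rep <- associate_panel(res$panel, co$cases)
head(rep$correlations, 3)                  # Spearman rho, ranked by |rho|
```

A thin CLI over the same functions lives at `inst/cli/segsim.R`
(`compare`, `batch`, `associate`, `synth` subcommands).

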