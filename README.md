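# telostorm

Quantifying telomere size and chromatin compaction from STORM
single-molecule localization microscopy.

## The problem

Human telomeres are a few kilobases of TTAGGG repeats whose chromatin state
is debated: does the DNA damage response (DDR) at dysfunctional telomeres
require the chromatin to decompact? STORM imaging answers this by resolving
each telomere as a cluster of single-fluorophore localizations (~10 nm
precision) and measuring its size as the **radius of gyration**

$$R_g = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}\lVert \mathbf{r}_i-\bar{\mathbf{r}}\rVert^2},$$

the RMS distance of the N localizations from the cluster centroid. With
mean telomere lengths $N_L$, $N_S$ (kb) and mean radii $R_{g,L}$, $R_{g,S}$
for two conditions, the ratio of chromatin volume densities is

$$\frac{\rho_L}{\rho_S} = \frac{N_L}{R_{g,L}^3}\cdot\frac{R_{g,S}^3}{N_S},$$

with upper/lower bounds from perturbing both radii by the
experiment-to-experiment variation of the mean ($\pm\delta$, 0.005 µm).
Comparing the measured $R_g$ with the B-DNA contour length
($n_{bp} \times 0.332$ nm) bounds the linear compaction factor
(contour / $2R_g$).

`telostorm` is for microscopists and chromatin biologists who need a
tested, scriptable version of this analysis: it takes localization tables
(or raw frame stacks) through fiducial-based drift correction, quality
filtering, blink merging, DBSCAN clustering, wide-field registration,
automated cluster QC and DDR-overlap classification, per-cluster
morphometrics, and the density-ratio / compaction estimators. A synthetic
data generator with full ground truth (cluster shapes and target $R_g$,
two-component blinking, smooth drift, always-on fiducials, DDR-marker
channel) stands in for the microscope so every stage is testable.

## Worked example

```r
library(telostorm)

cfg <- storm_config(
  seed = 42,
  conditions = list(
    list(label = "HeLa_S", n_fov = 2, mean_rg_nm = 68, sd_rg_nm = 21),
    list(label = "HeLa_L", n_fov = 2, mean_rg_nm = 88, sd_rg_nm = 23)),
  blink = list(frames_total = 4000))
report <- run_pipeline(cfg)
print(report)
#> telostorm run (seed 42): 4 FOVs processed, 0 discarded
#>   HeLa_S: 180 telomeres, mean Rg 69.7 nm (SD 19.1)
#>   HeLa_L: 180 telomeres, mean Rg 84.7 nm (SD 22.1)
print(report$summaries$HeLa_S)
#> Condition HeLa_S: 180 telomeres
#>   mean Rg 69.7 nm (SD 19.1), quartiles 56.8/68.3/79.7 nm
#>   mean localizations per telomere 131
#>   fraction Rg >80nm: 25.0%
#>   fraction Rg >100nm: 9.4%
```

Two simulated conditions with ground-truth mean R_g of 68 and 88 nm come
back at 69.7 and 84.7 nm: the short condition is slightly inflated by the
~10-nm localization noise (E[R_g²] = R_g,true² + 2σ²), and both carry the
heterogeneity (SD ~20 nm) put into the generator. Each of the 4
fields of view was drift-corrected from its fiducials, filtered
(precision > 30 nm, log-likelihood > 250, PSF width > 175 nm discarded),
blink-merged (30 nm radius, 1-frame gap), clustered (DBSCAN, eps 90 nm,
min 8), gated (≥ 50 localizations), registered to its wide-field image and
QC'd automatically.

The density-ratio and compaction estimators operate on the summary
numbers:

```r
density_ratio(33, 0.088, 11, 0.068)
#> Chromatin density ratio rho_L/rho_S = 1.4 (range 0.93-2 at delta = 0.005 um)
compaction_factor(contour_length(11000), 68)
#> [1] 26.85294   # < 27-fold linear compaction for an 11-kb telomere
```

So a three-fold longer telomere occupies only a slightly denser volume
(ratio 1.4, bounds 0.93–2.0), and an 11-kb telomere (3650-nm contour) at
R_g = 68 nm is compacted less than 27-fold in length.

## Scope

2D analysis only (positions in nm, origin at the field's lower-left
corner); axial drift is assumed handled in hardware. The raw-frame
localizer is a desk-scale Poisson-MLE fitter, not a GPU sCMOS pipeline;
the canonical entry point is a localization table.
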