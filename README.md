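# HistoDMRI

Quantitative comparison between gray-matter **cytoarchitecture** — cell
area density and its spatial heterogeneity, measured on Nissl-stained
histology sections — and in-vivo **diffusion MRI microstructure
measures**: FA and trace from the diffusion tensor model, and MSD and
RTOP from a biexponential (two-tensor plus free-water) propagator model.

The package is aimed at researchers validating dMRI measures against
histology: it implements the model fits, the cell-segmentation pipeline
with Dice-based quality control, the regional average/heterogeneity
statistics, the Pearson + FDR correlation design split by
cortical/subcortical class, and a synthetic-data generator that emulates
the whole study (subjects × regions × modalities) with a known, tunable
coupling between local cell density and local diffusivity — so every
stage is testable against ground truth.

## The measures at the core

For a region with voxel values $x_1,\dots,x_N$ of a dMRI measure:

- average: $\frac{1}{N}\sum_i x_i$
- heterogeneity: the inter-voxel statistic
  $h = \frac{1}{N^2}\sum_i\sum_j |x_i - x_j|$ (mean absolute pairwise
  difference, zero diagonal terms included in the $N^2$ denominator)

For histology: cell area density (CAD) is the fraction of ROI area
covered by segmented cell bodies; its heterogeneity is the population
variance of CAD over a grid of diffusion-voxel-sized (0.8 mm) squares
tiling the ROI.

Diffusion models: the tensor fit uses the $b \in \{0, 1000\}$ s/mm²
shells (WLLS on log-signal, one reweighting pass); the biexponential
model

$$S(b,\mathbf g)=S_0\big[f_{\rm iso}e^{-bD_{\rm iso}}+(1-f_{\rm iso})(w\,e^{-b\mathbf g^\top D_f\mathbf g}+(1-w)\,e^{-b\mathbf g^\top D_s\mathbf g})\big]$$

is fit to all shells by box-constrained Levenberg–Marquardt, and its
tissue-only propagator measures are
$\mathrm{MSD}=2\tau[w\,\mathrm{tr}D_f+(1-w)\,\mathrm{tr}D_s]$ and
$\mathrm{RTOP}=(4\pi\tau)^{-3/2}[w\det D_f^{-1/2}+(1-w)\det D_s^{-1/2}]$.

## Worked example

Generate a 4-subject × 9-region synthetic study with a strong positive
density–diffusivity coupling, run the full pipeline, and look at the
pooled heterogeneity correlations:

```r
library(HistoDMRI)
des   <- studyDesign("reduced", kappa = 1.5)   # desk-scale sizes
study <- do.call(generateStudy, c(des, list(nSubjects = 4, seed = 7)))
res   <- runStudyPipeline(study)
het   <- res$correlations[res$correlations$group == "het-all", ]
print(het[, c("pair", "n", "r", "p", "q")], row.names = FALSE, digits = 3)
```

```
       pair  n       r        p        q
   hCAD-hFA 36 0.00647 9.70e-01 9.70e-01
   hCAD-hTR 36 0.80608 2.98e-09 7.94e-09
  hCAD-hMSD 36 0.80244 3.97e-09 7.94e-09
 hCAD-hRTOP 36 0.08160 6.36e-01 8.48e-01
```

Reading this: across the 36 (subject, region) points, regions generated
with patchier cytoarchitecture (higher heterogeneity of cell area
density, hCAD) show higher heterogeneity in trace (r = 0.81) and MSD
(r = 0.80), both surviving FDR correction — the planted coupling is
recovered through segmentation, model fitting and the regional
statistics. FA and RTOP heterogeneity stay null because the generator
couples density to *diffusivity*, not to anisotropy. The summary table
behind these numbers has one row per (subject, region, measure):

```
 subject region    class measure  average heterogeneity  n
  sub-01    ACG cortical      FA 4.41e-02      1.50e-02 27
  sub-01    ACG cortical      TR 1.66e-03      2.17e-04 27
  sub-01    ACG cortical     MSD 1.09e-04      1.45e-05 27
  sub-01    ACG cortical    RTOP 1.93e+08      2.82e+08 27
  sub-01    ACG cortical     CAD 1.28e-01      1.65e-03 25
```

(trace in mm²/s, MSD in mm², RTOP in mm⁻³, CAD dimensionless; `n` is
voxels for dMRI rows and grid squares for CAD rows.)

With `kappa = 0` the same pipeline yields a calibrated null (|r| small,
p uniform). `writeStudy()` serializes a generated study to NIfTI + PNG +
CSV; `readDiffusionVolume()`, `readLabelVolume()`, `readSummaryTable()`
read the same formats back.

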