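# TFMtools

Traction force microscopy (TFM) analysis in R: from paired fluorescent
bead images to per-cell contractility readouts and group-level
statistics.

Cells adhering to a soft elastic substrate pull on it. TFM infers the
traction stresses behind that pulling from the motion of fiducial beads
embedded in the substrate surface, comparing a *traction-loaded* image
(cell attached and pulling) with a *traction-free* reference (cell
released). TFMtools is written for mechanobiology studies that compare
cell populations — e.g. diseased vs healthy muscle stem cells on
muscle-stiffness (~12 kPa) silicone — where the questions are: how
strongly does each cell pull, and do the groups differ?

## The method

1. **Bead detection** — difference-of-Gaussian band-pass (σ = 1.5/2.0
   px) plus a minimum-eigenvalue (Shi–Tomasi) corner response with
   non-maximum suppression and subpixel refinement, in the
   traction-free image.
2. **Displacement tracking** — pyramidal Kanade–Lucas–Tomasi optical
   flow with a 61 px window into the loaded image, with
   forward–backward consistency checks, followed by median drift
   correction against beads outside the cell.
3. **Gridding** — moving-least-squares interpolation of the scattered
   bead vectors onto a regular 8 px grid, then mild Gaussian smoothing.
4. **Traction reconstruction** — regularized Fourier transform traction
   cytometry (FTTC): per-wavevector Tikhonov inversion of the
   Boussinesq half-space Green's tensor

   $$\tilde T(k) = \bigl(\tilde G^\top \tilde G + \lambda I\bigr)^{-1}
     \tilde G^\top \tilde u(k), \qquad
     \tilde G(k) = \frac{2(1+\nu)}{E k^3}
     \begin{pmatrix}(1-\nu)k^2+\nu k_y^2 & -\nu k_x k_y\\
     -\nu k_x k_y & (1-\nu)k^2+\nu k_x^2\end{pmatrix}$$

   with E = 12 kPa, ν = 0.5 and λ = 2.47×10⁻⁵ (pixel-normalized) by
   default, zero-mode suppression (global force balance) and
   taper-padding against wrap-around.
5. **Readouts** — strain energy U = ½∑(T·u)ΔA over the field of view,
   max/mean traction magnitude inside the cell mask.
6. **Statistics** — two-tailed Mann–Whitney U (exact for small
   tie-free samples, normal approximation with tie/continuity
   correction otherwise), mean ± SEM summaries, significance stars,
   fold ratios, and a t-test from printed summary statistics.

A synthetic-scene generator renders bead image pairs from known
ground-truth traction patterns through the package's own forward
solver, so the whole chain is validated without microscope data.

## Worked example

Simulate a two-group cohort (disease-like cells pulling at 1000 Pa vs
controls at 600 Pa, 10 cells each) and run the full pipeline:

```r
library(TFMtools)
cfg <- list(
  seed = 11,
  simulate = list(n_per_group = 10, magnitudes = c(1000, 600),
                  image_dim = c(160, 160), pattern_radius = 18)
)
res <- runPipeline(cfg, "tfm_demo")
head(res$measurements[, 1:5], 4)
#>  cell_id group max_traction_pa mean_traction_pa strain_energy_j
#>  cell001   DMD        818.2765         187.4688    4.655318e-15
#>  cell002   DMD        912.8259         227.3855    6.054096e-15
#>  cell003   DMD        659.7860         147.3296    2.811005e-15
#>  cell004   DMD        681.5405         159.4632    3.274366e-15
```

`tfm_demo/report.txt` then contains:

```
== max_traction_pa ==
  DMD: 860.9 +/- 61.6 (n = 10)
  WT: 496 +/- 23.2 (n = 10)
  Mann-Whitney U = 99, p = 0.0002461 (normal-approximation) ***
```

Reading: each simulated "DMD" cell was reconstructed with a peak
traction around 0.86 kPa against 0.50 kPa for controls (means ± SEM
over cells; the group magnitudes differ and the built-in ~20 %
cell-to-cell variability plus measurement noise spread the values), and
the rank test flags the difference at p < 0.001. Per-cell traction
maps (`cell*_traction.tif` + sidecar scale tables), vector-field CSVs,
bead tables, a manifest and a run log are written alongside.

For real data, replace `simulate` with a `cells:` list of per-cell
`loaded`/`relaxed`/`mask` image paths and a group label (see
`readPipelineConfig()`); a thin command-line wrapper lives at
`inst/cli/tfm.R` (`simulate`, `run`, `compare` subcommands).

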