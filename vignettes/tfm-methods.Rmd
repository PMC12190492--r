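---
title: "Traction force microscopy with TFMtools: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traction force microscopy with TFMtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TFMtools)
```

## The measurement

Adherent cells pull on their surroundings. Traction force microscopy
(TFM) quantifies those forces by seeding cells on a soft, flat elastic
substrate carrying fluorescent fiducial beads, imaging the beads while
the cell pulls (the *loaded* image) and again after the cell has been
released (the *relaxed*, traction-free reference), and inverting the
observed substrate deformation for the in-plane traction stress field
the cell exerted. TFMtools implements that chain end to end:

1. bead detection in the relaxed image (`detectBeads()`),
2. optical-flow displacement tracking into the loaded image
   (`trackDisplacements()`),
3. drift correction and interpolation onto a regular grid
   (`driftCorrect()`, `gridDisplacements()`),
4. regularized Fourier transform traction cytometry
   (`reconstructTraction()`),
5. per-cell readouts (`strainEnergy()`, `tractionInRegion()`) and
   two-group statistics (`mannWhitneyU()`, `renderReport()`).

A forward-model generator (`generateScene()`, `generateCohort()`)
produces fully synthetic experiments with known ground truth, so every
stage and the end-to-end chain are testable without any microscope.

## Elastic model

The substrate is modelled as a semi-infinite, homogeneous, isotropic
linear-elastic half-space described by a Young's modulus $E$ (default
12\,000 Pa, a soft silicone matching muscle-tissue stiffness) and a
Poisson ratio $\nu$ (default 0.5, an incompressible gel). For in-plane
surface tractions $\mathbf T$ the surface displacement is a convolution
with the Boussinesq kernel; in Fourier space it is the per-wavevector
multiplication $\tilde{\mathbf u}(\mathbf k) = \tilde G(\mathbf k)
\tilde{\mathbf T}(\mathbf k)$ with

$$
\tilde G(\mathbf k) = \frac{2(1+\nu)}{E\,k^3}
\begin{pmatrix}
 (1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y\\
 -\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2
\end{pmatrix},
\qquad k = |\mathbf k|.
$$

The tensor is symmetric positive-definite for every $\mathbf k \ne 0$
and every $\nu \in [0, 0.5]$ — the incompressible limit $\nu = 0.5$
needs no special casing. It diverges as $k \to 0$: the zero mode (a
rigid offset plus the net force) is not recoverable, so the solvers
subtract the mean displacement, set $\tilde{\mathbf T}(0) = 0$, and
thereby enforce global force balance. Displacements and tractions are
consequently always mean-free; comparisons against free-space solutions
must be made up to a constant offset.

Two discrete details matter:

* **Nyquist symmetrization.** On even-sized grids the off-diagonal term
  $-\nu k_x k_y$ is odd in each component, which is sign-ambiguous at
  the Nyquist frequency (where $+\pi$ and $-\pi$ share one DFT index).
  It is set to zero on Nyquist rows/columns; otherwise the inverse
  transform of a real field acquires a spurious non-Hermitian part and
  the exact forward/inverse round trip breaks.
* **Periodicity.** `forwardDisplacement()` treats the grid as periodic
  by default, making it the exact algebraic inverse partner of
  `reconstructTraction(lambda = 0, pad = FALSE)`. For analysis of real
  (non-periodic) fields the inverse by default applies a cosine-taper
  border and zero-pads to twice the linear size before transforming,
  then crops back, which suppresses wrap-around artifacts.

## Regularization and its units

The inverse problem is stabilized by a per-wavevector Tikhonov (ridge)
term,

$$
\tilde{\mathbf T}(\mathbf k) =
\left(\tilde G^\top \tilde G + \lambda I\right)^{-1}
\tilde G^\top \tilde{\mathbf u}(\mathbf k),
$$

with a constant $\lambda = 2.47\times10^{-5}$ by default. The
convention here: displacements are expressed in pixels and the Green's
tensor is nondimensionalized by $E$ (the solver works in $E$-and-pixel
units internally and converts tractions to Pa on output), which makes
$\lambda$ transferable across magnifications. The conversion is
isolated in one place so the interpretation can be changed.

Under this convention $\lambda$ is numerically far below
$\tilde G^\top \tilde G$ at every resolvable wavevector of a
bead-spacing grid — it guards against exact singularity but performs
essentially no noise damping. Noise control in this workflow instead
comes from the measurement chain itself: the wide tracking window and a
mild Gaussian smoothing of the gridded displacement field
(`displacement_smoothing`, default $\sigma = 0.75$ grid nodes) applied
before inversion. That half-to-one-node smoothing damps sub-grid-scale
jitter — which the near-unregularized inverse would otherwise amplify
in proportion to $E k$ — while attenuating structures at the analysis
grid's feature scale (several nodes) by well under 10 %. Without it,
peak-traction estimates overshoot markedly (the maximum is an
extreme-value statistic and collects amplified noise), as does Gibbs
ringing at sharp traction edges.

## Bead detection and tracking

Detection mirrors the minimum-eigenvalue (Shi–Tomasi) corner detector:
a difference-of-Gaussian band-pass (`dogFilter()`, $\sigma = 1.5$ and
$2.0$ px by default, both configurable since image quality varies)
suppresses background and pixel noise; the smaller eigenvalue of the
Gaussian-windowed structure tensor forms the response; candidates above
`qualityLevel` times the global maximum are kept, non-maximum
suppression enforces a minimum spacing, and peaks are refined to
subpixel precision by separable quadratic interpolation of the
response.

Tracking is pyramidal Kanade–Lucas–Tomasi optical flow with a 61 px
window (default), run from the relaxed image into the loaded image so
that displacements are gel deformations at material points of the
relaxed reference — the configuration FTTC expects. The wide window
gives robust, smooth estimates but spatially averages the displacement
field; a final refinement pass with a small (15 px) window centred on
each bead removes that averaging bias while inheriting the wide
window's convergence basin (the refined vector is accepted only when
it stays within 2 px of the wide-window estimate). Tracks are dropped
when the intensity residual exceeds `maxResidual`, when the vector
exceeds `maxDisplacement`, or when a forward–backward consistency check
(1 px tolerance) fails.

Coordinates follow R conventions: 1-based, $x$ = column, $y$ = row,
origin top-left; subpixel positions are continuous.

Rigid stage drift between the two acquisitions is removed by
subtracting the median vector of beads outside the cell mask
(`driftCorrect()`, on by default in the pipeline); with fewer than 5
reference beads the field is returned unchanged with a warning.

Scattered bead vectors are interpolated onto a regular grid (8 px
default spacing, comparable to the bead spacing at the default seeding
density) by moving least squares: at each node a local quadratic is
fitted through the $k = 16$ nearest tracked beads with Gaussian
weights and evaluated at the node, falling back to a plane and then to
a weighted mean under rank deficiency, with the fitted value clamped to
the range of the neighbour values (a standard limiter against
extrapolation overshoot). Affine fields are reproduced exactly inside
the bead hull; globally collinear bead sets raise an error. No
installed scattered-interpolation routine was available, so this
component is implemented in the package.

## Per-cell readouts

* **Strain energy** $U = \tfrac12 \sum (\mathbf T \cdot \mathbf u)\,
  \Delta A$ over the full field of view (not restricted to the mask),
  in joules; with tractions in Pa and displacements in µm each term
  carries $10^{-18}$ J. Because the reconstructed traction field is
  mean-free and balanced, $U$ is invariant under rigid shifts of the
  displacement frame.
* **Max and mean traction** magnitude over the grid nodes inside the
  cell mask (nearest-pixel assignment). Both are reported since
  "average traction" in common usage can mean either the per-cell mean
  or a group mean of per-cell maxima; emitting both columns keeps
  either aggregation reproducible.

The report layer can display energy in J, µJ or pJ; stored values are
always joules.

## Group statistics

Per-cell readouts are compared between two groups (cells as the
sampling unit) with a two-tailed Mann–Whitney U test: midrank ties, the
exact null distribution when the combined sample size is at most 16 and
the data are tie-free (exact enumeration is cheap there and matches
small per-animal designs), otherwise a normal approximation with tie
and continuity corrections. The exact two-tailed p-value is defined as
$\min(1,\, 2\min(P(U \le u), P(U \ge u)))$. A t-test from printed
summary statistics (mean, SEM, n) is provided for reproducing published
group tables, in the classic Student form ($df = n_a + n_b - 2$) with a
Welch–Satterthwaite variant behind a flag. Summaries are mean ± SEM
(sd/$\sqrt n$); significance stars follow the conventional thresholds
(*** p < 0.001, ** p < 0.01, * p < 0.05, n.s. otherwise).

## The synthetic-data generator

`generateScene()` emulates the targeted imaging conditions: ~100 nm
beads rendered as isotropic Gaussian spots ($\sigma = 1.3$ px,
diffraction-limited at ~0.16 µm/px), seeded uniformly at 60 beads per
100×100 px (mean spacing comparable to the 8 px analysis grid), on a
12 kPa incompressible substrate. Traction patterns are adhesion-like:
a uniform circular patch, an inward-pulling dipole (zero net force by
construction — both discs share one node stencil with opposite signs),
or a ring of inward-pulling patches. Truth displacements come from the
package's own forward solver (2× zero-padded); loaded bead positions
are the relaxed positions plus the bilinearly interpolated truth field,
exactly, before any noise. Images carry Poisson shot noise (800
photons per intensity unit) plus Gaussian read noise (2 % of the bead
peak). Default cohort magnitudes (hundreds of Pa) produce 0.5–2 px
displacements at 12 kPa: in the regime the method targets, and well
above tracking noise. A fixed seed makes scenes and cohorts
bit-reproducible; per-cell seeds are derived deterministically from the
master seed.

What the generator does **not** emulate: realistic cell geometries,
bead polydispersity and clumping, photobleaching, focus drift,
out-of-plane displacements, and spatially correlated camera noise.
Passing recovery tests on these scenes therefore demonstrates the
correctness of the inverse chain under its own forward model and
realistic point-spread/noise rendering — not performance on any
particular microscope's data.

## Validation targets and observed behaviour

The test suite asserts, among others:

* Green's tensor closed forms to $10^{-12}$; forward solver linearity
  and translation equivariance.
* Fourier forward solution vs an independent direct-space Boussinesq
  convolution (singular self-term integrated analytically over an
  equal-area disc): within 2 % relative RMS on the central quarter of
  a 64×64 patch scene, after removing the (unrecoverable) mean offset.
* Exact forward/inverse round trip at $\lambda = 0$ on the same grid
  ($\le 10^{-8}$ relative; observed $\sim 4\times10^{-15}$).
* Ridge shrinkage: reconstructed traction norm non-increasing in
  $\lambda$.
* Tracking: identical frames give zero vectors; integer shifts
  recovered within 0.05 px; smooth ~2 px warps at SNR 20 within
  0.1 px RMS; error decreases with SNR over {5, 10, 20}.
* End-to-end on noiseless scenes (median over 10 cells): max traction
  within 20 % and strain energy within 35 % of truth (observed ~10 %
  and ~13 %); recovered metrics scale as $\alpha$ and $\alpha^2$ under
  magnitude scaling within 5 %.
* Exact Mann–Whitney p equals brute-force enumeration over random
  tie-free samples ($n \le 6$ per group); null rejection rate at
  $\alpha = 0.05$ within [0.03, 0.07] over 2000 replicates.
* Byte-identical reruns of cohort generation and the full pipeline
  under a fixed seed.

Problem sizes were chosen to keep the default suite fast: 64×64 grids
for solver algebra, 256×256 images for tracking and recovery, 10-cell
recovery cohorts, and a 2×25-cell pipeline cohort at 160×160 px in the
acceptance script.

## Known limitations

* The semi-infinite substrate assumption ignores finite gel thickness;
  tractions on thin gels are underestimated.
* The constant $\lambda$ is adopted verbatim under the pixel-normalized
  convention above; under this convention it provides essentially no
  smoothing, and results depend correspondingly on the tracking window
  and the displacement-smoothing sigma.
* Strain energy is integrated over the field of view, so neighbouring
  cells or drift residues inflate it.
* Masks are inputs; no segmentation is provided.
* 2D in-plane analysis only; out-of-plane tractions are not modelled.
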