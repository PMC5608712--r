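---
title: "Model-based vascular elastography: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based vascular elastography: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascelast)
```

vascelast reconstructs the spatial Young's modulus distribution of a small
artery's wall from ultrasound-measured displacements, and surrounds that core
with the rest of a low-flow carotid-remodeling study: Doppler-derived
hemodynamic indices, serial-section histology volumes, and the cohort
statistics. This vignette explains the models, the tunable parameters, the
numerical choices, and — importantly — what the synthetic experiments do and
do not demonstrate.

## The forward model

The vessel cross-section is an annulus (mouse carotid scale: lumen radius
0.19 mm, wall thickness 0.11 mm) treated as a linear, isotropic, nearly
incompressible solid in **plane strain** — the natural 2D reduction for a
long, axially constrained cylindrical vessel; the alternative (plane stress)
would be appropriate for a thin free plate, not an artery. Poisson's ratio is
fixed at 0.495, the conventional soft-tissue value. Loading is a uniform
luminal pressure (default 131 mmHg, a systolic tail-cuff value for the mouse
strain modeled here), converted internally at 0.133322 kPa/mmHg. All lengths
are mm, moduli kPa.

Discretization uses **6-node quadratic triangles** on a structured annular
grid, assembled with a 3-point (degree-2) rule that integrates the affine P2
stiffness exactly. Quadratic displacement elements are the cheapest standard
remedy for the volumetric locking that plagues linear triangles at
$\nu = 0.495$; the linear (constant-strain) element is retained only inside a
hand-verified unit test, at $\nu = 0$, where it is exact. Concentric material
interfaces are snapped onto the radial grid so each element belongs wholly to
one region.

The element stiffness is exactly linear in the local Young's modulus, so the
package assembles unit-modulus element blocks once per mesh and rescales them
per iteration; reassembly during the inversion costs a sparse-matrix build,
not a quadrature loop. Systems are solved by sparse Cholesky factorization;
the constrained residual is checked below $10^{-8}$ relative.

Two boundary-condition regimes exist:

* **Dirichlet regime** (the in vivo protocol): tracked displacements are
  imposed on the outer boundary, pressure on the lumen; the misfit then runs
  over interior nodes only, because the boundary entries carry no
  information.
* **Pure-pressure regime** (phantoms with known pressure): the outer boundary
  is traction-free and rigid-body modes are fixed by a minimal pin (one node
  fully, the lateral component of its neighbour). The pin selects an
  arbitrary member of the rigid-motion family, so all comparisons and misfits
  in this regime are made **gauge-invariant**: the three rigid modes are
  projected out of fields, residuals, and Jacobian columns in the nodal
  least-squares sense.

The independent oracle is the closed-form thick-walled-cylinder (Lamé)
solution. With the defaults (a = 0.19 mm, b = 0.30 mm, E = 20 kPa,
$\nu = 0.495$, p = 131 mmHg) the luminal radial displacement is 0.4158 mm;
the finite-element solution converges monotonically to it and agrees within
1% at a 0.01 mm mesh — at $\nu = 0.495$ specifically, which is the test that
rules out locking elements.

## Echo tracking

The tracking test-bed simulates radio-frequency (RF) frames as sums of
scatterer echoes: a 40 MHz modulated Gaussian pulse axially times a Gaussian
beam profile laterally, sampled at 250 MHz axially (3.08 µm per sample;
the instrument's RF sampling rate is not public, so a rate comfortably above
6 samples per carrier cycle was chosen) and 5.08 µm beam pitch (so the
default station grid lands on beam lines). Default PSF widths are
$\sigma_z = 10$ µm, $\sigma_x = 25$ µm, consistent with a high-frequency
small-animal scanner.

Displacements are estimated by block matching with the study protocol's
kernels — 100 µm by 25.4 µm, 80% overlap in both dimensions, hence 20 µm and
5.08 µm station steps — maximizing zero-normalized cross-correlation over an
integer search range. The axial estimate is refined to sub-sample precision
from the phase of the analytic (Hilbert-transformed) cross-correlation at
the integer peak, the standard near-unbiased RF delay estimator; a
3-point parabolic fit (measured bias ~0.04–0.06 samples at a quarter-sample
shift, vs ~0.02–0.03 for the phase fit) and a known-carrier cosine fit are
available behind config, and the lateral refinement is parabolic since
there is no lateral carrier. When the integer peak is an exact match
(correlation within $10^{-9}$ of 1) refinement is skipped: a fit through
asymmetric neighbours at a signal boundary would otherwise bias a perfect
match. Flat kernels are
flagged invalid, and stations below a correlation threshold (default 0.75)
are excluded when the grid is interpolated (bilinearly) onto mesh nodes.

Two deliberate experiment-design choices:

* **Scatterer density.** The generator default is 25 scatterers/mm²
  (configurable). Tracker-accuracy experiments use 500/mm², because a
  25.4 µm-wide kernel at 25/mm² is usually empty; ~1 scatterer per
  resolution cell is the minimum for usable speckle.
* **Frame-pair amplitude.** Tracked pairs represent a small intra-cycle
  pressure increment (3 mmHg, peak displacement ≈ 10 µm ≈ half a pulse-echo
  wavelength). Larger steps are counterproductive: at 6–9 mmHg the axial
  estimator starts slipping carrier cycles (measured axial RMS error grows
  from 0.85 µm to 5–8 µm).

**What tracking accuracy to expect.** On noise-free FEM-deformed vessel
speckle, with stations gated at correlation 0.95 (which drops the
partial-signal kernels at the wall edges, where occasional carrier-cycle
slips produce 20 µm outliers), the axial RMS error is ≈ 7% of the peak
displacement (0.75 µm against a 10.6 µm peak, stable across scatterer
seeds). The lateral channel is physically coarser: its
error floor is ≈ 1 µm (a fifth of a beam pitch) even at near-perfect
correlations, i.e. 25–50% of the peak displacement at physiological
frame-pair amplitudes, because the lateral correlation peak is as wide as
the beam (tens of µm) while the motion is micrometres. This asymmetry is
inherent to 2D speckle tracking, and it is why the kernel protocol invests
its resolution axially. Accuracy statements in the tests are therefore made
on the axial component; both components are reported by the acceptance
script.

## Modulus inversion

The unknown is the vector of region moduli $E$ (regions are the mesh's
labels: a single wall, intima/media, or sectors). The objective is the
squared-L2 Tikhonov form

$$\pi(E) = \tfrac12\,\lVert U(E) - U_m\rVert^2 + \tfrac{\alpha}{2}\,\lVert E \rVert^2,$$

minimized by damped Gauss–Newton updates
$\Delta E = [J^\top J + \alpha I]^{-1} J^\top (U_m - U)$, with the
sensitivity matrix $J$ computed exactly as
$-K^{-1}(\partial K/\partial E_k)U$ per region, reusing the factorization
(columns verified against central finite differences to $10^{-4}$ relative,
in practice agreeing to $10^{-8}$). The regularization weight is
dimensionless: the user-facing $\alpha$ is rescaled by
$\mathrm{trace}(J^\top J)/n_\text{params}$ at the first iteration.

Updates are applied multiplicatively, $E \leftarrow E\,e^{s\,\Delta E/E}$,
which preserves positivity smoothly and agrees with the additive step to
first order; box bounds (0.1–1000 kPa) are projected afterwards. A
backtracking line search halves $s$ until the full objective decreases, so
the objective is non-increasing across accepted iterations; the iteration
stops when the relative objective change or relative step falls below
$10^{-6}$, or after 50 iterations, and reports `converged`, `max_iter`, or
`stalled` with the full trajectory. All reconstructions start from the
homogeneous 20 kPa trial solution; trial values of 10 and 40 kPa reach the
same homogeneous answer within 1%.

Because the update direction omits the ridge gradient (it follows the
printed normal-equation form), a large $\alpha$ does not bias the iterates
toward zero — it stalls them near the misfit minimizer instead. The default
$\alpha = 10^{-6}$ keeps the ridge far below measurement-noise scale for the
coarse region parameterizations used here, where the Hessian is already
well-conditioned; `lcurve_sweep()` supports exploring the trade-off when
finer parameterizations make regularization load-bearing.

### Identifiability: what the phantom experiments show

Noise-free, a concentric two-region phantom (media 18 kPa, intima 54 kPa) is
recovered essentially exactly from the 20 kPa trial — the classic inverse
crime, which validates the machinery, not the practice.

With noise the geometry matters, and this is worth being precise about. For
a **concentric** nearly incompressible annulus under pure pressure, the
displacement field is dominated by a single equivoluminal $1/r$ mode whose
*shape* is modulus-independent; the moduli act through one amplitude. The
Fisher information for (intima, media) is therefore nearly rank-1 (measured
condition number of $J^\top J$: ~$3\times10^6$), and at 1% of peak
displacement Gaussian noise the media-modulus standard deviation is ~155% —
no estimator can resolve the split. An **eccentric** thickening (the package
uses a 120° sector, 0.06 mm deep — the typical shape of a flow-induced
neointima, consistent with the non-uniform modulus maps seen in remodeled
vessels) breaks the symmetry: the Cramér–Rao bound drops to well under 1%,
and the measured median recovery error across noisy repeats is ~0.2%. The
noisy-recovery experiments accordingly use the eccentric phantom; the
concentric case is kept for the noise-free oracle.

Relatedly, phantom reconstructions with known pressure solve the
pure-pressure problem rather than imposing the noisy measured boundary
values as Dirichlet data: independent per-node noise placed on a Dirichlet
boundary is amplified into strain artifacts (measured ~50-fold into modulus
error). The Dirichlet regime remains the right choice for in vivo data,
where tracked boundary displacements are spatially smooth.

## Synthetic cohorts

`generate_cohort()` draws per-animal Doppler metrics as
$\mathcal N(\text{mean}, \text{SEM}\sqrt{n})$ around the published group
parameters (four groups per artery: sham/ligated × 1/2 weeks), with two
physiological couplings: EDV is capped below PSV, and the systolic diameter
is the diastolic diameter minus a positive lognormal pulse difference —
drawing the two phases independently would randomize the sign of the
distension, which is a property of one vessel, not two. The time-averaged
mean velocity is VTI·HR/60.

Wall moduli implement the study's effect structure exactly: sham arteries
(and the contralateral RCA of ligated animals) get 18 kPa — deliberately
near, but not equal to, the 20 kPa trial solution — and the ligated LCA gets
18 kPa times the fold-change (2 at 1 week, 3 at 2 weeks). Moduli are not
jittered within arms, so within-arm modulus correlations carry no signal;
the correlation machinery is validated on purpose-built coupled cohorts in
the test suite. Histology profiles place a measurable intima only in ligated
LCAs (missing, never zero, elsewhere), with lognormal per-animal scale and
5% station noise on ring-geometry areas derived from the reported
histological lumen diameters (0.23 mm sham, 0.32 mm ligated).

What passing cohort tests shows: the pipeline — generation, reconstruction,
indices, volumes, statistics — preserves a 3-fold modulus contrast within
10% and detects it at n = 5 per arm. What it does not show: anything about
in vivo accuracy; real tracking noise is correlated, real pressure is not
known exactly, and real walls are not piecewise-constant.

## Hemodynamic indices and histology volumes

The index formulas are the study's: flow = HR × lumen area × VTI / 1000
(mL/min, circular lumen from one diameter — diastolic by default,
configurable, since the study does not say which it used); Poiseuille wall
shear $\tau = 4\mu Q/(\pi r^3)$ with $\mu$ = 0.035 P and an explicit
parabolic-flow assumption flag; RI = (PSV−EDV)/PSV; PI = (PSV−EDV)/TAmean
(the conventional reading of the denominator, with a literal-VTI variant
behind a flag); strain = (sys−dia)/sys × 100, reported as magnitude by
default because murine diastolic lumens exceed systolic ones and the
published plots show positive percentages — the signed value is always kept
alongside.

Compartment volumes integrate the 11-station area profiles (0–2000 µm every
200 µm) with the trapezoidal rule — exact for the piecewise-linear reading
of serial sections; a rectangle-rule variant exists since the study does not
state its quadrature. Missing intima yields missing volume and
intima/media ratio, never zero, so sham summaries exclude rather than bias.
The stacked surface model converts cumulative areas to equivalent-circle
radii (lumen black, intima yellow, media red, adventitia green).

## Statistics

Group summaries are mean ± SEM. Two-group comparisons use the
equal-variance Student's t (Welch behind a flag); four-group comparisons use
one-way ANOVA gated post hoc pairwise t tests at p < 0.05, uncorrected by
default to mirror the study's stated procedure (Bonferroni available, with a
log note). Correlations are Pearson with the exact t-transform p-value. The
published power calculation is not reimplemented: its test design is
underdetermined from the printed numbers.

## Problem sizes and determinism

The shipped experiments are desk-scale by design: recovery phantoms use
0.02–0.03 mm meshes (≈400–900 elements), the convergence study refines to
0.01 mm, tracking frames are ≈0.7 mm square, and cohorts run 5 animals per
arm. Every stochastic stage takes an explicit integer seed, child seeds are
derived per stream, and the RNG state is restored afterwards; identical
configurations reproduce bit-identical artifacts, which the test suite
checks by hashing.

## Known limitations

Linear elasticity at a fixed reference pressure (no hyperelasticity,
anisotropy, viscoelasticity, or 3D effects); scalar Doppler metrics are
drawn from group distributions, not synthesized from flow physics; lateral
tracking error is beam-width-limited as discussed; absolute moduli are
conditional on the assumed luminal pressure; and the regional
parameterization assumes the region map is known — per-element inversion is
configurable but needs regularization choices this package does not tune
for you.
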