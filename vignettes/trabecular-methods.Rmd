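---
title: "Methods: trabecular morphometry and phylogenetic allometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trabecular morphometry and phylogenetic allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabecula)
```

This vignette documents the models, conventions and numerical choices
behind the package: what each measurement means, which decisions were
genuinely open and how they were resolved, what the synthetic generators
do and do not emulate, and the known limitations of the statistical
machinery. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The measurement model

All morphometry operates on a `bin_volume`: a 3D logical grid with an
isotropic physical voxel size in mm. The axis convention is anatomical:
x mediolateral, y anteroposterior, z proximodistal, with lower z distal.
A grayscale stack is first thresholded (`binarize()`; Otsu's
between-class-variance criterion on the full 3D histogram by default,
with the method and threshold recorded in the volume's provenance) and
then cleaned (`purify()`): only the largest 26-connected foreground
component is kept, and every 6-connected background component that does
not touch the stack boundary is filled. After purification the structure
is a single component without internal cavities, which is what makes the
Euler characteristic interpretable as a loop count.

When the Otsu criterion has a plateau of equally good thresholds (well
separated modes always produce one), the plateau midpoint is returned;
this keeps the threshold stable and strictly between the modes.

### Connectivity (Conn, ConnD)

The Euler characteristic Δχ is computed as V − E + F − C of the
union-of-closed-cubes complex: vertices, edges and faces are counted if
they belong to at least one foreground voxel. This realizes the
26-connected-foreground / 6-connected-background convention and is
algebraically the same as summing 2×2×2 octant contributions over the
zero-padded volume, but vectorizes cleanly in R. For a purified volume
Δχ = 1 − β₁, so `conn = 1 - delta_chi` counts independent loops;
`conn_density` divides by the physical stack volume (mm⁻³). The octant
accounting is verified in the tests against an independent cycle-rank
oracle (an explicit graph of the rod-lattice skeleton: β₁ = E − V + C).

No mirror-boundary correction is applied: Δχ is that of the structure as
a closed object. This is the simplest defensible convention; absolute
Conn values near the stack boundary may therefore differ from tools that
apply edge corrections.

### Local thickness (TbTh, TbSp)

Thickness at a voxel is the diameter of the greatest sphere that fits in
the phase and contains the voxel. The discrete convention has to be
pinned down for "exact" to mean anything:

* the sphere centred at phase voxel c has radius r(c) = Euclidean
  distance from c to the nearest opposite-phase **voxel centre**;
* the sphere covers voxels i with d(i, c) < r(c) (open ball; squared
  centre-to-centre distances are integers, so the strict inequality is
  evaluated exactly in integer arithmetic);
* voxels outside the grid are treated as phase continuation — no
  artificial background padding, so a plate spanning the whole grid
  behaves like an infinite plate.

The implementation computes an exact squared Euclidean distance
transform (three-pass 1D lower-envelope algorithm), discards spheres
provably contained in a neighbour's sphere (r_j ≥ r_c + d(c,j), checked
in exact integer arithmetic), and propagates the surviving spheres in
decreasing radius order. The mean is volume-weighted over all phase
voxels. The identical convention is implemented independently in the
test suite as a brute-force two-loop oracle, and the two agree
voxel-for-voxel on grids up to 48³ (the shipped oracle case is a
radius-5 cylinder in a 21×21×16 grid and a random field at 18³).

With this convention a slab of thickness t voxels measures t + 1 voxels
(centre-to-centre distances cannot see the half-voxel of material beyond
the outermost centres), and voxelized cylinders and balls land within a
fraction of a voxel of their continuous diameters; the package's declared
tolerance for thickness ground truth is therefore ±1 voxel throughout.

### Surface density (BS/BV)

The bone surface is triangulated by marching tetrahedra (each 2×2×2 cell
split into six tetrahedra around its main diagonal; per-tetrahedron
triangulation needs no case table) at iso-level 0.5, after 1-voxel-plus
zero padding so boundary-touching structures are closed. Meshing the raw
binary indicator overestimates oblique surfaces (staircase bias), so the
indicator is first smoothed with a separable Gaussian of σ = 0.7 voxels:
for a locally flat interface the smoothed 0.5-level surface passes
exactly through the phase boundary, while curvature introduces a bias of
order σ²·κ. The σ = 0.7 default balances the upward staircase bias
against the downward edge-rounding bias; with it the voxelized sphere of
radius 12 and boxes of a few tens of voxels reproduce their analytic
areas within the 4% and 5% tolerances asserted in the tests. BS/BV
divides the triangulated area by the foreground voxel volume.

### Fabric (DA, MDT)

The mean intercept length along direction d is the total in-grid length
of a parallel ray bundle divided by the number of bone/marrow phase
crossings encountered. Defaults: 512 quasi-uniform directions (Fibonacci
hemisphere lattice, randomly rotated from a seed so the direction set has
no fixed alignment with the image axes), 1-voxel ray spacing, 0.5-voxel
marching step with nearest-voxel sampling. A quadratic form
d′A d = 1/MIL(d)² is fit by linear least squares; the ellipsoid radii are
the inverse square roots of the eigenvalues of A. Then
DA = 1 − r_min/r_max ∈ [0, 1] and MDT is the unit major-axis vector
(eigenvector of the smallest eigenvalue), sign-normalized to z ≥ 0.
Directions with zero crossings are dropped; if more than 20% drop the
structure is declared too coarse for MIL and an error is raised (the
full-volume summary reports DA/MDT as missing with a flag instead of
failing). If the smallest eigenvalue is non-positive (extreme
anisotropy), DA saturates at 1.

`project_mdt()` fixes the reporting convention for femora: right-side
vectors are mirrored mediolaterally (x → −x) first, then any vector with
negative z is replaced by its antipode so all directions lie on the
proximal hemisphere.

## 2. VOI selection and quality control

`central_slice()` returns the z index that best balances head-mask volume
below and above it; exact ties break toward the distal (lower-index)
side. `fit_max_cube()` returns the largest axis-aligned cube with **odd**
edge length whose z extent is centred on that slice and which contains no
cortical voxel; among equally large cubes the one whose centre is nearest
the trabecular centroid of the central slice wins (then lowest x, y — a
deterministic surrogate for the manual "maximum spread" placement).
Odd edges keep the cube symmetric about the central slice. The search
uses a 3D integral image, and is verified against exhaustive search on
small grids. Cortical segmentation itself is out of scope: the cortical
mask is an input, as is the juvenile flag (epiphyseal-plate detection is
a metadata question, not an image operation here).

`qc_filter()` applies the two study thresholds — relative resolution
TbTh/voxel ≥ 5 and absolute connectivity Conn ≥ 50 (exactly 50 passes;
"less than 50" fails) — and returns a record with all failing reasons.
The pipeline (`cmd_measure`) retains failed rows with
`qc_passed = FALSE` so the exclusion step is auditable; rows are dropped
only at the analysis stage.

## 3. The statistical model

`pgls()` fits y = Xβ + ε with ε ~ N(0, σ²V_λ), where V is the Brownian
matrix of shared root-to-ancestor path lengths of the (pruned) tree and
V_λ multiplies only the off-diagonal entries by Pagel's λ ∈ [0, 1]. λ is
clamped to [0, 1]: values outside the interval are uninterpretable as a
signal strength, though unconstrained implementations can wander there.
Estimation profiles λ by REML (default) or ML on a 1D optimize over
[0, 1] with the endpoints checked explicitly; coefficient inference is
conditional on the estimate (no λ-uncertainty propagation), with
t-statistics on n − p residual degrees of freedom. REML is the default
because it is the convention of the GLS tooling this analysis mirrors and
its λ estimates are less biased in small samples. With λ = 0 on an
ultrametric tree the fit reduces to ordinary least squares exactly
(coefficients, standard errors, p-values), which the tests assert to
machine precision; the test suite also checks agreement with an
independent GLS implementation (nlme + ape's corPagel correlation) to
numerical precision for both ML and REML.

The reported R² is computed in the whitened space against the
intercept-only GLS fit under the same covariance.

### Allometry classification

For trait tp with isometric exponent a_iso (its length dimension: 0 for
the dimensionless BV/TV and DA, 1 for TbTh and TbSp, −1 for BS/BV, −3
for ConnD — the constant-trabecular-geometry model), `allometry_test()`
fits log tp ~ log vl for the observed exponent a_obs and then the shifted
response log tp − a_iso·log vl on log vl, testing that slope against
zero. Because shifting the response by a linear function of the regressor
leaves the residuals (and hence the profile likelihood of λ) unchanged,
the shifted slope equals a_obs − a_iso algebraically — asserted to
machine precision in the tests. Classification: isometry if the deviation
p ≥ α (the boundary p = α folds into non-rejection), otherwise positive
or negative allometry by the sign of a_obs − a_iso. Natural logs are
applied internally; all values must be positive. In an exact
(zero-residual) fit the t statistic is 0/0 noise; a numerically zero
shifted slope with zero residual variance is reported as p = 1 (no
evidence of deviation).

### Lifestyle contrasts and multiple testing

`lifestyle_pairwise()` subsets the data to each pair of lifestyle
categories (each needs ≥ 3 species; smaller pairs are skipped with a
message), prunes the tree, fits log tp ~ log vl + lifestyle, and reports
the indicator coefficient (the size-adjusted contrast) with its raw
p-value. Benjamini–Hochberg correction (delegated to `stats::p.adjust`)
is applied within a declared family: per trait (six pairs — the default,
matching per-parameter reporting) or globally over all traits × pairs
(`lifestyle_analysis(family = "global")`). The family is a config switch
because the choice is genuinely underdetermined. Only corrected p-values
should be reported. Note that the BH step-up map is not idempotent;
the tests verify it against a direct evaluation of the step-up formula,
plus monotonicity and rank preservation.

`validate_size_proxy()` applies the same baseline-shift device to body
mass against vl with the isometric exponent 3.

### Calibration: what the tests show

The t-test is exactly calibrated when λ is known: the suite verifies OLS
identity at λ = 0, and the label-shuffled full-analysis check (no BH
discovery in ≥ 95 of 100 replicates, global family) is run at the
generating λ precisely to isolate the multiplicity logic from λ
estimation. When λ is estimated per fit, small subsets (two lifestyle
groups, ~27 species, three regressors) show a mildly inflated type-I
error — a known small-sample property of λ-PGLS shared with the
reference GLS implementation, to which this one agrees to machine
precision. The acceptance suite measures that level empirically over 500
exchangeable-null replicates at the study composition and reports it
against the 3–7% band; users contrasting small groups should prefer
estimating λ on the full dataset and fixing it in subset fits (the
`lambda` argument accepts a fixed value everywhere).

## 4. The synthetic generators

### Phantoms

`generate_phantom()` produces binary solids with analytic ground truth:
boxes (exact BV/TV, exact area), balls (BV/TV, TbTh = 2r, BS/BV = 3/r),
cylinders (TbTh = 2r; the measured area includes the end caps closed at
the grid boundary, so BS/BV = 2/r + 2/h), plate stacks (TbTh = plate
thickness, TbSp = gap; half-gap margins keep every plate interior),
rod lattices (Conn = 3L²(L−1) − L³ + 1 for L nodes per axis; spacing must
exceed 2·radius + 1 so rods cannot merge), and thresholded Gaussian
random fields. Geometry that does not fit the grid raises an error —
nothing is silently clipped. Phantom centres are placed on a voxel centre
so that diameters are realized symmetrically. Declared tolerances:
BV/TV ±0.02 absolute, TbTh/TbSp ±1 voxel, BS/BV 4–10% relative depending
on feature size, connectivity exact.

The random field smooths white noise with a separable Gaussian kernel
whose per-axis σ are the correlation lengths (edge variance damping from
the truncated kernel support is corrected analytically), then thresholds
at the empirical quantile of the target volume fraction — so the realized
BV/TV is exact by construction and anisotropy is controlled by the ratio
of correlation lengths.

### Comparative datasets

`simulate_comparative_dataset()` draws a pure-birth tree (ape::rphylo)
rescaled to unit height (branch-length units are arbitrary for GLS; the
original tree is time-calibrated, and rescaling fixes the scale), paints
lifestyles either on whole clades (greedy largest-clade-first painting,
mimicking the phylogenetic clustering of real lifestyle categories;
fossorial-like categories end up spread over several clades, as in
reality) or at random (the appropriate mode for null calibration),
partitions the tips into monophyletic genus labels, draws log vl
uniformly, and builds each trait as

log tp = intercept + a·log vl + lifestyle offset + ε,
ε ~ N(0, σ²·V_λ),

exporting traits on the raw scale so the analysis stage's log transform
is exercised. λ-rescaling of the residual covariance matches the
estimation model exactly, enabling λ-recovery tests; at λ = 0 the tip
residuals are distributionally identical to an iid simulator, which the
suite checks through replicate variances.

Defaults are fixed once as the emulated study conditions: 69 species in
33 genera; 27 arboreal, 19 fossorial, 15 semifossorial, 8 aerial
(clade-clustered); slopes (−0.193 DA, 0.166 BV/TV, 0.835 TbTh, 0.593
TbSp, −0.829 BS/BV, −2.138 ConnD); vl ∈ [0.5, 5] mm, a realistic range of
femoral-head VOI edges for rodents from ~16 g to ~3 kg; trait baselines
at vl = 1 mm chosen as typical rodent femoral-head values (BV/TV 0.4,
ConnD 50 mm⁻³, TbTh 0.10 mm, TbSp 0.25 mm, BS/BV 20 mm⁻¹, DA 0.65);
residual Brownian sd 0.2 log units at unit height with λ = 0.8 (strong
but incomplete phylogenetic signal, typical of morphometric traits); body
mass 60·vl³ g with lognormal sd 0.59, the noise level at which the
mass–vl regression attains r² ≈ 0.92 at the study size. The optional
mass column makes the size-proxy validation runnable out of the box.

What the generator does **not** emulate: measurement error in the
morphometry, intraspecific variation (one value per species),
correlation between traits beyond the shared vl term, bounded support for
DA (the log-linear model can exceed 1 in the upper tail), uneven
branch-length calibration, or missing data. Passing tests on these
simulations therefore demonstrate the correctness and calibration of the
*pipeline*, not the biological fidelity of any particular dataset.

## 5. Problem sizes and determinism

The shipped tests run phantoms at 16³–64³ with 128–256 MIL directions,
thickness oracles at ≤ 21×21×16, and Monte-Carlo blocks of 50–500
replicates at the study size (n = 69); the full suite and the acceptance
script complete in a few minutes on one core. All stochastic stages
(random fields, direction-set rotation, tree and trait simulation,
`simulate.pgls`) take explicit integer seeds, and fixed seeds give
bit-identical volumes, trees and trait tables; the pipeline commands
record their resolved configuration and the md5 checksum of every output
CSV header in a run log.

## 6. Known limitations

* Absolute agreement with any particular desktop tool's numbers is not
  claimed: the original tooling's threshold routine, MIL direction count
  and ray spacing, and boundary conventions are unpublished, so DA in
  particular is comparable in rank terms rather than absolutely.
* Thickness values carry the +1-voxel slab convention described above;
  compare only thicknesses computed under the same convention.
* λ-PGLS inference is conditional on the λ estimate; in small subsets
  the type-I error of coefficient tests is mildly inflated (see §3).
* The Euler-based Conn is meaningful only after purification; on
  unpurified volumes it mixes loops with components and cavities.
* Cortical segmentation, scan alignment, and epiphyseal-plate detection
  are inputs, not computations.
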