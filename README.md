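# trabecula

Trabecular bone morphometry from 3D micro-CT volumes, and phylogenetically
informed comparative statistics for the resulting parameters.

Comparative skeletal biologists quantify the spongy bone inside epiphyses
(e.g. the femoral head) with a small set of architectural parameters
measured on a cubic volume of interest (VOI), then ask how those parameters
scale with body size and whether they carry a signal of locomotor lifestyle
once size and shared ancestry are accounted for. This package implements
that entire workflow as tested, scriptable R code:

* **Morphometry** of a binary voxel volume:
  * bone volume fraction *BV/TV* (foreground voxel fraction);
  * connectivity density *ConnD* = (1 − Δχ)/V from the Euler
    characteristic Δχ of the structure (26-connected foreground,
    6-connected background), with absolute connectivity
    *Conn* = 1 − Δχ, the number of independent trabecular loops;
  * mean trabecular thickness *TbTh* and separation *TbSp*: the
    volume-weighted mean diameter of the greatest sphere fitting inside
    the bone (resp. marrow) phase at each voxel, by exact Euclidean
    distance transform and sphere propagation;
  * bone surface density *BS/BV* from a marching-tetrahedra triangulation
    of the phase boundary;
  * the mean-intercept-length (MIL) fabric tensor: an ellipsoid
    d′A d = 1/MIL(d)² is fit by least squares over quasi-uniform ray
    directions, giving the degree of anisotropy
    DA = 1 − (shortest/longest ellipsoid radius) ∈ [0, 1] and the main
    direction of trabeculae *MDT* (major axis, hemisphere-projected and
    mirrored for right femora).
* **VOI selection and quality control**: the central slice splitting the
  femoral head into proximal and distal halves, the largest cortex-free
  cube centred on it (edge length *vl*, which doubles as the body-size
  proxy), and the quality filter (relative resolution *TbTh*/voxel ≥ 5,
  *Conn* ≥ 50).
* **Comparative statistics**: `pgls()` — generalized least squares with
  Pagel's λ covariance (λ fixed, ML or REML), a classed model object with
  the usual `summary`/`coef`/`predict`/`simulate` methods. On top of it:
  allometric scaling tests of log *tp* ∝ *a*·log *vl* against the
  dimensional isometry exponents (*a*<sub>iso</sub> = 0 for *BV/TV* and
  *DA*, 1 for *TbTh*/*TbSp*, −1 for *BS/BV*, −3 for *ConnD*) via an exact
  baseline-shift device, pairwise lifestyle contrasts
  (*tp* ~ *vl* + lifestyle) with Benjamini–Hochberg correction, and a
  validation of *vl* as a mass proxy against *m* ∝ *vl*³.
* **Synthetic data**: geometric phantoms (box, ball, cylinder, plate
  stack, rod lattice, thresholded Gaussian random field) with analytic
  ground truth for every measurable parameter, and a comparative-dataset
  simulator (pure-birth phylogeny, clade-clustered lifestyles, Brownian
  λ-rescaled residuals) whose defaults emulate a 69-species, 33-genus,
  four-lifestyle sciuromorph study. Every stage of the pipeline is tested
  against these generators — no CT data needed.

## Worked example

```r
library(trabecula)

# a rod-lattice phantom with known connectivity
ph  <- generate_phantom(phantom_spec("rod_lattice", grid_shape = 64,
                                     voxel_size = 0.01,
                                     geometry = list(spacing = 16, radius = 2)))
vol <- purify(ph$volume)
summarize_morphometry(vol, side = "left", n_directions = 256)
#> Trabecular morphometry summary
#>   BV/TV   0.1013    Conn  81 (ConnD 308.99 mm^-3)
#>   TbTh    0.0484 mm  TbSp  0.1916 mm  BS/BV 87.51 mm^-1
#>   DA      0.012     MDT   (0.505, 0.756, 0.417)
#>   relative resolution 4.84 (TbTh / voxel)
ph$truth$conn
#> [1] 81
```

The 4×4×4-node lattice has cycle rank E − V + 1 = 3·16·3 − 64 + 1 = 81,
and the Euler-characteristic measurement returns exactly that; the
near-zero DA says the lattice has no preferred direction, and a relative
resolution below 5 would flag this synthetic scan for exclusion by
`qc_filter()`.

```r
sim <- simulate_comparative_dataset(simulation_spec(seed = 1))
allometry_table(sim$traits, sim$tree)
#>   trait a_iso  a_obs r_squared  p_value classification lambda
#> 1    DA     0 -0.221     0.640 1.61e-16          -allo  0.889
#> 2  BVTV     0  0.153     0.465 1.13e-10          +allo  0.539
#> 3  TbTh     1  0.818     0.936 1.83e-09          -allo  0.649
#> 4  TbSp     1  0.582     0.898 1.41e-26          -allo  0.502
#> 5  BSBV    -1 -0.854     0.963 9.03e-10          +allo  0.787
#> 6 ConnD    -3 -2.156     0.993 8.53e-48          +allo  0.555

summary(pgls(log(TbSp) ~ log(vl), sim$traits, sim$tree))
#>              Estimate Std. Error t value  Pr(>|t|)
#> (Intercept) -1.353190   0.053164 -25.453 < 2.2e-16 ***
#> log(vl)      0.582378   0.023974  24.292 < 2.2e-16 ***
#> lambda = 0.5021 (REML)   sigma^2 = 0.02644   R^2 = 0.8980
```

Each `a_obs` is the fitted log-log slope against the VOI edge length; the
p-value tests the deviation from the isometric exponent, and the
classification reports positive/negative allometry or isometry at
α = 0.05. Here the simulator planted slopes of −0.193 (*DA*), 0.166
(*BV/TV*), 0.835 (*TbTh*), 0.593 (*TbSp*), −0.829 (*BS/BV*) and −2.138
(*ConnD*), and every classification is recovered.

For shell use, `inst/scripts/trabec` wraps the three pipeline commands
(`trabec simulate|measure|analyze`) around `cmd_simulate()`,
`cmd_measure()` and `cmd_analyze()`, reading TIFF stacks (with JSON voxel
sidecars or `--voxel-size-um`), Newick trees and trait CSVs.

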