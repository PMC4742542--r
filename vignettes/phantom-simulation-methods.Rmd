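---
title: "Simulating multi-compartment diffusion MRI phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-compartment diffusion MRI phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiphantom)
```

## The signal model

`dwiphantom` simulates diffusion-weighted MRI from a voxel-wise
*microstructural model* that mixes three families of compartments:

* **Restricted** compartments: up to three fiber populations per voxel,
  each with a volume fraction $F_i \in [0,1]$ and a unit direction
  $\mathbf{V}_i$. Each population responds as an axially symmetric Gaussian
  tensor ("zeppelin") with axial diffusivity $\lambda_\parallel$ and radial
  diffusivity $\lambda_\perp$:
  $$A_\text{fiber}(\mathbf{g}, b) =
  \exp\!\left[-b\left(\lambda_\perp + (\lambda_\parallel - \lambda_\perp)
  (\mathbf{g} \cdot \mathbf{V}_i)^2\right)\right].$$
* **Hindered** compartments: isotropic mono-exponential decay
  $\exp(-b D_j)$ for white matter, cortical gray matter and deep gray
  matter fractions $T_j$.
* **Free** compartment: CSF, also mono-exponential with a fast
  diffusivity. An optional *abnormal tissue* compartment is carried
  structurally for pathology simulation; it has **no default diffusivity**
  and simulating a model that uses it without configuring one is an error.

The voxel signal is the convex combination

$$S(\mathbf{g}, b) = S_0 \left[\sum_i F_i\, A_\text{fiber}(\mathbf{g}, b)
  + \sum_j T_j\, e^{-b D_j}\right],$$

with per-voxel fractions normalized so that $\sum_i F_i + \sum_j T_j$ is 1
inside the head and 0 outside. Consequences used throughout the tests: the
$b=0$ signal equals $S_0$ in every in-head voxel, every diffusion-weighted
signal is bounded by the smallest and largest compartment attenuation, and
the signal is invariant under negation of any gradient direction.

### Default parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| $\lambda_\parallel$ | $2.2\cdot 10^{-3}$ | mm²/s | fiber kernel, axial |
| $\lambda_\perp$ | $0.2\cdot 10^{-3}$ | mm²/s | fiber kernel, radial |
| $D_{WM}$ | $2.0\cdot 10^{-4}$ | mm²/s | hindered white matter |
| $D_{cGM}$ | $7.0\cdot 10^{-4}$ | mm²/s | hindered cortical GM |
| $D_{dGM}$ | $9.0\cdot 10^{-4}$ | mm²/s | hindered deep GM |
| $D_{CSF}$ | $3.0\cdot 10^{-3}$ | mm²/s | free water |
| SNR | 30 | — | Rician noise level |
| $S_0$ | 1000 | a.u. | non-weighted intensity |
| scheme | 100 dirs, $b=1000$, 1 $b=0$ | s/mm² | acquisition protocol |

All are overridable (`fiber_kernel()`, `diffusivity_set()`, `noise_spec()`,
`run_config()`). $S_0$ is deliberately flat across tissues: no $T_2$
contrast is modeled, so the phantom's contrast is purely diffusion-driven
and every deviation from $S_0$ at $b=0$ would indicate a bug, which the
tests exploit.

## Assembling a model from raw ingredients

`assemble_model()` turns *raw* estimates — fiber fractions $F'_i$ as a
crossing-fiber model would produce, an FA map, tissue fractions $T'_j$ as a
segmentation would produce — into a final model. The combination rule is a
documented package convention (a stand-in; the literature this model family
comes from does not fix a unique rule, only that the dominant fiber fraction
is inferred from FA and that restricted compartments live inside white
matter):

1. $F_1 = \mathrm{clip}(FA \cdot T'_{WM},\, 0, 1)$ — the dominant fiber is
   inferred from anisotropy rather than the (noisy) raw $F'_1$;
2. $F_{2,3} = F'_{2,3} \cdot T'_{WM}$ — secondary fibers keep their raw
   ordering and ratio;
3. $\sum_i F_i$ is capped at $T'_{WM}$ by proportional rescaling;
4. $T_{WM} = T'_{WM} - \sum_i F_i$; other $T_j$ pass through;
5. fractions are normalized per voxel (`normalize_fractions()`).

This rule is permutation-covariant in the secondary fibers and idempotent
after normalization. Whether the residual should instead be left as a
signal-free compartment was an open design choice; full normalization was
picked because it makes the $b=0$ conservation property exact and testable.

## Synthetic microstructure fixtures

The generators in `make_fixture()` stand in for a model derived from real
data, reproducing its statistical structure rather than human anatomy:

* `single_voxel` — exact requested composition; the unit of closed-form
  signal tests.
* `crossing_slab` — two straight bundles crossing at a configurable angle
  (default 60°), flanked by single-fiber regions, hindered WM elsewhere.
  Default peak bundle fraction 0.45 so that the 2-bundle crossing region
  (0.45 + 0.45 + 0.10 WM) stays a valid mixture *without* renormalization
  distorting the angle geometry. Cross-sections use a cosine taper,
  mimicking the partial voluming of smoothed real fraction maps.
* `mini_brain` — concentric head: cortical-GM shell, WM interior, central
  CSF ventricle, two deep-GM nuclei, one straight bundle and one arc bundle
  whose tangent field varies smoothly (< 30° between neighbours). At the
  default 32³ grid the head occupies ~12.5k voxels, leaving ~20k empty
  background voxels — enough for stable background-noise statistics.

Default voxel size is 2 mm isotropic, of the order of typical dMRI
acquisitions. Generation is a pure function of the `fixture_spec` and seed (the
current generators are fully analytic, so the seed only matters for API
stability).

What the fixtures do **not** emulate: realistic tract geometry and
connectivity, $T_2$/coil-profile intensity variation, partial-volume mixing
beyond the taper profiles, fanning/kissing configurations, and spatially
varying SNR. Passing tests therefore validate the *simulator machinery*
(mixture model, noise, scheme, warping, estimators), not fidelity to any
particular brain.

## Gradient schemes

`generate_uniform_scheme()` distributes directions per shell by minimizing
the antipodally symmetric electrostatic energy
$\sum_{i<j} 1/\lVert\mathbf{v}_i-\mathbf{v}_j\rVert +
1/\lVert\mathbf{v}_i+\mathbf{v}_j\rVert$
with projected gradient descent on the sphere (backtracking line search,
default 20 seeded random restarts, stop when the relative energy change
falls below $10^{-8}$). For $n=6$ this reproduces the known icosahedral
optimum (minimal pairwise angle 63.4°); for the default $n=100$ the minimal
angle is ~14°, comfortably above the 10° the package treats as the floor
for "uniform coverage". Directions are stored in the **world frame**, the
same frame as the model's fiber directions — no image-axis flip is ever
applied when writing bval/bvec, which is the single most common silent
error in diffusion tooling and the reason the convention is fixed here.

## The FOD pathway

The default simulator evaluates the discrete per-fiber tensor sum, which is
closed-form and exactly testable. A second pathway mirrors how
deconvolution-based simulators represent fibers: the fiber compartments are
projected onto a fiber orientation distribution
$\mathrm{FOD} = \sum_i F_i\, \delta_{\pm\mathbf{V}_i}$ truncated at even
spherical-harmonic order $L$ (default 8, basis size 45), and the signal is
the spherical convolution with the kernel's rotational harmonics
($s_{lm} = \sqrt{4\pi/(2l+1)}\, k_l(b)\, c_{lm}$, $k_l$ by 64-point
Gauss–Legendre quadrature). Truncation at $L=8$ reproduces the discrete sum
within 2% RMS for 1–3 fibers at $b=1000$; the discrete path remains the
default precisely because it is exact.

## Noise

Rician noise is applied sample-wise as
$\sqrt{(S+n_1)^2 + n_2^2}$, $n_{1,2}\sim\mathcal{N}(0,\sigma^2)$, with
$\sigma = \overline{S_{b0,\text{in-brain}}}/\mathrm{SNR}$. "In-brain" means
voxels whose mean $b=0$ signal exceeds $S_0/2$, i.e. compartment-fraction
sum above 0.5 — the conventional foreground reference when no mask is
supplied. Background magnitudes are then Rayleigh with mean
$\sigma\sqrt{\pi/2}$, which is both a property test and the basis of the
`estimate_snr()` round-trip: at the default SNR 30 on the 32³ mini-brain
(~2·10⁴ background voxels) the estimator recovers the configured SNR within
a few percent.

## Susceptibility distortion

`make_synthetic_fieldmap()` builds a compactly supported Gaussian bump of
displacement along one phase-encode axis: peak `magnitude_mm` (default
6 mm) at the focus, decaying to exactly zero at `extent_mm` (default
20 mm; the raw Gaussian is shifted by its 1% floor and rescaled so the
warp is strictly local). The defaults are configurable and deliberately
moderate; they are not calibrated against any particular scanner.
`apply_distortion()` resamples each line along the phase-encode axis at
$x + d(x)$ (linear interpolation, edge clamping) and modulates intensity
by the 1D Jacobian $1 + \partial d/\partial x$ (central differences,
clipped at 0). Because that modulation is the exact change-of-variables
factor of the warp, total intensity is conserved up to discretization
error (< 1% in the tests) — pile-up and stretch behave like first-order
EPI physics. Distortion is applied *after* simulation, keeping the
microstructural ground truth identical between the reference and distorted
member of a pair.

## Self-validation estimators

* `fit_tensor_loglinear()` — unweighted OLS on $-\ln(S/S_0) = b\,
  \mathbf{g}^\top D \mathbf{g}$. Unweighted by design: it is exact on
  noise-free single-tensor data, which is what the acceptance checks need;
  no iterative/weighted refinement is attempted. Negative eigenvalues from
  noisy fits are clamped to zero for FA with a warning.
* `estimate_adc()` — slope through the origin of $-\ln(S/S_{b0})$ vs $b$.
* `estimate_snr()` — background-Rayleigh sigma plus foreground mean.

Round-trips are part of the test suite: a noise-free single-fiber voxel on
a 30-direction shell returns the generating eigenvalues to $10^{-9}$
mm²/s; pure CSF and pure WM voxels return their diffusivities to the same
precision.

## Numerical and design choices

* All attenuation math is double precision; outputs are never quantized.
* Stage seeds of `run_diffantomize()` derive from the master seed
  (scheme = seed, noise = seed + 1), making end-to-end runs byte-identical
  under a fixed configuration.
* Degenerate inputs: all-zero voxels pass through every stage as zeros;
  all-zero models cannot define a noise sigma and are rejected at the noise
  stage; rank-deficient tensor designs are an explicit estimation error.
* Problem sizes used by the tests and the acceptance script — 32³ mini-brain,
  101-volume default protocol, 24³/16² fixtures elsewhere — were chosen as
  the smallest grids that keep every statistical check well-conditioned
  (≥ 10⁴ background voxels for noise estimation, ≥ 10⁵ samples for the
  Rayleigh mean).

## Known limitations

* No restricted-geometry (cylinder radius) effects, water exchange,
  per-compartment $T_2$, eddy currents or motion.
* The hindered compartments are strictly mono-exponential; no kurtosis.
* The distortion model warps intensities only; it does not simulate the
  B0 field from susceptibility maps, and the default magnitude/extent are
  conventions, not measurements.
* BIDS output targets minimal dwi compliance (NIfTI + bval/bvec + JSON
  sidecar + dataset description), not the full specification surface.
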