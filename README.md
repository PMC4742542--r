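# dwiphantom

Simulation of whole-brain-style diffusion MRI (dMRI) phantoms with known
ground truth.

Validating tractography and connectomics pipelines needs data whose
microstructure is known exactly — something no acquisition can provide.
`dwiphantom` generates such data: it takes a voxel-wise microstructural
model (tissue fraction maps plus fiber populations with directions),
synthesizes the diffusion-weighted signal with a hindered/restricted/free
multi-compartment model, samples it on uniform-coverage gradient schemes,
degrades it with Rician noise, optionally warps it with a synthetic
susceptibility-distortion field, and writes a BIDS-layout dataset. It is
aimed at developers of dMRI processing methods who need unit- and
integration-test inputs, and at anyone studying the impact of sampling
schemes, noise or EPI distortion on downstream analysis.

## The model

Per voxel, up to three restricted fiber compartments (fractions `F_i`,
unit directions `V_i`), hindered isotropic compartments for white matter
and cortical/deep gray matter (`T_j`), and a free CSF compartment:

```
S(g, b) = S0 [ Σ_i F_i exp(-b (λ⊥ + (λ∥ − λ⊥)(g·V_i)²)) + Σ_j T_j exp(-b D_j) ]
```

with fractions forming a convex combination per voxel. Defaults:
λ∥ = 2.2·10⁻³, λ⊥ = 0.2·10⁻³ mm²/s for the fiber kernel;
D_WM = 2.0·10⁻⁴, D_cGM = 7.0·10⁻⁴, D_dGM = 9.0·10⁻⁴,
D_CSF = 3.0·10⁻³ mm²/s; SNR 30; a 100-direction single shell at
b = 1000 s/mm² plus one b = 0 volume. Every default is overridable. An
optional spherical-harmonic pathway represents the fibers as a fiber
orientation distribution (FOD) and synthesizes the signal by spherical
convolution with the kernel's rotational harmonics.

Because real microstructural inputs cannot be shipped, the package includes
synthetic fixtures with the same statistical structure: a single voxel with
an exact composition, a slab with two bundles crossing at a configurable
angle, and a "mini-brain" (cortical shell, WM interior, CSF ventricle, deep
gray nuclei, one straight and one arc-shaped bundle).

## Worked example

```r
library(dwiphantom)

cfg <- run_config(
  fixture = fixture_spec("mini_brain", shape = c(32, 32, 32)),
  snr = 30, seed = 42L, out_dir = "phantom"
)
manifest <- run_diffantomize(cfg)
manifest$scheme
#> <gradient_scheme> 101 volumes: 1 b=0, shells at b = 1000 (n = 100)
manifest$model
#> <microstructural_model>
#> <grid_geometry> 32 x 32 x 32 voxels, 2 x 2 x 2 mm
#>   12568/32768 voxels in head (fraction sum > 0); tissue maps present: cGM, dGM, WM, CSF; fibers present: 1, 2
manifest$report
#> <evaluation_report>
#>   snr: estimate 29.9289 vs truth 30 (rel err 0.00237) PASS
```

The run writes `phantom/sub-01/dwi/sub-01_dwi.{nii.gz,bval,bvec,json}` plus
`dataset_description.json`; the JSON sidecar carries the full simulation
provenance (seed, SNR, kernel, diffusivities), so any dataset can be
regenerated from its own metadata. The evaluation report shows the SNR
estimated back from the simulated data's background (Rayleigh statistics):
29.93 against the configured 30, a 0.2% error.

Closed-form checks work at the single-voxel level:

```r
sch <- manifest$scheme
sig <- voxel_signal(rep(0, 5), 1, matrix(c(0, 0, 1), 1), sch, s0 = 1)
tf  <- fit_tensor_loglinear(sig, sch, s0 = 1)
tf$eigenvalues
#> [1] 0.0022 0.0002 0.0002
fa(tf$eigenvalues)
#> [1] 0.9016696
```

The log-linear tensor fit recovers the generating kernel eigenvalues
exactly on noise-free data (FA 0.90 for the default kernel).

A command-line wrapper over the same functions is installed at
`inst/cli/dwiphantom.R` with subcommands `fixture`, `scheme`, `simulate`,
`distort`, `evaluate` and `run`.

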