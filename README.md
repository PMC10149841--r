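# isqsm — incomplete-spectrum dipole inversion for QSM

Quantitative susceptibility mapping (QSM) estimates tissue magnetic
susceptibility χ (in ppm) from the local magnetic field shift b measured with
gradient-echo MRI phase. In the frequency domain the two are related through
the unit dipole kernel

    D(k) = 1/3 − (k·ĥ)² / |k|²,        b = F⁻¹ D F χ,

with ĥ the main-field (B0) direction. D vanishes on a cone at the magic angle
((k·ĥ)²/|k|² = 1/3), so direct deconvolution χ = F⁻¹ D⁻¹ F b is ill posed and
produces streaking artifacts.

**isqsm** removes the ill-posed region instead of regularizing through it.
A band limit S_k keeps only the well-conditioned frequencies (|D| > t_well),
and the binary brain mask S_χ — which QSM pipelines already have from
background-field removal, and which satisfies S_χ χ = χ — restores
well-posedness: a bounded object can be reconstructed from an incomplete
spectrum. With ν = D⁻¹ F b the "input data" on the band limit, the package
solves the space-limited, band-limited normal equation

    AᴴA χ = Aᴴ ν,        A = S_k F S_χ,

by matrix-free conjugate-gradient least squares (CGLS) from a zero start,
which on rank-deficient systems yields the minimum-norm least-squares
solution. No sparsity prior or tuning beyond t_well is needed.

The package is written for QSM researchers who want a transparent, fully
tested reference implementation of this reconstruction together with the
pieces needed to evaluate it:

- `dipoleKernel()`, `forwardField()` — the dipole forward model;
- `bandLimit()`, `morphMask()`, `applySupport()` — frequency- and image-space
  supports, spherical-kernel mask erosion/dilation;
- `isReconstruct()`, `isReconstructRegularized()`, `cglsSolve()` — the core
  inversion, optionally with an added λ‖Ψχ‖₁ wavelet penalty (Daubechies-2)
  solved by a monotone proximal-gradient scheme;
- `tkdReconstruct()` (thresholded k-space division, δ = 2/3, with
  point-spread-function scaling correction) and `csReconstruct()`
  (compressed sensing sharing the same band limit) as comparators;
- `xsim()` (susceptibility-tuned SSIM, K1 = 0.01, K2 = 0.001), `psnr()`,
  `roiStats()` — evaluation metrics and ROI tables;
- `makePhantom()`, `simulateField()` — a synthetic brain phantom (deep
  grey-matter nuclei, tissue compartments, a focal calcification) with a
  forward-simulated noisy field, so everything is testable without data
  downloads;
- `readVolume()`, `writeVolume()`, `runExperiment()` and a CLI
  (`inst/scripts/isqsm.R`) for NIfTI-based pipelines.

## Worked example

```r
library(isqsm)

ph  <- makePhantom(shape = 32, seed = 7)      # ground truth, mask, ROI labels
ph  <- simulateField(ph, snr = 100)           # noisy masked local field (ppm)
D   <- dipoleKernel(voxelGrid(ph@chiTruth))
rec <- isReconstruct(ph@field, ph@mask, D, solverConfig(tWell = 0.25))
rec
#> ReconResult: 100 iterations, not converged
#>   final residual: 5.072
#> SusceptibilityMap: 32 x 32 x 32 voxels [ppm]
#>   range: [-0.8902, 0.1441]
#> VolumeGrid: 32 x 32 x 32 voxels, 1 x 1 x 1 mm, B0 dir ( 0, 0, 1 )

psnr(reconChi(rec), ph@chiTruth, ph@mask)     # 37.04 dB
xsim(reconChi(rec), ph@chiTruth, ph@mask)     # 0.762
head(roiStats(reconChi(rec), ph), 3)
#>   label            name       mean          se  n
#> 1     1         caudate 0.04481668 0.004330425 74
#> 2     2         putamen 0.08064758 0.002413566 72
#> 3     3 globus_pallidus 0.11890063 0.003738616 24
```

The residual norm ‖Aχᵢ − S_kν‖ decreases monotonically over the CGLS
iterations ("not converged" only means the iteration cap was reached before
the 1e-6 relative tolerance; quality plateaus much earlier). The ROI means
recover the configured ground-truth values (caudate 0.06, putamen 0.09,
globus pallidus 0.15 ppm) up to the expected slight underestimation of a
band-limited reconstruction. On the same data, PSF-corrected TKD reaches
32.7 dB / XSIM 0.63 — the incomplete-spectrum reconstruction is more accurate
and shows weaker streaking.

The same operations are available from the shell:

    Rscript inst/scripts/isqsm.R phantom --size 64 --seed 7 --snr 100 -o out/
    Rscript inst/scripts/isqsm.R recon --method is --twell 0.25 \
        --field out/field.nii.gz --mask out/mask.nii.gz -o out/rec
    Rscript inst/scripts/isqsm.R metrics --truth out/chi_gt.nii.gz \
        --recon out/rec/chi.nii.gz --mask out/mask.nii.gz -o out/report.json

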