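---
title: "Incomplete-spectrum dipole inversion: model, choices and limitations"
author: "isqsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incomplete-spectrum dipole inversion: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(isqsm)
```

## The inverse problem

Tissue magnetic susceptibility χ (ppm) perturbs the main field B0; after
phase unwrapping and background-field removal, the measured local field
shift b (ppm) is the convolution of χ with the unit dipole response. In the
frequency domain,

$$ b = F^{-1} D F \chi, \qquad D(\mathbf k) = \tfrac13 - \frac{(\mathbf k\cdot\hat h)^2}{|\mathbf k|^2}, $$

with $\hat h$ the B0 direction. $D$ ranges over $[-2/3, 1/3]$ and vanishes
on the magic-angle cone $(\mathbf k\cdot\hat h)^2/|\mathbf k|^2 = 1/3$, so
the deconvolution $\chi = F^{-1}D^{-1}Fb$ is ill posed there; noise near the
cone becomes the familiar streaking artifacts of QSM.

The incomplete-spectrum (IS) approach discards the ill-conditioned data
instead of rescaling or penalizing them. Two binary supports define the
problem:

- the **band limit** $S_k$, retaining frequencies with $|D| > t_{well}$
  (strict inequality; at the maximum $t_{well} = \max|D| = 2/3$ the support
  is empty). There is no transition band: a frequency is either used
  verbatim or discarded.
- the **image support** (mask) $S_\chi$, which must contain the
  susceptibility sources: $S_\chi\chi = \chi$. In brain QSM this is the
  brain mask already required by mask-based background-field removal, which
  is precisely what guarantees the assumption holds for the field it
  outputs.

With $\nu = D^{-1}Fb$ on the band limit ("the input data"), the
reconstruction solves

$$ A^H A \chi = A^H \nu, \qquad A = S_k F S_\chi, $$

by conjugate-gradient least squares (CGLS) with matrix-free operators (two
FFTs per iteration). Reconstructing a support-limited object from an
incomplete spectrum is a well-posed problem, so no sparsity prior is needed;
the mask also pins down the volume mean that the (always excluded, $D=0$)
zero frequency cannot supply.

## Numerical and design choices

**Fourier convention.** The forward transform is the unnormalised FFT and
the inverse is its exact inverse ($F^{-1}F = I$). The least-squares
minimiser is invariant to a common scaling of $A$ and $\nu$, so the CGLS
path uses unnormalised transforms; the proximal solvers use the unitary
scaling $F/\sqrt N$ so that $\|A\|\le 1$ and the regularization weight λ has
the scale of the formulation in which $F^H = F^{-1}$.

**Discrete kernel.** The continuous (Salomir / Marques–Bowtell) kernel
expression is evaluated at the discrete frequencies
$k_i = n_i/(N_i\Delta_i)$, so anisotropic voxel sizes enter through
$\Delta_i$; the value at $k=0$, where the expression is undefined, is set to
0 by convention (simulated fields then have zero mean over the periodic
domain). Float noise at the extreme values is clamped to $[-2/3, 1/3]$ so
the analytic bounds hold exactly. Whether a discrete-Laplacian kernel
variant would behave differently is untested here; the continuous form is
the standard choice.

**CGLS.** Zero initialization guarantees the iterates remain in the row
space of $A$, so on rank-deficient systems the solver converges to the
minimum-norm least-squares solution — the property the dense-oracle tests
pin down to 1e-6 relative against an explicit pseudoinverse. Stopping is on
the relative data residual ($\|r\|/\|\nu\|\le$ tol, default 1e-6, cap 100
iterations) or on the normal-equation residual $\|A^Hr\|$, which is the
correct optimality measure on inconsistent systems; a step that fails to
reduce the residual (the numerical floor) is undone and iteration stops.
The per-iteration residual history is recorded and is non-increasing by
construction.

**Regularized variant.** The compressed-sensing-style objective
$\|S_k\nu - S_kFS_\chi\chi\|^2 + \lambda\|\Psi\chi\|_1$ is minimised by a
monotone proximal-gradient scheme (ISTA with backtracking; initial step
$1/(2\|A\|^2) = 0.5$ in unitary scaling). Ψ is a 3D orthonormal Daubechies-2
DWT with 3 levels. Periodization was chosen over symmetric extension so the
transform is exactly orthonormal and soft thresholding of the coefficients
is the *exact* proximal operator — the monotonicity guarantee of the scheme
rests on that. Shapes not divisible by $2^{levels}$ fall back to the largest
compatible depth (odd shapes: plain image-space soft thresholding, the
depth-0 limit) rather than padding, which would have made the prox
approximate at the boundary. The baseline `csReconstruct()` minimises the
same objective without $S_\chi$ in the data term; with an all-ones mask the
two solvers coincide iterate for iterate, which the tests assert. As λ grows
the two reconstructions approach each other and collapse to the same answer
once shrinkage dominates — the λ ladder in the acceptance tests expresses
that claim with λ quoted as fractions of the computable kill threshold
$\lambda_{max} = \|\Psi(2A^H\nu)\|_\infty$ (the subgradient condition for
the zero solution) instead of magic constants.

**TKD baseline.** Thresholded k-space division replaces $D$ by
$\mathrm{sign}(D)\,\delta$ wherever $|D| < \delta$ (sign(0) := +1, covering
the cone and DC), with δ = 2/3 as the default. Thresholding rescales part of
the spectrum and underestimates susceptibility; the correction implemented
here is the simplest global form — dividing by the scalar central value of
the effective point-spread function, $c = \mathrm{mean}_{k\neq 0}(D/D_\delta)$.
The DC term is excluded from the mean so that $c = 1$ exactly when no
nonzero frequency is thresholded; richer (deconvolving) PSF corrections
exist and the scalar can be swapped out. TKD is linear in the field, and
toggling the correction changes the output only by a global positive scalar;
both properties are tested.

**Metrics.** XSIM is the SSIM-family index with stabilisation constants
$C_i = (K_iL)^2$, $K_1 = 0.01$, $K_2 = 0.001$ (the susceptibility-tuned
values), local moments from a 3D Gaussian window (7³ taps, σ = 1.5 voxels —
the common SSIM practice; the challenge implementation's window is not
documented, so absolute XSIM values may differ slightly from published
tables), averaged over the ROI. Windows overhanging the volume edge are
renormalised by the in-volume weight mass so constant maps score exactly 1.
The dynamic range $L$ defaults to the combined max − min of the two maps
within the ROI, which keeps the index symmetric in its arguments (using the
reference alone would break the symmetry property the tests assert); a fixed
$L$ can be supplied. PSNR uses peak = max − min of the reference within the
ROI — the peak convention is a package decision, as the cited definition
admits variants. ROI tables report mean, standard error (SD/√n) and voxel
count per label.

## The synthetic phantom

`makePhantom()` builds a piecewise-constant, brain-like susceptibility
distribution on an ellipsoidal head: bilateral ellipsoidal deep grey-matter
nuclei (globus pallidus 0.15, substantia nigra 0.12, red nucleus 0.10,
putamen 0.09, caudate 0.06, thalamus 0.02 ppm), surrounding tissue
compartments (peripheral grey matter +0.02, deep white matter −0.03, CSF
ventricles −0.01 ppm), and one small spherical calcification at −1 ppm whose
streaking stresses the inversion. These values are plausible
order-of-magnitude settings spanning roughly −1 to +0.15 ppm; they are
generator defaults, **not** literature measurements. The tissue compartments
matter for evaluation: an early flat-background design made the truth's
local variance zero almost everywhere, which degenerates any SSIM-family
metric (every reconstruction error dominates the variance term), so the
phantom carries piecewise-constant structure throughout the head as real
brains do.

`simulateField()` applies the dipole forward model and adds seeded Gaussian
noise with σ = rms(field within mask)/SNR, then masks the field — the same
masking rule the reconstruction assumes. The default study conditions used
by the tests and the acceptance script are a 64³ isotropic 1 mm grid at
SNR 100. What the phantom does *not* emulate: realistic anatomy and
microstructure, within-tissue texture, phase-derived (complex, Rician-type)
noise, or any specific acquisition's SNR definition. Passing tests on this
phantom demonstrate the algorithmic claims (solver correctness, method
ordering, support behavior), not in-vivo image quality.

## Problem sizes and runtime

The test suite runs the full method comparison at 64³ (about 100 CGLS
iterations, two 64³ FFTs each), the regularization-equivalence ladder at
32³, and the dense-oracle property tests on ≤ 10³ grids where an explicit
system matrix (a few hundred columns) is tractable; the whole suite
completes in well under a minute on a laptop-class core, and
`scripts/acceptance.R` in about one. These sizes were chosen as the smallest
at which each claim is meaningfully exercised — the 64³ comparison keeps the
calcification small relative to the head, and the oracle grids keep the
pseudoinverse exact.

## Known limitations

- The band-limit sweep optimum depends on the data: on this phantom the
  XSIM-optimal t_well lands at the low end of the sweep, whereas richer,
  noisier data favor larger thresholds. The sweep endpoints are
  configuration, not constants.
- CGLS on noisy data shows semiconvergence (late iterations fit amplified
  noise near the band edge); the iteration cap acts as mild implicit
  regularization, and the paper-style stopping rule is unspecified, so both
  tolerance and cap are exposed in `solverConfig()`.
- Single-orientation, scalar susceptibility only; oblique acquisitions are
  handled through the B0 direction vector, not affine resampling. No
  brain-extraction, unwrapping or background-field removal is included —
  inputs are assumed to be preprocessed local field maps with a consistent
  mask.
- The ℓ1-regularized variants inherit the usual caveat that band-limiting by
  kernel threshold produces correlated (not incoherent) artifacts, so the
  compressed-sensing assumptions are only approximately met; the
  unregularized IS reconstruction is the method's primary form.
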