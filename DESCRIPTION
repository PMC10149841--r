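Package: isqsm
Title: Incomplete-Spectrum Dipole Inversion for Quantitative Susceptibility Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs magnetic susceptibility maps from masked local field
    maps by solving a space-limited, band-limited Fourier normal equation with
    conjugate-gradient least squares (incomplete-spectrum QSM). Includes
    thresholded k-space division with point-spread-function correction and
    wavelet-regularized compressed-sensing baselines, susceptibility-tuned
    structural similarity (XSIM) and peak signal-to-noise ratio metrics,
    region-of-interest statistics, a synthetic brain phantom generator with a
    forward field simulator, and NIfTI input/output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, RNifti, jsonlite, utils
Suggests: testthat (>= 3.0.0), MASS, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
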