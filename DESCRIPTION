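Package: octdespeckle
Title: Speckle Reduction for Volumetric OCT in the 3D Dual-Tree Complex
    Wavelet Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian speckle reduction for three-dimensional optical
    coherence tomography (OCT) volumes.  Implements a 3D dual-tree complex
    wavelet transform with 28 oriented subbands per scale, a locally
    parameterized bivariate Gaussian mixture prior on parent-child
    coefficient pairs fitted by a windowed EM algorithm, and closed-form
    minimum mean-square-error shrinkage functions for additive Gaussian and
    two-sided Rayleigh wavelet-domain noise, under homomorphic (log-domain)
    and non-homomorphic speckle models.  Anisotropic per-voxel estimation
    windows are selected by local polynomial approximation with the
    intersection-of-confidence-intervals rule (LPA-ICI).  Includes a seeded
    retina-like phantom generator, MSNR/CNR/PSNR evaluation over regions of
    interest, and TIFF/NIfTI volume input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    pracma,
    jsonlite,
    yaml,
    tiff,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
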