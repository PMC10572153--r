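Package: ctiq
Title: Task-Based Image Quality Assessment for CT: Noise Power Spectrum,
    Task Transfer Function and Model-Observer Detectability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for task-based image quality assessment of computed
    tomography (CT) image stacks in Hounsfield units, as practiced on
    multi-diameter image-quality phantoms. Implements noise power spectrum
    (NPS) estimation from homogeneous regions of interest with polynomial
    detrending and radial averaging, the circular-edge technique for the
    task-based transfer function (TTF) of a contrast insert (edge spread
    function, line spread function, f50), and the non-prewhitening model
    observer with an eye filter (NPWE) detectability index d-prime for
    circular Gaussian-profile lesions under a specified viewing geometry.
    A synthetic phantom-image generator produces uniform-section stacks
    with stationary correlated noise of prescribed radial power spectrum,
    a circular contrast insert and Gaussian edge blur, so every estimator
    can be validated by parameter recovery. A study pipeline orchestrates
    datasets by section diameter and virtual monoenergetic energy level
    and summarises metrics as percent-difference means and standard
    deviations. Minimal DICOM series and portable array readers/writers
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'ctiq-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'noise-model.R'
    'phantom.R'
    'nps.R'
    'ttf.R'
    'detectability.R'
    'study.R'
    'io-dicom.R'
    'io-array.R'
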