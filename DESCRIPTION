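Package: mwibreast
Title: Microwave Breast Imaging: Huygens Reconstruction, PCNN Segmentation
    and Quartile Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for multi-bistatic microwave breast imaging.
    Simulates complex S21 scattering acquisitions over an azimuthal
    receiver ring, reconstructs coronal intensity maps by Huygens-principle
    back-propagation with conductivity-weighted complex wavenumbers and
    attenuation compensation, segments the maps adaptively with a
    simplified pulse-coupled neural network (PCNN), localizes lesion
    regions into upper/lower zones, and separates malignant-finding
    breasts from no-finding/benign breasts with a non-parametric
    quartile-boxplot threshold.  Includes a synthetic phantom and cohort
    generator so the full pipeline is testable without clinical
    recordings, plus confusion-matrix based evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
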