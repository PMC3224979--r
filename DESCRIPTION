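Package: echolv
Title: Left-Ventricle Segmentation and Area Variation Curves for Dynamic
    2D Echocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic segmentation of the left-ventricular cavity in
    apical four-chamber 2D echocardiography sequences over a complete
    cardiac cycle.  Implements ECG-synchronized temporal averaging,
    shift-invariant wavelet denoising, Laplacian-of-Gaussian edge
    enhancement, morphological smoothing, homotopy modification (minima
    imposition), marker-controlled watershed segmentation with an
    adaptively tracked atrioventricular barrier, and an
    intensity-threshold contour correction step.  From the per-frame
    cavity masks the package builds the area variation curve (AVC) and
    the area variation fraction (AVF), computes four
    segmentation-agreement metrics (root mean squared contour distance,
    cross-correlation coefficient, percent area error, and edge error
    sum), and provides a synthetic beating-heart phantom with ground
    truth for end-to-end validation, including an automated analogue of
    an intra-/inter-operator barrier-placement variability experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
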