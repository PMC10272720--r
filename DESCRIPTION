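Package: AngioTIC
Title: Time-Intensity-Curve Velocimetry for Angiographic Image Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating blood-flow velocity from digital
    subtraction angiography (DSA) cine sequences with the time-intensity-curve
    (TIC) peak-shift method. The package reads multi-frame DICOM files or
    plain image stacks, segments the contrast-filled vessel from temporal
    intensity changes, extracts and smooths a one-pixel centerline by
    morphological thinning, places regions of interest along the centerline,
    builds area-averaged time-intensity curves, detects contrast peaks, and
    converts per-peak frame shifts into velocities (mm/s), velocity retention
    ratios, and full-width-at-half-maximum vessel diameters with stent-induced
    expansion rates. A synthetic angiographic phantom generator with ground
    truth supports validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    signal,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'dicom.R'
    'geometry.R'
    'phantom.R'
    'pipeline.R'
    'sequence-io.R'
    'thinning.R'
    'tic.R'
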