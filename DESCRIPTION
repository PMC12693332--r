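Package: ScarQuant
Title: Myocardial Scar Detection and Quantification on Co-Registered
    Bright- and Black-Blood LGE Short-Axis MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for joint bright-blood (anatomy) and
    black-blood (scar contrast) late gadolinium enhancement cardiac MRI.
    Given co-registered short-axis stacks, left-ventricular endo/epicardial
    contours and right-ventricular insertion landmarks, the package detects
    myocardial scar by multi-level Otsu thresholding or seeded adaptive
    region growing, and quantifies it with an AHA 16-segment infarct-size
    bullseye, a 100-chord transmurality bullseye, and global volume, mass
    and extent metrics assembled into a clinical report. A fully synthetic
    phantom generator with analytic ground truth supports end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry-utils.R'
    'imaging-io.R'
    'phantom.R'
    'preprocess.R'
    'scar-detect.R'
    'quantify.R'
    'report.R'
    'pipeline.R'
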