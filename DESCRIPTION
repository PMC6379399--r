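Package: sosct
Title: Quantitative CT Volumetry of Hepatic Lesions in Sinusoidal
    Obstruction Syndrome
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies hepatic lesion burden on contrast-enhanced CT in
    pyrrolizidine-alkaloid-induced sinusoidal obstruction syndrome (PA-SOS).
    Volumes in Hounsfield units are denoised by Perona-Malik anisotropic
    diffusion, the liver and its hypoattenuating lesions are extracted by
    threshold-constrained seeded region growing (with a lesion interval
    derived by merging the low-density and enhancement thresholds), and
    physical volumes and the lesion-to-liver volume Ratio are computed per
    patient. A statistical layer provides descriptive statistics, one-way
    ANOVA from raw data or from per-group summary statistics, Fisher LSD
    post-hoc comparisons and Pearson correlation, relating the Ratio to
    clinical severity and outcome. A synthetic phantom and cohort generator
    makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    oro.nifti,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'diffusion.R'
    'io.R'
    'stats.R'
    'volumetry.R'
    'segmentation.R'
    'pipeline.R'
    'sosct-package.R'
    'synthetic.R'
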