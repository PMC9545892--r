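Package: shapetexture
Title: Shape and Texture Analysis of Category-Selective Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how shape (spatial envelope) and texture
    (orientation and spatial-frequency content) properties of images relate to
    responses in category-selective visual cortex (fusiform face area,
    parahippocampal place area). Implements Fourier-domain orientation and
    spatial-frequency stimulus filters, shape and texture variants of the GIST
    image descriptor built from a 64-filter log-Gabor bank, leave-one-image-out
    condition similarity matrices, correlation-based multivariate pattern
    analysis with leave-one-participant-out cross-validation and
    representational-similarity regression, flood-fill region-of-interest
    definition on statistical maps, and block-design fMR-adaptation analysis
    with repeated-measures ANOVA and Benjamini-Hochberg corrected contrasts.
    Synthetic generators for stimuli, condition voxel patterns, block-design
    BOLD time series and statistical maps make the full pipeline testable
    end to end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    tiff
Config/testthat/edition: 3
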