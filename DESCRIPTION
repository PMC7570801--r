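Package: slendervol
Title: Single Top-View Volume and Mass Estimation for Slender Produce
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the volume, mass and commercial size class of slender
    axi-symmetric fruit and vegetables (carrot, cucumber and similar) from a
    single calibrated top-view image.  The silhouette is segmented from the
    background, enclosed in a rotated minimum-area bounding box, sliced into
    equal parallel sections, and the solid is reconstructed as two elliptical
    end caps plus a stack of chopped-pyramid (frustum) slices with elliptical
    cross-sections.  Includes the classical one- and two-view disk-method and
    multiple-linear-regression baselines, agreement statistics (Bland-Altman
    limits, paired t-test, R squared), size-class confusion matrices, and a
    synthetic silhouette generator with closed-form ground-truth volumes for
    desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
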