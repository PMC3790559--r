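Package: esmorph
Title: Eigenshape Morphometrics and Phylogenetic Comparative Analysis of
    Bone Outlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outline-based geometric morphometrics and phylogenetic
    comparative analysis for closed two-dimensional bone outlines, built
    around the opercle-shape workflow used in studies of fish adaptive
    radiations. Reads multi-specimen TPS outline files, resamples outlines
    to equidistant semilandmarks, converts them to the Zahn-Roskies
    tangent-angle (phi-star) shape function, and extracts orthogonal
    eigenshape axes by singular value decomposition, with broken-stick
    axis selection and shape-model reconstruction. Downstream comparative
    tools include phylomorphospace projection with maximum-likelihood
    ancestral states, disparity-through-time curves with a Brownian-motion
    simulation envelope and the morphological disparity index (MDI),
    maximum-likelihood fitting and AICc/Akaike-weight comparison of
    Brownian-motion, Ornstein-Uhlenbeck and early-burst trait models,
    phylogenetic generalized least squares regression against stable
    isotope ecology proxies, per-axis ANOVA, canonical variates analysis
    with Wilks' Lambda, and measurement-error repeatability. A synthetic
    data generator produces trees, traits, outlines and isotope tables
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
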