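Package: duplexish
Title: Quantification of Duplex Chromogenic RNA In Situ Hybridization Images
Version: 0.1.0
Authors@R: person("Maintainer", "Duplexish", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of duplex chromogenic RNA in situ
    hybridization (RNA-ISH) micrographs in which a target transcript is
    labelled with a blue chromogen and a housekeeping transcript with fast
    red over a hematoxylin counterstain. Chromogens are separated by
    colour-vision-deficiency (tritanope) simulation and CIELAB a* channel
    extraction; dots are enumerated with an undecimated B3-spline a-trous
    wavelet spot detector restricted to an epithelial region of interest;
    per-sample target/housekeeping dot-count ratios are aggregated with
    quality-control exclusions. The package also provides the cohort
    statistics layer (tie-corrected Kruskal-Wallis, exact and approximate
    Mann-Whitney U, Bonferroni post-hoc, and exact Fisher and
    Fisher-Freeman-Halton contingency tests by enumeration) and a synthetic
    image and cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
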