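Package: habelect
Title: Use-Versus-Availability Habitat Electivity and Niche Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quadrat-based microhabitat selection analysis for
    presence/pseudo-absence survey designs. Computes Vanderploeg (Wi) and
    Scavia (Ei) electivity indices with the five-level preference
    classification, Levins niche breadth and directional niche overlap with a
    group-label resampling significance test, and the univariate seasonal and
    sexual comparison battery (Mann-Whitney U with tie-corrected normal
    approximation, chi-square tests, and normality/homogeneity gating to
    one-way ANOVA). Includes a synthetic survey-data generator with known
    group-specific selection structure and a pseudo-absence sampler with a
    minimum-distance exclusion radius, so the whole pipeline can be exercised
    and validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
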