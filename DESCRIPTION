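Package: resight
Title: Photo-Identification Resight Analysis and Migration Detection Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing photo-identification sighting catalogues of
    individually recognisable marine megafauna at seasonal aggregation sites.
    Computes resight statistics (yearly unique counts, new-versus-resight
    proportions, years-observed distributions, consecutive-year runs, sex
    composition, cross-site matches and implied minimum travel speeds),
    permutational one-way ANOVA on Euclidean distances with post-hoc pairwise
    tests, pooled chi-square contingency tests on years-returned
    distributions, and a Monte Carlo power simulation that estimates how many
    individuals must be identified yearly at a sink aggregation to detect a
    given migration rate from a source aggregation. Includes a synthetic
    sighting-catalogue generator with known migration ground truth and an
    agent-based sampling oracle for validating the power model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
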