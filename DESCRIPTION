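Package: seedtrends
Title: Germination Time-Course Indices, Nonparametric Treatment Comparison,
    and Multi-Temporal Climate and Land-Cover Change Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for seed-germination trials of narrow-endemic
    Mediterranean plants and for the environmental pressures acting on their
    range. Computes the classical germination time-course statistics (final
    germination percentage, mean germination time and rate, first and last day
    of germination, interpolated median germination time, coefficients of
    variation and velocity, day-weighted germination rate and germination
    indices) from per-dish daily count schedules; compares treatments with
    rank-based tests (Wilcoxon signed ranks, Mann-Whitney U, Friedman,
    Kruskal-Wallis) using exact permutation p-values for small samples,
    Bonferroni-adapted pairwise contrasts and compact letter displays;
    summarises annual temperature and rainfall series as windowed linear
    trends; and performs multi-temporal land-cover composition and change
    accounting over class-area tables (CORINE Land Cover level III, with
    classification crosswalks) and desertification-sensitivity class shares.
    Includes seeded synthetic-data generators for germination trials, climate
    series and land-cover tables so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
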