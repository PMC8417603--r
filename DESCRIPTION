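Package: ineqconc
Title: Statistical Inequality and Concentration Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Descriptive distributional statistics of inequality and
    concentration for non-negative data: the Lorenz curve and the
    rank-based concentration curve; deviation-model indices (Gini,
    corrected Gini, Hoover, corrected Hoover, Rosenbluth); combinatorial
    indices (Herfindahl-Hirschman, Simpson, Gini-Simpson, inverse
    Simpson); entropy-model indices (Shannon with selectable logarithm
    base, generalized entropy with its Theil and mean-log-deviation
    special cases); the Atkinson social-welfare index with its
    equally-distributed-equivalent standard; and distributional tail
    ratios (Palma, S80:S20, percentile ratios). Includes delimited-text
    input, a per-component distribution table, a measure catalog with
    theoretical limits, curve export, seeded fixture generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
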