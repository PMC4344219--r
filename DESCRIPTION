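Package: cvregion
Title: Uncertainty-Constrained Regionalization of Survey Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges contiguous small survey reporting areas (for example census
    tracts publishing estimates with margins of error) into the maximum number of
    internally homogeneous regions whose estimates all meet a user-specified
    coefficient-of-variation (CV) target. Implements full margin-of-error
    propagation for counts, proportions and ratio means; the standard survey
    preprocessing rules (zero-household exclusion, zero-estimate MOE reset,
    z-scoring, variance-weighted principal components, the small-proportion CV
    exemption); a two-phase max-p heuristic (randomized seeded region growth with
    leftover assignment, then tabu-search swap optimization of the within-region
    sum of squared deviations); and information-loss diagnostics for the
    resulting aggregation. Includes a synthetic lattice-survey generator with
    planted homogeneous zones for validation, plot methods for the diagnostic
    scatter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
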