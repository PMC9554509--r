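Package: hrdmiln
Title: Homologous Recombination Deficiency Scoring from LOH Segments by
    Multi-Instance Learning
Version: 0.1.0
Authors@R:
    person("HRD-MILN", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates the homologous recombination deficiency (HRD) status
    of tumor samples from the loss-of-heterozygosity (LOH) segments reported
    by allele-specific copy-number callers (FACETS 'cncf' tables).  Each
    sample is treated as a bag of LOH instances and only the bag carries an
    HRD label; a modified expectation-maximization diverse-density (EMDD)
    algorithm learns K "target concept" points in LOH feature space, and a
    sample is scored by the proximity of its segments to those concepts.
    Includes MILBoost-based feature-importance ranking, ablation curves for
    the effective feature count, cross-validation / nested cross-validation /
    bootstrap evaluation over bags, and a synthetic FACETS-table generator
    with planted concepts for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
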