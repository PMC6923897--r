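Package: strpanel
Title: Forensic STR Panel Selection Across Multiple Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates per-locus forensic parameters (heterozygosity,
    probability of matching, power of discrimination, power of exclusion,
    maximum profile frequency) from short tandem repeat (STR) genotype
    tables in one or more species, filters candidate loci by structural and
    forensic-parameter thresholds, and greedily selects a minimal marker
    panel whose combined power of discrimination and random-match
    probability satisfy user thresholds in every species and in the
    integrated pseudo species. Includes a synthetic multi-species
    population generator and simulation experiments: sample-size effects on
    allele detection and parameter estimation, random-match-probability
    distributions over simulated individuals, and true/false trio paternity
    index simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
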