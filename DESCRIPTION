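Package: protosex
Title: Sex-Determining Locus Discovery on Undifferentiated (Proto) Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Fisheries Genomics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping a master sex-determining (SD) locus in species
    with XY heterogamety but undifferentiated, freely recombining sex
    chromosomes, as in the tiger pufferfish. Implements pedigree recombinant
    screening and SD-interval refinement from transmitted paternal haplotypes,
    X/Y clone sequence comparison and XY-pattern variant screening with
    missense annotation, exact genotype-count association under a recessive
    penetrance model (point-probability two-sided Fisher test, Bonferroni and
    max-T permutation corrections), EM haplotype-frequency estimation with
    D, D', r-squared and LOD linkage-disequilibrium statistics, trans-species
    polymorphism detection with per-species and pooled association tests, and
    forward-time simulators (wild XY population, F1 families, X/Y clone pairs,
    multi-species panels) that generate every input the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
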