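Package: xstrkit
Title: Forensic and Population Genetics of X-Chromosomal STR Markers
Version: 0.1.0
Authors@R:
    person("Forensic Genetics Toolkit Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Analysis of X-chromosomal short tandem repeat (X-STR) genotype
    data with sex-aware chromosome dosage (hemizygous males, diploid females):
    allele and linkage-group haplotype frequencies, haplotype diversity, exact
    Hardy-Weinberg and linkage-disequilibrium tests, exact tests of population
    differentiation, the standard battery of forensic efficiency parameters
    (PIC, heterozygosity, power of exclusion and discrimination, paternity
    index, mean exclusion chances for trios and duos) with multi-locus combined
    values, pairwise Fst from haploid variance components, Nei's unbiased
    genetic distance, UPGMA trees with Newick output, principal coordinate
    analysis, STRUCTURE input export with Evanno delta-K post-processing, and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
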