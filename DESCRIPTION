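Package: paraconv
Title: Population Genetics of Recently Duplicated Genes with Interlocus
    Gene Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the evolution of recently duplicated gene
    families that exchange sequence by interlocus gene conversion. Provides
    an event-driven structured coalescent simulator for two paralogous loci
    with geometric conversion tracts, a duplication event and stepwise
    population expansion; classical summary statistics (nucleotide
    diversity, Watterson's theta, Tajima's D, Fu and Li's D, Hudson's F_ST,
    shared/private/fixed polymorphism classification, sliding windows);
    approximate Bayesian computation with rejection sampling and
    local-linear regression adjustment for estimating the population gene
    conversion rate and for model choice via Bayes factors; demography-aware
    null distributions for neutrality tests; a general-linear-model scan
    for SNP-phenotype association with Bonferroni correction; and a
    synthetic-data generator producing allele panels with the statistical
    structure the pipeline assumes (two paralogous loci, balanced intronic
    sequence types, pseudogene alleles, planted causal variants).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
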