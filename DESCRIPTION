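Package: dtcprs
Title: Polygenic Risk Scoring for Direct-to-Consumer Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scoring engine for heterogeneous direct-to-consumer (DTC)
    genotype exports. Parses the major raw-data dialects (23andMe-style,
    AncestryDNA-style, MyHeritage-style), harmonizes alleles against a
    reference panel with strand-flip resolution and Hardy-Weinberg exact-test
    quality control, computes frequency-centered polygenic risk scores scaled
    to 1000 Genomes super-population Z-scores (analytic or empirical
    normalization), assigns continental ancestry by genotype likelihood, and
    evaluates case/control prediction with Nagelkerke R-squared and AUC. A
    liability-threshold simulation framework generates synthetic cohorts and
    vendor SNP-set masks to quantify how un-imputed, mixed-vendor SNP sets
    destroy the predictive power of polygenic scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
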