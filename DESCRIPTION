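Package: hologen
Title: Host-Genetic and Gut-Microbiome Variance Partitioning for Feed
    Efficiency Traits
Version: 0.1.0
Authors@R:
    person("hologen", "developers", email = "hologen@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of host genetics and the gut microbiome for
    quantitative traits such as pig feed efficiency. Builds genomic (GRM),
    microbial (MRM) and genotype-by-microbiome (Hadamard) relationship
    kernels, partitions phenotypic variance by multi-kernel restricted
    maximum likelihood (heritability, microbiability, interaction fraction),
    runs mixed-model GWAS and microbiome-GWAS with an empirical FDR
    threshold, and screens taxa for phenotype association with a two-part
    (hurdle) model, extreme-group tests, Pearson correlation and a consensus
    rule. A synthetic-data generator with known ground truth supports
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
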