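Package: pleioscan
Title: Prioritization of Causal Pleiotropic Regulatory Variants Across
    Autoimmune Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for evidence-based prioritization of
    causal pleiotropic regulatory variants from GWAS summary statistics.
    Implements summary-statistic standardization and allele harmonization
    against a reference panel, single-causal-variant fine-mapping with
    approximate Bayes factors and 95% credible sets, block-wise pairwise
    pleiotropy posteriors with a MeSH-hierarchy heuristic for expected
    cohort-overlap correlation, regulatory trait concordance (RTC) eQTL
    colocalization, a causal inference test for variant/cis-gene/trans-gene
    triplets with directed network assembly, aggregation of four evidence
    conditions into a ranked candidate list, disease-gene bipartite network
    summaries, and strand-aware alternative-promoter transcript-usage QTL
    mapping.  A synthetic-data module generates LD-structured genotypes,
    paired GWAS summary statistics, cis-eQTL expression, causal triplets,
    and promoter-usage expression so that every stage is testable without
    external cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
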