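Package: yhapq
Title: Y-Chromosome STR Haplotype and Haplogroup-Q Lineage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for Y-chromosome short-tandem-repeat (Y-STR) haplotype
    analysis in a haplogroup framework: SNP-based hierarchical haplogroup
    classification with paragroup labelling and direct-count frequency
    tables; haplotype diversity and repeat-number variance on the forensic
    minimal haplotype; pairwise individual-by-individual genetic distances
    and principal coordinates analysis; variance-weighted median-joining
    networks with reduced-median preprocessing; and average-squared-distance
    (ASD) coalescence and expansion-time estimation with standard errors
    over loci. Includes a stepwise-mutation-model simulator (star and
    coalescent genealogies, SNP mutations on branches, injected
    duplicated-locus and micro-variant anomalies) so every stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
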