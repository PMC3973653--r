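Package: canesrna
Title: Small RNA Profiling, Target Prediction and Secondary siRNA
    Discovery for Plant Drought Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for bulk small-RNA sequencing analysis in
    non-model plants such as sugarcane: read cleaning (adapter trimming,
    length window, low-complexity and t/rRNA contaminant filters),
    conserved-miRNA profiling against a mature-miRNA reference with an
    "electronic northern" expression table, Fisher exact differential
    expression with Bonferroni control and a pool-versus-individual-
    genotype concordance classifier, rule-based plant miRNA target
    prediction with a nearest-neighbor duplex energy criterion,
    discovery of 22-nt-miRNA-triggered secondary siRNAs anchored at the
    predicted cleavage site, and annotation of repeat-derived siRNA
    clusters. A deterministic synthetic-data generator emulating the
    salient structure of plant small-RNA libraries makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
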