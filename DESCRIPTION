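Package: vitapath
Title: Vitamin B and K2 Biosynthesis Potential of Gut Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing de novo vitamin B and menaquinone (K2)
    biosynthesis potential in gut metagenome collections. Provides a curated,
    editable vitamin-pathway knowledge base (KEGG KO sets grouped into
    functional roles, routes and pathways, with cobalamin biosynthesis stage
    labels), genome quality filtering and greedy ANI dereplication, pathway
    completeness classification of genomes as de novo vitamin producers,
    stage-aware cobalamin gap analysis across focal genera, TPM-based
    functional and taxonomic abundance profiling, the diversity and
    group-comparison statistics used for gut-region and infection contrasts
    (Bray-Curtis, PCoA, PERMANOVA, Wilcoxon rank-sum, BH-FDR, Fisher's method,
    Cohen's d), and a synthetic metagenome generator with recorded ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
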