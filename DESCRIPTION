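Package: viralbins
Title: Identification of Viral Genome Bins in Bulk-Metagenome Binning Output
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies viral genomes among the bins produced by
    metagenome binning (VAMB-style contig clusters) by aggregating
    per-contig annotations (viral prediction scores, viral orthologous
    group hits, bacterial hallmark genes) into bin-level features and
    classifying bins with a random forest. Carries predicted viral bins
    through MIUViG-style quality tiers and concatemer/overcompleteness
    filters, viral-population definition and dark-matter stratification,
    metavirome recovery and bin purity from genome alignments,
    CRISPR-spacer and prophage host prediction with plurality voting,
    plurality viral taxonomy, and RPKM population abundance profiles
    with community summaries. Includes a seeded synthetic-study
    generator with full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    vegan,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
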