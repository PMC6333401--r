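Package: globinquant
Title: Paralog-Aware Globin Transcript Quantification and CRISPR Deletion
    Screen Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of a dual-guide CRISPR deletion
    screen of the beta-globin locus: enumeration of SpCas9 guide sites and
    selection of deletion-forming guide pairs, construction of 150-nt
    "stapler" single-stranded oligonucleotide donors, automated genotyping of
    deep-sequenced PCR amplicons, and quantification of near-identical globin
    transcripts (e.g. HBG1/HBG2, HBA1/HBA2) from short single-end RNA-seq
    reads by k-mer equivalence-class expectation-maximisation. A
    simulation-based calibration converts mean observed/expected count ratios
    from reads sampled out of known transcript mixtures into per-transcript
    adjustment factors that correct multi-mapping bias among paralogs. A
    synthetic-data module generates paralog families, truth-labelled reads
    and edited-amplicon reads so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
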