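Package: metamock
Title: Design and Simulation of Shotgun Metagenomic Communities with Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs microbial community compositions from abundance
    specifications (reads, bases, coverage, sequence or taxonomic
    abundances; even or log-normal draws), simulates short (single or
    paired Illumina-like) and long reads with a parametric error model
    and exact per-read ground truth, and writes anonymized shuffled
    FASTQ, truth SAM/BAM alignments, and CAMI biobox taxonomic profiles
    carrying both sequence-abundance and taxonomic-abundance flavors.
    Also ranks and selects genome assemblies from offline metadata
    tables (RefSeq category, assembly status, BUSCO and checkM
    completeness), optionally capped per taxonomic rank. A fixture
    generator produces synthetic genomes, taxonomies, and metadata so
    the whole pipeline runs without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
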