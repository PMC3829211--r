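Package: ampcall
Title: Variant Calling for Fully Overlapping Amplicon Read Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variant calling and coverage quality control for highly
    multiplexed PCR amplicon sequencing libraries in which both mates of a
    paired-end read span the entire amplicon. Every template base is read
    twice, once per mate, so candidate variants are required to appear in
    both mates of a read pair before they count as evidence; calls are then
    made from read-pair support thresholds (minimum supporting pairs,
    minimum pair fraction, homozygous pair fraction) and written as VCF.
    Also reports per-amplicon read-pair depth, on-target rates and
    fold-of-median coverage uniformity, and includes a read-pair simulator
    that writes FASTQ, aligned SAM and truth VCF for hermetic end-to-end
    testing without an external aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
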