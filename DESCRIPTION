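Package: bsmarkdup
Title: Bisulfite-Aware Duplicate Marking for WGBS and WGS Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marks PCR duplicates in name-grouped SAM/BAM alignment streams
    from whole genome bisulfite sequencing (WGBS) and whole genome sequencing
    (WGS) experiments. Bisulfite library preparation yields two distinct
    template strands (OT/CTOT versus OB/CTOB) per genomic fragment, so
    co-located reads from opposite strands are distinct molecules, not
    duplicates. Duplicate detection couples a clip-corrected read signature
    (supercontig bin and position of both mates, mate order, orientation,
    pairedness, optional cell barcode) with the inferred bisulfite strand
    class, obtained from aligner tags or, as a fallback, by comparing C-to-T
    and G-to-A conversion counts against an indexed reference. The first
    occurrence of each signature is kept unmarked; later occurrences have the
    SAM duplicate flag (0x400) set on all primary, secondary, and
    supplementary records of the template. Includes a synthetic alignment
    generator with planted duplicates and a brute-force oracle for
    validation, plus a command-line interface for streamed pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    stringr,
    purrr,
    rlang,
    generics,
    ggplot2,
    optparse,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
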