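Package: pepdepth
Title: Sequencing-Depth Characterization of Phage Display Peptide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing phage display peptide libraries from
    single-end amplicon sequencing reads. Extracts displayed peptides from
    FASTQ reads by anchored insert location, translation and linker
    filtering; builds frequency-sorted peptide matrices with full removal
    accounting; computes diversity and quality statistics (percent distinct
    sequences, singleton/bin composition, frequency spectra and distinct
    frequency values); and compares datasets sequenced at different depths
    via Bonferroni-corrected Poisson confidence intervals on absolute
    frequencies, identical-peptide overlap, and position-specific amino
    acid frequency differences. Includes a synthetic NNK degenerate-codon
    library and read simulator with configurable defect classes so every
    pipeline stage can be exercised without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
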