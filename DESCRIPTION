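Package: aligndude
Title: Two-Pass Statistical Denoising of Aligned Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Corrects substitution errors in aligned short sequencing reads
    with a two-pass discrete universal denoiser (DUDE). The first pass over a
    SAM file estimates the sequencer's substitution noise channel from pileup
    majorities and collects double-sided context statistics over coupled
    (base, quality-bin) symbols; the second pass inverts the channel estimate
    to obtain a posterior over the true base at each low-confidence position,
    replaces the base by the posterior mode, and updates the Phred quality
    score in tandem. Includes a read simulator with a known substitution
    channel and an evaluation harness scoring error correction and variant
    retention against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
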