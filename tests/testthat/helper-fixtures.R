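# In-code fixture builders: tiny SAM files and read tibbles.

sam_record <- function(qname = "r1", flag = 0L, rname = "ref", pos = 1L,
                       mapq = 60L, cigar = "5M", seq = "ACGTA",
                       qual = NULL, tags = character()) {
  if (is.null(qual)) qual = strrep("I", nchar(seq))  # I = Phred 40
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, qual,
          tags), collapse = "\t")
}

write_tiny_sam <- function(records, header = c("@HD\tVN:1.6",
                                               "@SQ\tSN:ref\tLN:1000"),
                           path = withr::local_tempfile(fileext = ".sam",
                                                        .local_envir = parent.frame())) {
  writeLines(c(header, records), path)
  path
}

# Reads tibble straight from field vectors (skipping file I/O)
reads_tibble <- function(qname, pos, cigar, seq, qual, flag = 0L,
                         rname = "ref") {
  n <- length(qname)
  reads <- tibble::tibble(
    qname = qname, flag = rep_len(flag, n), rname = rep_len(rname, n),
    pos = as.integer(pos), mapq = 60L, cigar = cigar, rnext = "*",
    pnext = 0L, tlen = 0L, seq = seq, qual = qual, tags = "")
  reads$class <- classify_read(reads$flag)
  attr(reads, "header") <- c("@HD\tVN:1.6")
  reads
}

# A quality profile with a sizable low-quality tail, so that a useful
# fraction of bases sits below the t_p confidence gate in small tests.
lowq_profile <- function() {
  tibble::tibble(phred = c(2L, 12L, 37L, 41L),
                 prob = c(0.2, 0.2, 0.3, 0.3))
}
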