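#' Default per-base quality profile for simulated reads
#'
#' An Illumina-like discrete Phred distribution: most calls are confident
#' (q37/q41), with small tails of mid- and low-quality calls so that every
#' quality bin receives observations and a realistic fraction of bases sits
#' below the denoiser's confidence gate.
#'
#' @return Tibble with columns `phred` and `prob` (summing to 1).
#' @export
default_quality_profile <- function() {
  tibble::tibble(
    phred = c(2L, 7L, 12L, 22L, 27L, 32L, 37L, 41L),
    prob = c(0.02, 0.02, 0.03, 0.05, 0.08, 0.10, 0.30, 0.40))
}

#' True substitution channel implied by per-bin error rates
#'
#' Builds the 4 x 32 row-stochastic matrix of P(observed (base, bin) | true
#' base) for the simulator's generative model: a Phred score is drawn from
#' the quality profile, its bin fixes the substitution rate, and errors are
#' uniform over the three other bases.
#'
#' @param error_by_bin Numeric vector of 8 per-bin substitution rates (a
#'   single rate is recycled).
#' @param quality_profile Tibble with `phred`, `prob`.
#' @param scheme Binning scheme.
#' @return 4 x 32 matrix with rows A, C, G, T and columns
#'   [symbol_labels()].
#' @export
channel_from_rates <- function(error_by_bin,
                               quality_profile = default_quality_profile(),
                               scheme = quality_scheme_illumina8()) {
  eps <- rep_len(error_by_bin, 8L)
  stopifnot(all(eps >= 0 & eps <= 1))
  bin_prob <- rep(0, 8L)
  bins <- bin_quality(quality_profile$phred, scheme)
  for (i in seq_along(bins)) {
    bin_prob[bins[i]] <- bin_prob[bins[i]] + quality_profile$prob[i]
  }
  Pi <- matrix(0, 4L, 32L, dimnames = list(BASES, symbol_labels()))
  for (j in 1:4) {
    for (b in 1:4) {
      for (bin in 1:8) {
        Pi[j, 8L * (b - 1L) + bin] <-
          bin_prob[bin] * if (b == j) 1 - eps[bin] else eps[bin] / 3
      }
    }
  }
  Pi
}

#' Simulate aligned reads with a known substitution noise channel
#'
#' Emulates shotgun sequencing of a random reference: fixed-length reads at
#' uniform positions, per-base Phred scores drawn from a quality profile,
#' and substitution errors drawn at the bin's configured rate, uniformly
#' over the other three bases. Reads are emitted pre-aligned with correct
#' POS and CIGAR, so the denoiser can be exercised without an external
#' aligner. Optionally plants heterozygous SNVs (each read drawn from one
#' of two haplotypes), soft-clip heads and 1-base insertions.
#'
#' @param ref_length Reference length in bases.
#' @param coverage Mean fold coverage; the number of reads is
#'   `round(ref_length * coverage / read_length)`.
#' @param read_length Read length in bases.
#' @param error_by_bin Per-bin substitution rate(s), recycled to 8.
#' @param quality_profile Tibble `phred`/`prob`.
#' @param het_rate Expected heterozygous SNVs per reference base; alleles
#'   are drawn by each read's haplotype.
#' @param vaf Variant allele fraction: probability a read carries
#'   haplotype 2 (default 0.5, the germline heterozygous case).
#' @param clip_rate Per-read probability of a 5-base soft-clip head of
#'   random bases.
#' @param ins_rate Per-read probability of one 1-base insertion at a random
#'   interior offset.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param ref_name Reference sequence name written to the header.
#' @param scheme Binning scheme (used only to derive `channel_true`).
#' @return A `sim_dataset` list: `reads` (SAM tibble with header
#'   attribute), `truth` (tibble: `read_name`, `read_index`, `ref_pos`,
#'   `true_base`, `emitted_base`, `phred`; one row per query base, NA
#'   `ref_pos` for clipped/inserted bases), `variants` (tibble: `ref_pos`,
#'   `allele_a` reference allele, `allele_b` alternate), `channel_true`,
#'   `reference` (haplotype-1 sequence) and `config`.
#' @export
simulate_reads <- function(ref_length = 1e5, coverage = 30,
                           read_length = 100,
                           error_by_bin = 0.01,
                           quality_profile = default_quality_profile(),
                           het_rate = 0, vaf = 0.5, clip_rate = 0,
                           ins_rate = 0, seed = NULL, ref_name = "sim1",
                           scheme = quality_scheme_illumina8()) {
  stopifnot(ref_length >= read_length, coverage > 0,
            all(c(het_rate, vaf, clip_rate, ins_rate) >= 0),
            all(c(het_rate, vaf, clip_rate, ins_rate) <= 1))
  if (!is.null(seed)) set.seed(seed)
  eps <- rep_len(error_by_bin, 8L)
  L <- as.integer(ref_length)
  rl <- as.integer(read_length)

  hap1 <- sample(BASES, L, replace = TRUE)
  n_var <- rbinom(1L, L, het_rate)
  var_pos <- sort(sample.int(L, n_var))
  hap2 <- hap1
  allele_b <- character(n_var)
  if (n_var > 0L) {
    shift <- sample.int(3L, n_var, replace = TRUE)
    allele_b <- BASES[(base_index(hap1[var_pos]) + shift) %% 4L + 1L]
    hap2[var_pos] <- allele_b
  }
  variants <- tibble::tibble(ref_pos = var_pos, allele_a = hap1[var_pos],
                             allele_b = allele_b)

  n_reads <- max(1L, as.integer(round(L * coverage / rl)))
  starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
  hap <- 1L + (runif(n_reads) < vaf)
  read_name <- sprintf("sim%06d", seq_len(n_reads))

  nb <- n_reads * rl
  idx <- rep(starts, each = rl) + rep.int(0:(rl - 1L), n_reads)
  truth_base <- ifelse(rep(hap, each = rl) == 1L, hap1[idx], hap2[idx])
  phred <- sample(quality_profile$phred, nb, replace = TRUE,
                  prob = quality_profile$prob)
  bins <- bin_quality(phred, scheme)
  err <- runif(nb) < eps[bins]
  emitted <- truth_base
  if (any(err)) {
    shift <- sample.int(3L, sum(err), replace = TRUE)
    emitted[err] <- BASES[(base_index(truth_base[err]) + shift) %% 4L + 1L]
  }

  seq_mat <- matrix(emitted, nrow = rl)
  seqs <- do.call(paste0, split(seq_mat, row(seq_mat)))
  qual_mat <- matrix(rawToChar(as.raw(phred + 33L), multiple = TRUE),
                     nrow = rl)
  quals <- do.call(paste0, split(qual_mat, row(qual_mat)))

  reads <- tibble::tibble(
    qname = read_name, flag = 0L, rname = ref_name, pos = starts,
    mapq = 60L, cigar = paste0(rl, "M"), rnext = "*", pnext = 0L,
    tlen = 0L, seq = seqs, qual = quals, tags = "",
    class = "primary_mapped")
  truth <- tibble::tibble(
    read_name = rep(read_name, each = rl),
    read_index = rep.int(0:(rl - 1L), n_reads),
    ref_pos = idx, true_base = truth_base, emitted_base = emitted,
    phred = as.integer(phred))

  # CIGAR events are injected read-by-read; they are rare by construction
  clip_len <- 5L
  clipped <- which(runif(n_reads) < clip_rate)
  inserted <- which(runif(n_reads) < ins_rate)
  extras <- vector("list", length(clipped) + length(inserted))
  ei <- 0L
  for (i in clipped) {
    cb <- sample(BASES, clip_len, replace = TRUE)
    cq <- sample(quality_profile$phred, clip_len, replace = TRUE,
                 prob = quality_profile$prob)
    reads$seq[i] <- paste0(paste(cb, collapse = ""), reads$seq[i])
    reads$qual[i] <- paste0(phred_to_qual(cq), reads$qual[i])
    reads$cigar[i] <- paste0(clip_len, "S", rl, "M")
    ei <- ei + 1L
    extras[[ei]] <- tibble::tibble(
      read_name = read_name[i], read_index = 0:(clip_len - 1L),
      ref_pos = NA_integer_, true_base = cb, emitted_base = cb,
      phred = as.integer(cq))
    sel <- truth$read_name == read_name[i] & !is.na(truth$ref_pos)
    truth$read_index[sel] <- truth$read_index[sel] + clip_len
  }
  for (i in inserted) {
    lo <- max(1L, min(10L, rl - 1L))
    hi <- max(lo, rl - 10L)
    at <- if (hi > lo) sample(lo:hi, 1L) else lo  # insertion after `at` M bases
    ib <- sample(BASES, 1L)
    iq <- sample(quality_profile$phred, 1L, prob = quality_profile$prob)
    pre <- nchar(reads$seq[i]) - rl  # clip length if also clipped
    reads$seq[i] <- paste0(substr(reads$seq[i], 1L, pre + at), ib,
                           substr(reads$seq[i], pre + at + 1L,
                                  nchar(reads$seq[i])))
    reads$qual[i] <- paste0(substr(reads$qual[i], 1L, pre + at),
                            phred_to_qual(iq),
                            substr(reads$qual[i], pre + at + 1L,
                                   nchar(reads$qual[i])))
    reads$cigar[i] <- paste0(if (pre > 0L) paste0(pre, "S") else "",
                             at, "M1I", rl - at, "M")
    sel <- truth$read_name == read_name[i] & truth$read_index >= pre + at
    truth$read_index[sel] <- truth$read_index[sel] + 1L
    ei <- ei + 1L
    extras[[ei]] <- tibble::tibble(
      read_name = read_name[i], read_index = pre + at,
      ref_pos = NA_integer_, true_base = ib, emitted_base = ib,
      phred = as.integer(iq))
  }
  if (ei > 0L) {
    truth <- dplyr::arrange(dplyr::bind_rows(truth, extras[seq_len(ei)]),
                            match(.data$read_name, read_name),
                            .data$read_index)
  }

  attr(reads, "header") <- c("@HD\tVN:1.6\tSO:unsorted",
                             paste0("@SQ\tSN:", ref_name, "\tLN:", L))
  structure(list(
    reads = reads, truth = truth, variants = variants,
    channel_true = channel_from_rates(eps, quality_profile, scheme),
    reference = paste(hap1, collapse = ""),
    config = list(ref_length = L, coverage = coverage, read_length = rl,
                  error_by_bin = eps, het_rate = het_rate, vaf = vaf,
                  clip_rate = clip_rate, ins_rate = ins_rate, seed = seed,
                  ref_name = ref_name)),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", nrow(x$reads), "reads x", x$config$read_length,
      "bp over", x$config$ref_length, "bp reference;",
      nrow(x$variants), "het sites\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' @param sim A `sim_dataset`.
#' @param sam_path Output SAM path.
#' @param truth_path Optional TSV path for the per-base truth table.
#' @param variants_path Optional TSV path for the planted-variant list.
#' @return `sam_path`, invisibly.
#' @export
sim_write <- function(sim, sam_path, truth_path = NULL,
                      variants_path = NULL) {
  stopifnot(inherits(sim, "sim_dataset"))
  write_sam(sim$reads, sam_path, pg_cl = NULL)
  if (!is.null(truth_path)) {
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(variants_path)) {
    utils::write.table(sim$variants, variants_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(sam_path)
}
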