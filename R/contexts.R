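#' Build the effective read used for context statistics
#'
#' Soft-clipped bases are dropped (long stretches of low-confidence calls),
#' inserted bases are kept — an insertion relative to the reference may be a
#' true feature of the sample — and aligned bases keep their reference
#' position. Deletions consume no entry. Order follows the read.
#'
#' @param read A one-row tibble with `pos`, `cigar`, `seq`, `qual`.
#' @param scheme Quality binning scheme.
#' @return Tibble with columns `base` (character, may be `"N"`), `bin`,
#'   `origin` (`"read"`), `read_index` (0-based) and `ref_pos` (1-based, NA
#'   for insertions).
#' @export
effective_read <- function(read, scheme = quality_scheme_illumina8()) {
  stopifnot(nrow(read) == 1L)
  walk <- walk_alignment(read$cigar, read$pos, read$seq)
  keep <- walk[!is.na(walk$query_index) & walk$op != "S", ]
  chars <- strsplit(read$seq, "")[[1]]
  phred <- qual_to_phred(read$qual)
  tibble::tibble(
    base = chars[keep$query_index + 1L],
    bin = bin_quality(phred[keep$query_index + 1L], scheme),
    origin = "read",
    read_index = keep$query_index,
    ref_pos = keep$ref_pos)
}

#' Pad an effective read with sequence-estimate bases
#'
#' When a read begins (ends) with a reference-mapped base at position j, up
#' to k estimated bases from positions j-k..j-1 (j+1..j+k) are prepended
#' (appended) so that positions near the read edges still have full
#' double-sided contexts. Padding stops at the first position where the
#' sequence estimate is undefined (pads must be contiguous with the read),
#' and a side that starts or ends with an insertion gets no pad.
#'
#' @param eff Tibble from [effective_read()].
#' @param x_hat Tibble with `ref_pos`, `base` ([sequence_estimate()] rows
#'   for the read's reference sequence).
#' @param k Single-sided context length.
#' @return The padded effective-read tibble; pad rows have `origin =
#'   "pad"`, no bin and no read index.
#' @export
pad_read <- function(eff, x_hat, k) {
  stopifnot(k >= 1)
  pad_row <- function(p) {
    b <- x_hat$base[match(p, x_hat$ref_pos)]
    if (is.na(b)) return(NULL)
    tibble::tibble(base = b, bin = NA_integer_, origin = "pad",
                   read_index = NA_integer_, ref_pos = p)
  }
  grab <- function(from, step) {
    rows <- list()
    for (t in seq_len(k)) {
      r <- pad_row(from + step * t)
      if (is.null(r)) break
      rows[[t]] <- r
    }
    dplyr::bind_rows(rows)
  }
  out <- eff
  if (nrow(eff) > 0L && !is.na(eff$ref_pos[1])) {
    pre <- grab(eff$ref_pos[1], -1L)
    if (nrow(pre) > 0L) out <- dplyr::bind_rows(pre[rev(seq_len(nrow(pre))), ], out)
  }
  if (nrow(eff) > 0L && !is.na(eff$ref_pos[nrow(eff)])) {
    post <- grab(eff$ref_pos[nrow(eff)], 1L)
    if (nrow(post) > 0L) out <- dplyr::bind_rows(out, post)
  }
  out
}

#' Count double-sided context vectors over all primary reads
#'
#' For every window of 2k+1 consecutive effective-read entries whose center
#' is a read base in A/C/G/T and whose k-base flanks are all unambiguous
#' (pads allowed in flanks, never as center), the count of the center's
#' coupled (base, bin) symbol under the flanking context (l^k, r^k) is
#' incremented. The result is the sparse map from context to 32-long counts
#' vector that drives the second-pass posterior.
#'
#' @param reads Tibble of alignment records.
#' @param channel A `channel_estimate` (supplies the sequence estimate used
#'   for padding and the binning scheme).
#' @param k Single-sided context length (default 7).
#' @return A `context_store`: list with `k`, `keys` (2k-character context
#'   strings, left flank then right flank), `counts` (32 x n_keys integer
#'   matrix) and a hash `index`.
#' @export
count_contexts <- function(reads, channel, k = 7L) {
  stopifnot(inherits(channel, "channel_estimate"), k >= 1)
  el <- eligible_reads(reads)
  lut <- bin_lookup(channel$scheme)
  parts <- lapply(split(el, el$rname), function(g) {
    xh <- channel$x_hat[[g$rname[1]]]
    if (is.null(xh)) xh <- list(start = 1L, codes = integer())
    count_contexts_cpp(g$pos, g$cigar, g$seq, g$qual, lut, xh$codes,
                       xh$start, as.integer(k))
  })
  merged <- merge_contexts_cpp(lapply(parts, `[[`, "keys"),
                               lapply(parts, `[[`, "counts"))
  new_context_store(k, merged$keys, merged$counts)
}

new_context_store <- function(k, keys, counts) {
  index <- new.env(hash = TRUE, parent = emptyenv(),
                   size = max(1L, length(keys)))
  for (j in seq_along(keys)) assign(keys[j], j, envir = index)
  structure(list(k = as.integer(k), keys = keys, counts = counts,
                 index = index),
            class = "context_store")
}

#' Look up the counts vector of one context
#'
#' @param store A `context_store`.
#' @param left,right k-character flank strings (A/C/G/T only).
#' @return Integer vector of 32 counts in [symbol_labels()] order, or
#'   `NULL` if the context was never observed.
#' @export
lookup_context <- function(store, left, right) {
  stopifnot(nchar(left) == store$k, nchar(right) == store$k)
  j <- get0(paste0(left, right), envir = store$index)
  if (is.null(j)) return(NULL)
  v <- store$counts[, j]
  names(v) <- symbol_labels()
  v
}

#' @export
print.context_store <- function(x, ...) {
  cat("<context_store> k =", x$k, "|", length(x$keys), "contexts |",
      format(sum(x$counts), big.mark = ","), "windows\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.context_store <- function(x, ...) {
  nz <- which(x$counts != 0, arr.ind = TRUE)
  keys <- x$keys[nz[, 2]]
  tibble::tibble(
    left = substr(keys, 1L, x$k),
    right = substr(keys, x$k + 1L, 2L * x$k),
    symbol = symbol_labels()[nz[, 1]],
    count = x$counts[nz]) %>%
    dplyr::arrange(.data$left, .data$right, .data$symbol)
}

#' @exportS3Method generics::glance
glance.context_store <- function(x, ...) {
  tibble::tibble(k = x$k, contexts = length(x$keys),
                 windows = sum(x$counts),
                 max_context_depth = if (length(x$keys)) max(colSums(x$counts)) else 0L)
}
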