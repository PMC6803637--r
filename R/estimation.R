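#' Accumulate a per-position pileup of coupled (base, bin) symbols
#'
#' First-pass statistic: every reference-aligned (M/=/X) base of every
#' primary read increments the 32-symbol count of its reference position.
#' Soft-clipped and inserted bases contribute nothing, deletions only
#' advance coordinates, and ambiguous bases (N) are skipped. Reads that are
#' unmapped, secondary, supplementary, or missing SEQ/QUAL/CIGAR are
#' excluded.
#'
#' @param reads Tibble from [read_sam()] or [simulate_reads()].
#' @param scheme Quality binning scheme.
#' @return A `pileup_store`: per reference sequence a list with `start`
#'   (1-based position of the first column) and `counts` (32 x width
#'   integer matrix, rows in [symbol_labels()] order).
#' @export
sam_pileup <- function(reads, scheme = quality_scheme_illumina8()) {
  el <- eligible_reads(reads)
  if (nrow(el) == 0L) {
    return(structure(list(per_ref = list(), scheme = scheme),
                     class = "pileup_store"))
  }
  lut <- bin_lookup(scheme)
  per_ref <- lapply(split(el, el$rname), function(g) {
    start <- min(g$pos)
    end <- max(g$pos + cigar_ref_length(g$cigar) - 1L)
    counts <- pileup_counts_cpp(g$pos, g$cigar, g$seq, g$qual, lut,
                                start, end - start + 1L)
    rownames(counts) <- symbol_labels()
    list(start = start, counts = counts)
  })
  structure(list(per_ref = per_ref, scheme = scheme),
            class = "pileup_store")
}

eligible_reads <- function(reads) {
  dplyr::filter(reads, .data$class == "primary_mapped", .data$seq != "*",
                .data$qual != "*", .data$cigar != "*")
}

#' Majority base of a pileup column
#'
#' A base is the majority base of a position when its normalized count is at
#' least `t_m`. Positions without a qualifying base — in particular
#' heterozygous sites with a ~50/50 allele mix — are left undefined and
#' contribute nothing to channel estimation.
#'
#' @param base_counts Numeric vector of 4 counts in A, C, G, T order.
#' @param t_m Majority threshold (default 0.9; must be declared >= 0.5 for a
#'   unique majority).
#' @return A single base character, or `NA` if no base qualifies.
#' @export
#' @examples
#' majority_base(c(9, 1, 0, 0), t_m = 0.9)  # boundary inclusive -> "A"
#' majority_base(c(8, 2, 0, 0), t_m = 0.9)  # NA
majority_base <- function(base_counts, t_m = 0.9) {
  stopifnot(length(base_counts) == 4L)
  total <- sum(base_counts)
  if (total == 0) return(NA_character_)
  hit <- which(base_counts / total >= t_m)
  if (length(hit) != 1L) return(NA_character_)
  BASES[hit]
}

# Vectorized majority over a 32 x L symbol-count matrix; returns 0..3 codes,
# -1 where undefined.
majority_codes <- function(symbol_counts, t_m) {
  L <- ncol(symbol_counts)
  bc <- rbind(colSums(symbol_counts[1:8, , drop = FALSE]),
              colSums(symbol_counts[9:16, , drop = FALSE]),
              colSums(symbol_counts[17:24, , drop = FALSE]),
              colSums(symbol_counts[25:32, , drop = FALSE]))
  tot <- colSums(bc)
  top <- max.col(t(bc), ties.method = "first")
  topv <- bc[cbind(top, seq_len(L))]
  thresh <- matrix(t_m * tot, nrow = 4L, ncol = L, byrow = TRUE)
  n_qual <- colSums(bc >= thresh & bc > 0)
  ok <- tot > 0 & topv / tot >= t_m & n_qual == 1L
  ifelse(ok, top - 1L, -1L)
}

#' Estimate the substitution noise channel from a pileup
#'
#' At every position with a defined majority base j, the position's 32
#' symbol counts are added to row j of the conditional counts matrix N.
#' Row-normalizing N yields the 4 x 32 channel estimate: row j gives the
#' probability of observing each coupled (base, bin) symbol when the true
#' base is j. The majority bases themselves form the sequence estimate used
#' for read padding.
#'
#' A base that never appears as a majority leaves its row of N empty; such a
#' row falls back to a uniform distribution over that base's own 8 symbols,
#' encoding "no evidence of error" while keeping the channel well
#' conditioned.
#'
#' @param pileup A `pileup_store` from [sam_pileup()].
#' @param t_m Majority threshold.
#' @return A `channel_estimate`: list with `N` (4 x 32 integer counts), `Pi`
#'   (4 x 32 row-stochastic matrix), `x_hat` (per reference: `start` and
#'   0..3 base `codes`, -1 undefined), `t_m` and the binning `scheme`.
#' @export
build_channel <- function(pileup, t_m = 0.9) {
  stopifnot(inherits(pileup, "pileup_store"))
  N <- matrix(0, nrow = 4L, ncol = 32L,
              dimnames = list(BASES, symbol_labels()))
  x_hat <- lapply(pileup$per_ref, function(ref) {
    codes <- majority_codes(ref$counts, t_m)
    for (j in 0:3) {
      sel <- codes == j
      if (any(sel)) {
        N[j + 1L, ] <<- N[j + 1L, ] + rowSums(ref$counts[, sel, drop = FALSE])
      }
    }
    list(start = ref$start, codes = as.integer(codes))
  })
  if (sum(N) == 0) {
    stop("cannot estimate channel: no pileup position has a majority base")
  }
  Pi <- N
  for (j in 1:4) {
    rs <- sum(N[j, ])
    if (rs > 0) {
      Pi[j, ] <- N[j, ] / rs
    } else {
      Pi[j, ] <- 0
      Pi[j, (8L * (j - 1L) + 1L):(8L * j)] <- 1 / 8
    }
  }
  structure(list(N = N, Pi = Pi, x_hat = x_hat, t_m = t_m,
                 scheme = pileup$scheme),
            class = "channel_estimate")
}

#' @describeIn build_channel Convenience wrapper: pileup + channel in one
#'   call from a reads tibble.
#' @param reads Tibble of alignment records.
#' @param scheme Quality binning scheme.
#' @export
estimate_channel <- function(reads, t_m = 0.9,
                             scheme = quality_scheme_illumina8()) {
  build_channel(sam_pileup(reads, scheme), t_m = t_m)
}

#' Sequence estimate as a tibble
#'
#' @param channel A `channel_estimate`.
#' @return Tibble with `rname`, `ref_pos` (1-based) and `base` for every
#'   position whose majority base is defined.
#' @export
sequence_estimate <- function(channel) {
  stopifnot(inherits(channel, "channel_estimate"))
  dplyr::bind_rows(lapply(names(channel$x_hat), function(rn) {
    xh <- channel$x_hat[[rn]]
    def <- which(xh$codes >= 0L)
    tibble::tibble(rname = rn, ref_pos = xh$start + def - 1L,
                   base = BASES[xh$codes[def] + 1L])
  }))
}

# Pseudo-inverse-based posterior operator G = (Pi Pi^T)^+ Pi. Singular
# values below rcond * max are dropped (least-squares pseudo-solution).
channel_inverse <- function(Pi, rcond = 1e-10) {
  A <- Pi %*% t(Pi)
  sv <- svd(A)
  keep <- sv$d > rcond * max(sv$d, 0)
  if (!any(keep)) return(NULL)
  Ainv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  Ainv %*% Pi
}

#' @export
print.channel_estimate <- function(x, ...) {
  cat("<channel_estimate>\n")
  cat("  observations:", format(sum(x$N), big.mark = ","),
      " majority threshold t_m:", x$t_m, "\n")
  cat("  per-base error rates:",
      paste0(BASES, "=", signif(1 - off_diag_mass(x$Pi), 3),
             collapse = " "), "\n")
  invisible(x)
}

# P(emitted base == true base) per channel row
off_diag_mass <- function(Pi) {
  vapply(1:4, function(j) sum(Pi[j, (8L * (j - 1L) + 1L):(8L * j)]),
         numeric(1))
}

#' @exportS3Method generics::tidy
tidy.channel_estimate <- function(x, ...) {
  tibble::tibble(
    true_base = rep(BASES, each = 32L),
    symbol = rep(symbol_labels(), times = 4L),
    base = rep(rep(BASES, each = 8L), times = 4L),
    bin = rep(rep(1:8, times = 4L), times = 4L),
    count = as.vector(t(x$N)),
    prob = as.vector(t(x$Pi)))
}

#' @exportS3Method generics::glance
glance.channel_estimate <- function(x, ...) {
  d <- tidy(x)
  tibble::tibble(
    observations = sum(x$N),
    positions_defined = nrow(sequence_estimate(x)),
    t_m = x$t_m,
    concordance = sum(d$count[d$true_base == d$base]) / sum(d$count))
}

#' Heatmap of the estimated noise channel
#'
#' @param object A `channel_estimate`.
#' @param ... Unused.
#' @return A ggplot: observed symbols on x, true base on y, fill =
#'   log10 conditional probability.
#' @exportS3Method ggplot2::autoplot
autoplot.channel_estimate <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$symbol, y = .data$true_base,
                                  fill = log10(pmax(.data$prob, 1e-8)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 P(symbol | base)") +
    ggplot2::labs(x = "observed (base, quality bin)", y = "true base") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
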