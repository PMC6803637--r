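#' Quality-score binning schemes
#'
#' The ~42-value Phred alphabet is reduced to 8 bins before any statistic is
#' collected, so that the coupled output alphabet (base x bin) stays at a
#' tractable 32 symbols. The default scheme follows Illumina's published
#' 8-level quality binning; any score above the top boundary falls into
#' bin 8.
#'
#' A scheme is a tibble with columns `bin` (1..8), `lo`, `hi` (inclusive
#' Phred bounds); ranges must be disjoint, contiguous from 0 and monotone.
#'
#' @param lo,hi Integer vectors of 8 inclusive Phred range bounds.
#' @return A `quality_scheme` tibble.
#' @export
#' @examples
#' quality_scheme_illumina8()
quality_scheme_illumina8 <- function() {
  quality_scheme(lo = c(0L, 2L, 10L, 20L, 25L, 30L, 35L, 40L),
                 hi = c(1L, 9L, 19L, 24L, 29L, 34L, 39L, 93L))
}

#' @rdname quality_scheme_illumina8
#' @export
quality_scheme <- function(lo, hi) {
  stopifnot(length(lo) == 8L, length(hi) == 8L)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo[1] != 0L) stop("binning scheme must start at Phred 0")
  if (any(hi < lo)) stop("binning scheme has an empty range")
  if (any(lo[-1] != hi[-8] + 1L)) {
    stop("binning scheme ranges must be contiguous and disjoint")
  }
  structure(tibble::tibble(bin = 1:8, lo = lo, hi = hi),
            class = c("quality_scheme", "tbl_df", "tbl", "data.frame"))
}

#' Map a Phred quality score to its bin
#'
#' @param q Vector of nonnegative integer Phred scores.
#' @param scheme A binning scheme; defaults to [quality_scheme_illumina8()].
#' @return Integer vector of bins in 1..8. Scores above the top boundary map
#'   to bin 8.
#' @export
#' @examples
#' bin_quality(c(2, 34, 41))
bin_quality <- function(q, scheme = quality_scheme_illumina8()) {
  if (any(q < 0)) stop("negative Phred quality score")
  b <- findInterval(q, scheme$lo)
  pmin.int(b, 8L)
}

# Lookup table bin_of_phred[q + 1] for q in 0..93, used by the C++ passes.
bin_lookup <- function(scheme) {
  bin_quality(0:93, scheme)
}
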