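#' Score a denoised SAM against simulation truth
#'
#' Joins the per-base truth table with the denoised reads and classifies
#' every reference-aligned (M) base: corrected (was wrong, now right),
#' introduced (was right, now wrong), missed (wrong before and after).
#' Clipped and inserted bases (NA `ref_pos` in the truth table) are
#' excluded — they are never denoised.
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @param denoised Denoised reads: a tibble from [read_sam()] or a SAM file
#'   path.
#' @param channel Optional `channel_estimate` to report channel recovery.
#' @param channel_true Optional true 4 x 32 channel matrix (with
#'   `channel`).
#' @param min_support Row/column support threshold for
#'   [channel_deviation()].
#' @return A `denoise_eval` list: `errors_corrected`, `errors_missed`,
#'   `errors_introduced`, `noisy_error_rate`, `denoised_error_rate`,
#'   `net_error_reduction`, `bases_evaluated`, and `channel_max_abs_dev`
#'   when the true channel is supplied. `glance()` returns it as one row.
#' @export
error_accounting <- function(truth, denoised, channel = NULL,
                             channel_true = NULL, min_support = 0) {
  if (is.character(denoised)) denoised <- read_sam(denoised)
  tr <- truth[!is.na(truth$ref_pos), ]
  ri <- match(tr$read_name, denoised$qname)
  if (anyNA(ri)) {
    stop("truth table names reads absent from the SAM: e.g. '",
         tr$read_name[which(is.na(ri))[1]], "'")
  }
  if (any(tr$read_index >= nchar(denoised$seq[ri]))) {
    stop("truth read_index exceeds read length; truth and SAM do not match")
  }
  den_base <- substr(denoised$seq[ri], tr$read_index + 1L,
                     tr$read_index + 1L)
  was_err <- tr$emitted_base != tr$true_base
  now_err <- den_base != tr$true_base
  corrected <- sum(was_err & !now_err)
  missed <- sum(was_err & now_err)
  introduced <- sum(!was_err & now_err)
  n <- nrow(tr)
  out <- list(
    errors_corrected = corrected, errors_missed = missed,
    errors_introduced = introduced,
    noisy_errors = corrected + missed,
    noisy_error_rate = (corrected + missed) / n,
    denoised_error_rate = (missed + introduced) / n,
    net_error_reduction = if (corrected + missed > 0) {
      (corrected - introduced) / (corrected + missed)
    } else 0,
    bases_evaluated = n)
  if (!is.null(channel) && !is.null(channel_true)) {
    out$channel_max_abs_dev <- channel_deviation(channel, channel_true,
                                                 min_support)
  }
  structure(out, class = "denoise_eval")
}

#' @export
print.denoise_eval <- function(x, ...) {
  cat("<denoise_eval>\n")
  cat(sprintf("  errors: %d corrected, %d missed, %d introduced\n",
              x$errors_corrected, x$errors_missed, x$errors_introduced))
  cat(sprintf("  error rate: %.3g -> %.3g (net reduction %.1f%%)\n",
              x$noisy_error_rate, x$denoised_error_rate,
              100 * x$net_error_reduction))
  if (!is.null(x$channel_max_abs_dev)) {
    cat(sprintf("  channel recovery: max |dev| = %.4g\n",
                x$channel_max_abs_dev))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.denoise_eval <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Worst-case deviation between estimated and true channel
#'
#' @param channel A `channel_estimate` (its conditional counts N supply the
#'   support), or a bare 4 x 32 matrix (then `min_support` must be 0).
#' @param channel_true True 4 x 32 row-stochastic matrix.
#' @param min_support Only entries whose row and column of N both hold at
#'   least this many observations are compared.
#' @return Maximum absolute entrywise deviation over the supported entries
#'   (`NA` if none qualify).
#' @export
channel_deviation <- function(channel, channel_true, min_support = 0) {
  if (inherits(channel, "channel_estimate")) {
    Pi <- channel$Pi
    N <- channel$N
  } else {
    Pi <- channel
    N <- NULL
  }
  if (!all(dim(Pi) == c(4L, 32L)) || !all(dim(channel_true) == c(4L, 32L))) {
    stop("channel matrices must be 4 x 32")
  }
  keep <- matrix(TRUE, 4L, 32L)
  if (min_support > 0) {
    if (is.null(N)) stop("min_support needs a channel_estimate with counts")
    keep <- outer(rowSums(N) >= min_support, colSums(N) >= min_support, FUN = "&")
  }
  if (!any(keep)) return(NA_real_)
  max(abs(Pi - channel_true)[keep])
}

#' Fraction of variant-carrying read bases preserved by denoising
#'
#' A read base carries a planted variant when its truth base and its
#' emitted base both equal the site's alternate allele; the retention is
#' the fraction of such bases whose denoised base still equals that allele.
#' Quantifies whether the denoiser erodes true polymorphisms towards the
#' consensus.
#'
#' @param variants Variant tibble from [simulate_reads()].
#' @param truth Truth tibble from [simulate_reads()].
#' @param denoised Denoised reads tibble or SAM path.
#' @return A fraction in [0, 1]; `NaN` when no read base carries a
#'   variant.
#' @export
variant_retention <- function(variants, truth, denoised) {
  if (is.character(denoised)) denoised <- read_sam(denoised)
  if (nrow(variants) == 0L) return(NaN)
  alt <- variants$allele_b[match(truth$ref_pos, variants$ref_pos)]
  carrier <- !is.na(truth$ref_pos) & !is.na(alt) &
    truth$true_base == alt & truth$emitted_base == alt
  tr <- truth[carrier, ]
  if (nrow(tr) == 0L) return(NaN)
  alt <- alt[carrier]
  ri <- match(tr$read_name, denoised$qname)
  den_base <- substr(denoised$seq[ri], tr$read_index + 1L,
                     tr$read_index + 1L)
  mean(den_base == alt)
}
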