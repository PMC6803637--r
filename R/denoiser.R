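#' Phred score / confidence probability conversions
#'
#' A Phred score q corresponds to an error probability 10^(-q/10); the
#' confidence probability is its complement, p = 1 - 10^(-q/10). The
#' back-conversion rounds half away from zero and is capped at `q_cap` so
#' that p = 1 stays encodable.
#'
#' @param q Nonnegative Phred scores.
#' @param p Probabilities in [0, 1].
#' @param q_cap Maximum output Phred (default 41, the top of the Phred+33
#'   printable range used here).
#' @return `phred_to_prob`: probabilities; `prob_to_phred`: integer Phred
#'   scores.
#' @export
#' @examples
#' phred_to_prob(c(0, 10, 30))
#' prob_to_phred(c(0, 0.99, 1))
phred_to_prob <- function(q) {
  if (any(q < 0)) stop("negative Phred quality score")
  1 - 10^(-q / 10)
}

#' @rdname phred_to_prob
#' @export
prob_to_phred <- function(p, q_cap = 41L) {
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]")
  q <- ifelse(p >= 1, Inf, -10 * log10(1 - p))
  as.integer(pmin(floor(q + 0.5), q_cap))
}

#' Update a quality score after a denoising decision
#'
#' If the posterior mode agrees with the original base, the sequencer's
#' confidence and the denoiser's are averaged: q~ = prob_to_phred((p_i +
#' p_max)/2) with p_i = phred_to_prob(q_i). If the base was changed, the
#' original score no longer refers to the reported base and is replaced
#' outright: q~ = prob_to_phred(p_max).
#'
#' @param q_i Original Phred score(s).
#' @param p_max Posterior probability of the chosen base.
#' @param base_changed Logical: did the denoiser pick a different base?
#' @param q_cap Output cap.
#' @return Integer updated Phred score(s).
#' @export
#' @examples
#' update_quality(20, 0.99, FALSE)  # fixed point: stays 20
#' update_quality(10, 1.0, FALSE)   # mean 0.95 -> 13
#' update_quality(35, 0.9, TRUE)    # replaced -> 10
update_quality <- function(q_i, p_max, base_changed, q_cap = 41L) {
  stopifnot(all(p_max >= 0 & p_max <= 1))
  p_new <- ifelse(base_changed, p_max, (phred_to_prob(q_i) + p_max) / 2)
  prob_to_phred(p_new, q_cap)
}

#' Posterior distribution over the true base at one position
#'
#' The core channel-inversion rule: with m the 32-long counts vector of the
#' position's double-sided context and Pi the 4 x 32 channel estimate,
#' u = (Pi Pi^T)^{-1} Pi m estimates how often each true base generated
#' this context; negative components (sampling noise) are clamped to zero.
#' The element-wise product with the observed symbol's channel column,
#' pi_obs * u, re-weights by the likelihood of the actual observation, and
#' is normalized so its maximum can be read as a probability. A singular
#' system falls back to the least-squares pseudo-solution; an all-zero
#' product yields an invalid (unused) estimate.
#'
#' @param m Integer vector of 32 context counts.
#' @param channel A `channel_estimate` (or bare 4 x 32 row-stochastic
#'   matrix).
#' @param base,bin Observed base character and quality bin.
#' @param pinv_rcond Relative condition tolerance of the 4 x 4 solve.
#' @return List with `q_hat` (named length-4 probabilities), `u` (the
#'   clamped channel-inverted counts) and `valid`.
#' @export
dude_estimate <- function(m, channel, base, bin, pinv_rcond = 1e-10) {
  Pi <- if (inherits(channel, "channel_estimate")) channel$Pi else channel
  stopifnot(length(m) == 32L, all(dim(Pi) == c(4L, 32L)))
  G <- channel_inverse(Pi, pinv_rcond)
  if (is.null(G)) {
    return(list(q_hat = rep(NA_real_, 4L), u = rep(NA_real_, 4L),
                valid = FALSE))
  }
  u <- pmax(as.vector(G %*% m), 0)
  obs <- symbol_index(base, bin) + 1L
  q_raw <- Pi[, obs] * u
  tot <- sum(q_raw)
  if (!is.finite(tot) || tot <= 0) {
    return(list(q_hat = rep(NA_real_, 4L), u = u, valid = FALSE))
  }
  q_hat <- q_raw / tot
  names(q_hat) <- BASES
  list(q_hat = q_hat, u = u, valid = TRUE)
}

#' Denoiser configuration
#'
#' Bundles the tunable parameters: single-sided context length `k`,
#' majority threshold `t_m`, confidence gate `t_p` (denoising is attempted
#' only where phred_to_prob(q) < t_p), output quality cap, pseudo-inverse
#' tolerance, binning scheme, and whether statistics are pooled across
#' reference sequences.
#'
#' @param k Single-sided context length, >= 1.
#' @param t_m Majority threshold in [0.5, 1].
#' @param t_p Confidence gate in (0, 1).
#' @param q_cap Maximum output Phred score.
#' @param pinv_rcond Condition tolerance for the channel inversion.
#' @param scheme Quality binning scheme.
#' @param pooled_stats Pool channel/context statistics across reference
#'   sequences (default) or estimate per reference.
#' @return A `denoiser_config` list.
#' @export
denoiser_config <- function(k = 7L, t_m = 0.9, t_p = 0.9, q_cap = 41L,
                            pinv_rcond = 1e-10,
                            scheme = quality_scheme_illumina8(),
                            pooled_stats = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (t_m < 0.5 || t_m > 1) stop("t_m must lie in [0.5, 1]")
  if (t_p <= 0 || t_p >= 1) stop("t_p must lie in (0, 1)")
  structure(list(k = k, t_m = t_m, t_p = t_p, q_cap = as.integer(q_cap),
                 pinv_rcond = pinv_rcond, scheme = scheme,
                 pooled_stats = isTRUE(pooled_stats)),
            class = "denoiser_config")
}

#' Denoise a single read position
#'
#' The per-position rule, exposed for inspection and testing: gate on the
#' original confidence, look up the context's counts vector, invert the
#' channel, take the posterior mode (ties prefer the original base, then
#' A < C < G < T), and update the quality. Any degenerate step — missing
#' context, invalid posterior — leaves base and quality untouched.
#'
#' @param base,bin,q_i Observed base, its quality bin and raw Phred score.
#' @param left,right k-character context flanks.
#' @param store A `context_store`.
#' @param channel A `channel_estimate`.
#' @param config A [denoiser_config()].
#' @return List with `base`, `q`, and `attempted`.
#' @export
denoise_position <- function(base, bin, q_i, left, right, store, channel,
                             config = denoiser_config()) {
  stopifnot(base %in% BASES)
  if (phred_to_prob(q_i) >= config$t_p) {
    return(list(base = base, q = q_i, attempted = FALSE))
  }
  m <- lookup_context(store, left, right)
  if (is.null(m)) return(list(base = base, q = q_i, attempted = FALSE))
  est <- dude_estimate(m, channel, base, bin, config$pinv_rcond)
  if (!est$valid) return(list(base = base, q = q_i, attempted = FALSE))
  best <- base
  bestv <- est$q_hat[[base]]
  for (b in BASES) {
    if (est$q_hat[[b]] > bestv) { best <- b; bestv <- est$q_hat[[b]] }
  }
  list(base = best,
       q = update_quality(q_i, bestv, best != base, config$q_cap),
       attempted = TRUE)
}

#' Second-pass denoising of a reads tibble
#'
#' Applies [denoise_position()]'s rule (in compiled form) at every eligible
#' window of every primary read: centers must be read bases in A/C/G/T
#' below the confidence gate, flanks (sequence-estimate pads allowed) must
#' be unambiguous. Non-primary reads and reads without SEQ/QUAL pass
#' through unchanged; only SEQ and QUAL ever change, never lengths.
#'
#' @param reads Tibble of alignment records.
#' @param channel A `channel_estimate` from the first pass.
#' @param store A `context_store` from the first pass.
#' @param config A [denoiser_config()].
#' @return The reads tibble with updated `seq`/`qual`; attribute `report`
#'   holds a `denoise_report` of counters.
#' @export
denoise_reads <- function(reads, channel, store,
                          config = denoiser_config()) {
  stopifnot(inherits(channel, "channel_estimate"),
            inherits(store, "context_store"))
  G <- channel_inverse(channel$Pi, config$pinv_rcond)
  if (is.null(G)) stop("channel estimate is numerically degenerate")
  lut <- bin_lookup(config$scheme)
  attempt <- phred_to_prob(0:93) < config$t_p
  out <- reads
  el_idx <- which(reads$class == "primary_mapped" & reads$seq != "*" &
                    reads$qual != "*" & reads$cigar != "*")
  counters <- c(bases_examined = 0, bases_attempted = 0, bases_changed = 0,
                quals_updated = 0)
  reads_denoised <- 0L
  for (rn in unique(reads$rname[el_idx])) {
    idx <- el_idx[reads$rname[el_idx] == rn]
    xh <- channel$x_hat[[rn]]
    if (is.null(xh)) xh <- list(start = 1L, codes = integer())
    res <- denoise_reads_cpp(reads$pos[idx], reads$cigar[idx],
                             reads$seq[idx], reads$qual[idx], lut,
                             xh$codes, xh$start, config$k, store$keys,
                             store$counts, G, channel$Pi, attempt,
                             config$q_cap)
    touched <- res$seq != reads$seq[idx] | res$qual != reads$qual[idx]
    reads_denoised <- reads_denoised + sum(touched)
    out$seq[idx] <- res$seq
    out$qual[idx] <- res$qual
    counters <- counters + c(res$bases_examined, res$bases_attempted,
                             res$bases_changed, res$quals_updated)
  }
  attr(out, "header") <- attr(reads, "header")
  attr(out, "report") <- new_denoise_report(
    reads_total = nrow(reads), reads_denoised = reads_denoised,
    counters = counters, config = config)
  out
}

new_denoise_report <- function(reads_total, reads_denoised, counters,
                               config) {
  structure(list(
    reads_total = as.numeric(reads_total),
    reads_denoised = as.numeric(reads_denoised),
    bases_examined = as.numeric(counters[["bases_examined"]]),
    bases_attempted = as.numeric(counters[["bases_attempted"]]),
    bases_changed = as.numeric(counters[["bases_changed"]]),
    quals_updated = as.numeric(counters[["quals_updated"]]),
    config = config), class = "denoise_report")
}

#' @export
print.denoise_report <- function(x, ...) {
  cat("<denoise_report>\n")
  cat(sprintf("  reads: %.0f total, %.0f modified\n", x$reads_total,
              x$reads_denoised))
  cat(sprintf(
    "  bases: %.0f examined, %.0f attempted, %.0f changed, %.0f quality updates\n",
    x$bases_examined, x$bases_attempted, x$bases_changed, x$quals_updated))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.denoise_report <- function(x, ...) {
  tibble::tibble(reads_total = x$reads_total,
                 reads_denoised = x$reads_denoised,
                 bases_examined = x$bases_examined,
                 bases_attempted = x$bases_attempted,
                 bases_changed = x$bases_changed,
                 quals_updated = x$quals_updated)
}

#' Denoise a SAM file end to end
#'
#' Two passes over the file's primary alignments: the first estimates the
#' sequence (pileup majorities), the noise channel (row-normalized
#' conditional counts) and the double-sided context statistics; the second
#' rewrites each read's SEQ/QUAL through the channel-inverted posterior.
#' Secondary, supplementary and unmapped records are copied through
#' unchanged, and all fields other than SEQ/QUAL are preserved
#' byte-identically. A program-group line is appended to the header.
#'
#' @param input Path to the input SAM file.
#' @param output Path for the denoised SAM file.
#' @param config A [denoiser_config()].
#' @param report_path Optional path for a JSON summary report.
#' @return The `denoise_report`, printable, with
#'   `glance()`/`tidy()` support.
#' @export
denoise_sam <- function(input, output, config = denoiser_config(),
                        report_path = NULL) {
  reads <- read_sam(input)
  channel <- estimate_channel(reads, t_m = config$t_m,
                              scheme = config$scheme)
  store <- count_contexts(reads, channel, k = config$k)
  denoised <- denoise_reads(reads, channel, store, config)
  cl <- sprintf("aligndude denoise -i %s -o %s --k %d --tm %g --tp %g --qcap %d",
                input, output, config$k, config$t_m, config$t_p,
                config$q_cap)
  write_sam(denoised, output, pg_cl = cl)
  report <- attr(denoised, "report")
  if (!is.null(report_path)) {
    jsonlite::write_json(as.list(glance(report)), report_path,
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
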