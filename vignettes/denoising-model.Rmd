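---
title: "The two-pass channel-inversion model behind aligndude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-pass channel-inversion model behind aligndude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aligndude)
```

## The statistical model

`aligndude` treats substitution errors in aligned short reads as the output
of a discrete memoryless channel. The channel input is the unknown true
genomic base at each position, taking values in the nucleotide alphabet
A = {A, C, G, T}. The channel output couples the called base with the
quality score the sequencer attached to it. Because a ~42-letter Phred
alphabet would blow the coupled alphabet up to 168 symbols, quality scores
are first reduced to 8 bins (the familiar Illumina 8-level binning), giving
an output alphabet B = A × Q of 32 symbols. Coupling base and bin has a
second purpose: position-within-read error trends express themselves
through quality scores, so a quality-conditioned channel absorbs positional
effects without modelling read position explicitly.

The denoiser is a two-pass scheme in the DUDE (discrete universal denoiser)
family. It estimates everything it needs from the data itself — no external
reference sequence, no training set:

**Pass 1a — sequence estimate.** A pileup is taken over every covered
reference position using the alignment coordinates (CIGAR-aware: clipped
and inserted bases are excluded, deletions shift coordinates). A base whose
normalized pileup count is at least the majority threshold `t_m` is
declared the position's true base; positions without such a majority are
left undefined. At `t_m = 0.9` a heterozygous site with a ~50/50 allele mix
can essentially never qualify, which is precisely the point: differences
between haplotypes must not be mistaken for channel noise.

**Pass 1b — channel estimate.** At each majority position with true base
j, the position's 32 observed symbol counts accumulate into row j of a
4 × 32 conditional counts matrix N. Row-normalizing N gives the channel
estimate Π̂, the empirical distribution of observed (base, bin) symbols
given the true base.

**Pass 1c — context statistics.** For every read position whose center is
an unambiguous read base and whose k flanking bases on each side are
unambiguous, the counts vector m(l, r) of its double-sided context (l, r)
is incremented at the center's coupled symbol. Reads are first reduced to
*effective reads*: soft-clipped bases are dropped (they are exactly the
stretches the aligner distrusts), inserted bases are kept (an insertion may
be a real feature of the sample, and discarding it would shift every
downstream context). When a read begins or ends with a reference-mapped
base, up to k sequence-estimate bases are prepended/appended so that edge
positions still see full contexts; padding stops at the first position
where the estimate is undefined, and a side beginning with an insertion is
not padded (there is no defined reference neighbour to extend from).

**Pass 2 — denoising.** For each read base z with quality q below the
confidence gate (confidence p = 1 − 10^(−q/10) < `t_p`), the posterior
over the true base is estimated as

    q̂ ∝ π_(z,bin) ⊙ [(Π̂ Π̂ᵀ)⁻¹ Π̂ m(l, r)]

The bracket inverts the channel: it converts the observed-symbol histogram
m of this context into an estimate u of how often each *true* base carries
this context. The element-wise product with the observed symbol's channel
column then weights each candidate true base by the likelihood of having
observed exactly (z, bin). The base is replaced by the posterior mode, and
the quality score is updated from the posterior maximum p_max: averaged
with the sequencer's own confidence when the base is kept
(q̃ = −10 log10(1 − (p_i + p_max)/2)), replaced outright
(q̃ = −10 log10(1 − p_max)) when the base changes — once the denoiser
overrides the call, the sequencer's confidence in the old call carries no
information about the new one.

## Parameters

* `k` (default 7): single-sided context length, 14 context bases in total.
  Short contexts blur distinct loci together; long contexts fragment the
  counts until every histogram is nearly empty. k = 7 balances the two at
  typical short-read lengths and is the package default.
* `t_m` (default 0.9): pileup majority threshold, on normalized counts,
  boundary inclusive. High enough to exclude heterozygous sites, low
  enough to accept ordinary sequencing noise at moderate coverage.
* `t_p` (default 0.9): confidence gate. Bases with p ≥ t_p (Phred ≥ 10 at
  the default) are never touched — their base *and* quality pass through
  byte-identical. The comparison is strict (`p < t_p` attempts denoising),
  so the boundary case is treated conservatively.
* `q_cap` (default 41): output Phred ceiling. p_max = 1 would otherwise
  map to an infinite score; 41 keeps the Phred+33 encoding in its usual
  printable range.
* `pinv_rcond` (default 1e-10): relative singular-value cutoff for
  inverting Π̂Π̂ᵀ. The 4 × 4 system is solved by SVD throughout, which *is*
  the least-squares pseudo-solution when the matrix is singular, so the
  well-conditioned and degenerate paths share one code path.

## Numerical and design choices

* The raw product π ⊙ u is not a probability; q̂ is normalized to sum to 1
  before p_max is extracted, since p_max feeds the Phred back-conversion
  and must live in [0, 1]. Negative components of u (pure sampling noise
  pushed through the inverse) are clamped to zero first.
* Argmax ties prefer the original base, then A < C < G < T. Changing a
  base on a tie would be an arbitrary edit.
* Updated scores round half away from zero; log is log10 throughout, per
  the Phred convention.
* A base that never appears as a pileup majority leaves its row of N
  empty. That row of Π̂ falls back to uniform mass 1/8 over the base's own
  8 symbols — "no evidence of error" — keeping Π̂Π̂ᵀ invertible without
  inventing cross-base error rates.
* Degenerate positions — context never recorded (possible only through
  edge effects), q̂ summing to zero, a gate hit — leave base and quality
  both untouched, and the quality is not updated either: a quality update
  expresses the denoiser's posterior, and in these cases it has none.
* Contexts are counted in the orientation stored in the SAM record; no
  reverse-complement collapsing. This forgoes a factor-two of counts on
  opposite-strand reads but avoids asserting a strand symmetry the channel
  may not have.
* A read's own windows are included in the counts it is later denoised
  with; with tens of thousands of windows per context the self-count is
  immaterial, and excluding it would make the result depend on read order.
* Statistics (N, Π̂, contexts) are pooled across reference sequences by
  default; the sequence estimate is of course per-reference. Pileups are
  held per reference sequence to bound memory.
* Secondary, supplementary and unmapped records, and records with `*`
  SEQ/QUAL, contribute to no statistic and are never modified, but are
  copied through to the output so the file remains usable downstream.

## What the simulator emulates — and what it does not

`simulate_reads()` generates the conditions the estimator is designed for:
a uniform random reference, fixed-length reads at uniform positions,
per-base Phred scores drawn i.i.d. from a configurable profile (the
default has 70% of mass at q37/q41 and a few percent below q10, an
Illumina-like shape chosen so every bin receives data and a realistic
fraction of bases sits below the gate), and substitution errors at a
per-bin rate, uniform over the other three bases. Heterozygous SNVs are
planted by giving each read one of two haplotypes (50/50 by default,
configurable via `vaf`); soft-clip heads and 1-base insertions exercise
the CIGAR paths. Reads are emitted pre-aligned with correct POS/CIGAR.

Real data differ in ways the simulator deliberately omits: error rates
that depend on sequence context (e.g. after GGC motifs), alignment
artifacts near true indels, coverage waves, chimeric reads, PCR
duplicates. Passing the simulation-based tests therefore shows the
machinery is implemented correctly under its own model assumptions, not
that any particular improvement will materialize on a given real data set.

The default study conditions used in the test-suite properties and in
`scripts/acceptance.R` are 30× coverage of 50–100 kb references with
100-bp reads and 1% per-bin substitution error — large enough that channel
entries with ≥1000 supporting observations are estimated to well within
0.01, small enough to run comfortably on a laptop. Tiny instances (≤10
reads, k ≤ 2) are compared base-for-base against a straight-line
re-implementation of the whole procedure.

## Known limitations

* Substitutions only: indel errors are out of scope, and read lengths are
  never changed.
* Low-VAF somatic variants sit below any majority threshold's protection
  in the *context* statistics; at 50/50 the method is safe by
  construction, but rare alleles at low coverage can be eroded towards
  the consensus. The `vaf` parameter of the simulator exists to study
  exactly this.
* The quality-bin channel assumes scores are comparable across the run;
  mixed-run files with re-scaled quality tracks should be denoised
  per run.
* Single-threaded by design; the two passes stream the file but the
  context map for k = 7 can hold one entry per distinct 14-mer context in
  the data.
```{r example, eval = FALSE}
sim <- simulate_reads(ref_length = 2e4, coverage = 30, read_length = 100,
                      error_by_bin = 0.01, het_rate = 1e-3, seed = 1)
channel <- estimate_channel(sim$reads)
store <- count_contexts(sim$reads, channel, k = 7)
denoised <- denoise_reads(sim$reads, channel, store)
error_accounting(sim$truth, denoised,
                 channel = channel, channel_true = sim$channel_true,
                 min_support = 1000)
```
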