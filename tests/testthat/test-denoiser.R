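test_that("Phred/probability conversions obey the closed forms", {
  expect_equal(phred_to_prob(30L), 0.999)
  expect_equal(phred_to_prob(10L), 0.9)
  expect_equal(phred_to_prob(0L), 0)
  expect_equal(prob_to_phred(0.99), 20L)
  expect_equal(prob_to_phred(1.0), 41L)
  expect_equal(prob_to_phred(0), 0L)
  expect_equal(prob_to_phred(1.0, q_cap = 35L), 35L)
  expect_error(phred_to_prob(-3), "negative")
  expect_error(prob_to_phred(1.2), "probability")
})

test_that("quality updates average on agreement and replace on change", {
  expect_equal(update_quality(20L, 0.99, FALSE), 20L)     # fixed point
  expect_equal(update_quality(10L, 1.0, FALSE), 13L)      # mean 0.95
  expect_equal(update_quality(35L, 0.9, TRUE), 10L)       # replaced
  expect_equal(update_quality(10L, 1.0, TRUE), 41L)       # capped
  expect_equal(update_quality(c(20L, 10L), c(0.99, 1.0), c(FALSE, FALSE)),
               c(20L, 13L))
})

test_that("channel inversion recovers composition under a noiseless channel", {
  Pi <- matrix(0, 4, 32)
  for (j in 1:4) Pi[j, 8 * j] <- 1  # every base -> (base, bin8)
  m <- integer(32)
  m[8] <- 10L   # (A, bin8)
  m[16] <- 2L   # (C, bin8)
  est <- dude_estimate(m, Pi, base = "C", bin = 8L)
  expect_true(est$valid)
  expect_equal(est$u, c(10, 2, 0, 0), tolerance = 1e-9)
  expect_equal(unname(est$q_hat), c(0, 1, 0, 0), tolerance = 1e-12)

  empty <- dude_estimate(integer(32), Pi, base = "A", bin = 8L)
  expect_false(empty$valid)
})

test_that("channel inversion matches a dense pseudo-inverse oracle", {
  set.seed(4711)
  for (rep in 1:200) {
    Pi <- t(apply(matrix(rgamma(4 * 32, shape = 0.5), 4, 32), 1,
                  function(x) x / sum(x)))
    m <- rpois(32, lambda = 3)
    obs_base <- sample(c("A", "C", "G", "T"), 1)
    obs_bin <- sample(1:8, 1)
    est <- dude_estimate(m, Pi, obs_base, obs_bin)
    u_oracle <- as.vector(MASS::ginv(Pi %*% t(Pi)) %*% Pi %*% m)
    expect_equal(est$u, pmax(u_oracle, 0), tolerance = 1e-9)
    if (est$valid) {
      obs <- (match(obs_base, c("A", "C", "G", "T")) - 1) * 8 + obs_bin
      q_oracle <- Pi[, obs] * pmax(u_oracle, 0)
      expect_equal(unname(est$q_hat), q_oracle / sum(q_oracle),
                   tolerance = 1e-9)
    }
  }
})

test_that("denoise_position gates on confidence and breaks ties conservatively", {
  # one read carries a low-quality center so bin 2 symbols exist in N
  reads <- reads_tibble(sprintf("r%02d", 1:10), rep(50L, 10),
                        rep("3M", 10), rep("ACG", 10),
                        c(rep("III", 9), "I$I"))  # $ = Phred 3 -> bin 2
  ch <- estimate_channel(reads)
  st <- count_contexts(reads, ch, k = 1)
  # q40: p = 0.9999 >= t_p, untouched even though the context is known
  res <- denoise_position("C", 8L, 40L, "A", "G", st, ch,
                          denoiser_config(k = 1))
  expect_equal(res, list(base = "C", q = 40L, attempted = FALSE))
  # q5 attempts; the posterior is concentrated on the consensus base
  res <- denoise_position("C", 2L, 5L, "A", "G", st, ch,
                          denoiser_config(k = 1))
  expect_true(res$attempted)
  expect_equal(res$base, "C")
  expect_gt(res$q, 5L)
  # unknown context: untouched
  res <- denoise_position("C", 2L, 5L, "T", "T", st, ch,
                          denoiser_config(k = 1))
  expect_false(res$attempted)
})

test_that("config invariants are enforced", {
  expect_error(denoiser_config(k = 0), "positive")
  expect_error(denoiser_config(t_m = 0.4), "t_m")
  expect_error(denoiser_config(t_p = 1), "t_p")
})

test_that("full pipeline equals the straight-line oracle base-for-base", {
  # small instances spanning clips, insertions and low-quality tails
  cases <- list(
    list(ref = 200, cov = 6, rl = 40, eps = 0.08, k = 1, seed = 501),
    list(ref = 200, cov = 8, rl = 30, eps = 0.05, k = 2, seed = 502),
    list(ref = 150, cov = 10, rl = 25, eps = 0.1, k = 2, seed = 503))
  for (cs in cases) {
    sim <- simulate_reads(ref_length = cs$ref, coverage = cs$cov,
                          read_length = cs$rl, error_by_bin = cs$eps,
                          quality_profile = lowq_profile(),
                          clip_rate = 0.15, ins_rate = 0.15,
                          seed = cs$seed)
    cfg <- denoiser_config(k = cs$k)
    out <- run_pipeline(sim, cfg)
    orc <- oracle_pipeline(sim$reads, k = cs$k)
    expect_equal(out$denoised$seq, orc$seq)
    expect_equal(out$denoised$qual, orc$qual)
  }
})

test_that("a ten-read toy instance matches the oracle too", {
  sim <- simulate_reads(ref_length = 60, coverage = 5, read_length = 30,
                        error_by_bin = 0.1,
                        quality_profile = lowq_profile(), seed = 99)
  expect_lte(nrow(sim$reads), 10L)
  out <- run_pipeline(sim, denoiser_config(k = 2))
  orc <- oracle_pipeline(sim$reads, k = 2)
  expect_equal(out$denoised$seq, orc$seq)
  expect_equal(out$denoised$qual, orc$qual)
})

test_that("denoising output is invariant to read order", {
  sim <- simulate_reads(ref_length = 500, coverage = 10, read_length = 40,
                        error_by_bin = 0.05,
                        quality_profile = lowq_profile(), seed = 77)
  out1 <- run_pipeline(sim, denoiser_config(k = 2))$denoised
  perm <- withr::with_seed(1, sample(nrow(sim$reads)))
  shuffled <- sim$reads[perm, ]
  attr(shuffled, "header") <- attr(sim$reads, "header")
  out2 <- run_pipeline(list(reads = shuffled),
                       denoiser_config(k = 2))$denoised
  expect_equal(out2$seq, out1$seq[perm])
  expect_equal(out2$qual, out1$qual[perm])
})

test_that("high-confidence bases and record structure are never touched", {
  sim <- simulate_reads(ref_length = 800, coverage = 12, read_length = 40,
                        error_by_bin = 0.05,
                        quality_profile = lowq_profile(), clip_rate = 0.1,
                        seed = 31)
  cfg <- denoiser_config(k = 2)
  out <- run_pipeline(sim, cfg)$denoised
  expect_equal(nchar(out$seq), nchar(sim$reads$seq))
  expect_equal(nchar(out$qual), nchar(sim$reads$qual))
  for (i in seq_len(nrow(sim$reads))) {
    q_in <- utf8ToInt(sim$reads$qual[i]) - 33L
    gated <- phred_to_prob(q_in) >= cfg$t_p
    s_in <- strsplit(sim$reads$seq[i], "")[[1]]
    s_out <- strsplit(out$seq[i], "")[[1]]
    q_out <- utf8ToInt(out$qual[i]) - 33L
    expect_equal(s_out[gated], s_in[gated])
    expect_equal(q_out[gated], q_in[gated])
  }
})

test_that("non-primary reads pass through denoise_sam unchanged", {
  sim <- simulate_reads(ref_length = 400, coverage = 10, read_length = 40,
                        error_by_bin = 0.05,
                        quality_profile = lowq_profile(), seed = 13)
  input <- withr::local_tempfile(fileext = ".sam")
  extra <- c(sam_record(qname = "sec", flag = 256L, pos = 11L,
                        cigar = "5M", seq = "ACGTA", qual = "!!!!!"),
             sam_record(qname = "unm", flag = 4L, pos = 0L, cigar = "*",
                        seq = "ACGTA", qual = "!!!!!"))
  sim_write(sim, input)
  write(extra, input, append = TRUE)
  output <- withr::local_tempfile(fileext = ".sam")
  report <- denoise_sam(input, output, denoiser_config(k = 2))
  expect_s3_class(report, "denoise_report")
  expect_gt(report$bases_attempted, 0)
  expect_gt(report$quals_updated, 0)
  inl <- readLines(input)
  outl <- readLines(output)
  expect_equal(length(outl), length(inl) + 1L)  # the @PG line
  expect_equal(utils::tail(outl, 2), utils::tail(inl, 2))
  gl <- glance(report)
  expect_equal(gl$reads_total, nrow(sim$reads) + 2)
})

test_that("an empty SAM cannot seed a channel estimate", {
  path <- write_tiny_sam(character())
  out <- withr::local_tempfile(fileext = ".sam")
  expect_error(denoise_sam(path, out), "no pileup position|nonempty|empty")
  expect_false(file.exists(out))
})
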