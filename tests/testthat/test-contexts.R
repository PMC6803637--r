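test_that("effective reads drop clips, keep insertions, skip deletions", {
  r <- reads_tibble("a", 10L, "2S3M2S", "GGACTTT", "IIIIIII")
  eff <- effective_read(r[1, ])
  expect_equal(eff$base, c("A", "C", "T"))
  expect_equal(eff$ref_pos, 10:12)
  expect_equal(eff$read_index, 2:4)

  r <- reads_tibble("b", 10L, "2M1I2M", "ACGTA", "IIIII")
  eff <- effective_read(r[1, ])
  expect_equal(nrow(eff), 5L)
  expect_true(is.na(eff$ref_pos[3]))

  r <- reads_tibble("c", 10L, "5M", "ACNGT", "IIIII")
  eff <- effective_read(r[1, ])
  expect_equal(eff$base, c("A", "C", "N", "G", "T"))

  r <- reads_tibble("d", 10L, "2M1D2M", "ACGT", "IIII")
  eff <- effective_read(r[1, ])
  expect_equal(eff$ref_pos, c(10L, 11L, 13L, 14L))
})

test_that("padding draws contiguous sequence-estimate bases, up to k per side", {
  x_hat <- tibble::tibble(ref_pos = c(99L, 100L, 103L, 104L, 105L),
                          base = c("T", "G", "A", "C", "G"))
  eff <- effective_read(reads_tibble("a", 101L, "2M", "AC", "II")[1, ])
  padded <- pad_read(eff, x_hat, k = 2)
  expect_equal(padded$base, c("T", "G", "A", "C", "A", "C"))
  expect_equal(padded$origin, c("pad", "pad", "read", "read", "pad", "pad"))
  expect_equal(padded$ref_pos, 99:104)

  # undefined estimate at 98 truncates the left pad to one base
  x_hat2 <- tibble::tibble(ref_pos = c(97L, 99L, 100L),
                           base = c("A", "T", "G"))
  padded2 <- pad_read(eff, x_hat2, k = 2)
  expect_equal(sum(padded2$origin == "pad"), 2L)
  expect_equal(padded2$base[1:2], c("T", "G"))

  # a read starting with an insertion gets no left pad
  eff_ins <- effective_read(reads_tibble("b", 101L, "1I2M", "GAC",
                                         "III")[1, ])
  padded3 <- pad_read(eff_ins, x_hat, k = 2)
  expect_equal(padded3$origin[1], "read")
})

test_that("context counting reproduces the tiny worked examples", {
  ch <- estimate_channel(reads_tibble(
    qname = sprintf("r%d", 1:3), pos = rep(500L, 3), cigar = rep("3M", 3),
    seq = rep("ACG", 3), qual = rep("III", 3)))
  # k=1, single read ACG, no pads available away from ref 500
  reads <- reads_tibble("a", 5L, "3M", "ACG", "III")
  st <- count_contexts(reads, ch, k = 1)
  expect_equal(unname(lookup_context(st, "A", "G")["C:bin8"]), 1L)
  expect_equal(sum(st$counts), 1L)

  two <- reads_tibble(c("a", "b"), c(5L, 5L), rep("3M", 2),
                      rep("ACG", 2), rep("III", 2))
  st2 <- count_contexts(two, ch, k = 1)
  expect_equal(unname(lookup_context(st2, "A", "G")["C:bin8"]), 2L)

  amb <- reads_tibble("a", 5L, "3M", "ANG", "III")
  st3 <- count_contexts(amb, ch, k = 1)
  expect_equal(sum(st3$counts), 0L)
})

test_that("padded reads contribute their edge windows through the estimate", {
  # consensus AAAAACGTAAAAA at 30x so every position has a majority
  body <- "AAAAACGTAAAAA"
  reads <- reads_tibble(sprintf("c%02d", 1:30), rep(1L, 30),
                        rep(sprintf("%dM", nchar(body)), 30),
                        rep(body, 30), rep(strrep("I", nchar(body)), 30))
  ch <- estimate_channel(reads)
  # one extra short read entirely inside the consensus
  probe <- reads_tibble("p", 6L, "3M", "CGT", "III")
  st_pad <- count_contexts(rbind(probe, reads[0, ]), ch, k = 2)
  # every one of the 3 centers has a full double-sided context via padding
  expect_equal(sum(st_pad$counts), 3L)
  expect_equal(unname(lookup_context(st_pad, "AA", "GT")["C:bin8"]), 1L)
  expect_equal(unname(lookup_context(st_pad, "AC", "TA")["G:bin8"]), 1L)
  expect_equal(unname(lookup_context(st_pad, "CG", "AA")["T:bin8"]), 1L)
})

test_that("window totals match a brute-force scan; padding only adds windows", {
  sim <- simulate_reads(ref_length = 300, coverage = 10, read_length = 30,
                        error_by_bin = 0.05,
                        quality_profile = lowq_profile(), clip_rate = 0.2,
                        ins_rate = 0.2, seed = 19)
  ch <- estimate_channel(sim$reads)
  for (k in c(1, 2, 3)) {
    st <- count_contexts(sim$reads, ch, k = k)
    orc <- oracle_pipeline(sim$reads, k = k)
    okeys <- ls(orc$store)
    expect_setequal(st$keys, okeys)
    same <- vapply(okeys, function(key) {
      identical(as.numeric(lookup_context(st, substr(key, 1, k),
                                          substr(key, k + 1, 2 * k))),
                as.numeric(orc$store[[key]]))
    }, logical(1))
    expect_true(all(same))
    # padding adds at most 2k windows per read, and never removes counts
    empty <- structure(list(N = ch$N, Pi = ch$Pi,
                            x_hat = list(sim1 = list(start = 1L,
                                                     codes = integer())),
                            t_m = ch$t_m, scheme = ch$scheme),
                       class = "channel_estimate")
    st_nopad <- count_contexts(sim$reads, empty, k = k)
    expect_lte(sum(st$counts),
               sum(st_nopad$counts) + 2 * k * nrow(sim$reads))
    expect_gte(sum(st$counts), sum(st_nopad$counts))
    mono <- vapply(st_nopad$keys, function(key) {
      all(lookup_context(st, substr(key, 1, k),
                         substr(key, k + 1, 2 * k)) >=
            lookup_context(st_nopad, substr(key, 1, k),
                           substr(key, k + 1, 2 * k)))
    }, logical(1))
    expect_true(all(mono))
  }
})
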