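# Straight-line reference implementations, written independently of the
# package internals (own CIGAR walker, own binning, dense linear algebra via
# MASS::ginv). Used as oracles for the compiled two-pass pipeline.

OB <- c("A", "C", "G", "T")

oracle_bin <- function(q) {
  hi <- c(1, 9, 19, 24, 29, 34, 39, Inf)
  which(q <= hi)[1]
}

# Expand a CIGAR into per-base records by scanning the string directly.
oracle_walk <- function(cigar, pos) {
  out <- list()
  num <- 0L
  qi <- 0L
  rp <- pos
  for (ch in strsplit(cigar, "")[[1]]) {
    if (grepl("[0-9]", ch)) {
      num <- num * 10L + as.integer(ch)
      next
    }
    for (t in seq_len(num)) {
      if (ch %in% c("M", "=", "X")) {
        out[[length(out) + 1L]] <- list(qi = qi, rp = rp, op = ch)
        qi <- qi + 1L; rp <- rp + 1L
      } else if (ch %in% c("I", "S")) {
        out[[length(out) + 1L]] <- list(qi = qi, rp = NA, op = ch)
        qi <- qi + 1L
      } else if (ch %in% c("D", "N")) {
        out[[length(out) + 1L]] <- list(qi = NA, rp = rp, op = ch)
        rp <- rp + 1L
      }
    }
    num <- 0L
  }
  out
}

# Effective read: drop soft clips, keep insertions, then pad both ends with
# contiguous defined sequence-estimate bases.
oracle_effective <- function(read, k, xhat) {
  sq <- strsplit(read$seq, "")[[1]]
  qs <- utf8ToInt(read$qual) - 33L
  eff <- list()
  for (w in oracle_walk(read$cigar, read$pos)) {
    if (is.na(w$qi) || w$op == "S") next
    eff[[length(eff) + 1L]] <- list(base = sq[w$qi + 1L],
                                    bin = oracle_bin(qs[w$qi + 1L]),
                                    q = qs[w$qi + 1L], ri = w$qi,
                                    rp = if (is.na(w$rp)) NA else w$rp,
                                    pad = FALSE)
  }
  if (length(eff) == 0L) return(eff)
  key <- function(p) paste(read$rname, p)
  if (!is.na(eff[[1L]]$rp)) {
    pre <- list()
    for (t in seq_len(k)) {
      b <- xhat[[key(eff[[1L]]$rp - t)]]
      if (is.null(b)) break
      pre[[length(pre) + 1L]] <- list(base = b, bin = NA, q = NA, ri = NA,
                                      rp = eff[[1L]]$rp - t, pad = TRUE)
    }
    eff <- c(rev(pre), eff)
  }
  last <- eff[[length(eff)]]
  if (!is.na(last$rp)) {
    for (t in seq_len(k)) {
      b <- xhat[[key(last$rp + t)]]
      if (is.null(b)) break
      eff[[length(eff) + 1L]] <- list(base = b, bin = NA, q = NA, ri = NA,
                                      rp = last$rp + t, pad = TRUE)
    }
  }
  eff
}

# The whole two-pass procedure on a reads tibble; returns the denoised
# seq/qual strings plus the intermediate statistics for inspection.
oracle_pipeline <- function(reads, k, t_m = 0.9, t_p = 0.9, q_cap = 41L) {
  prim <- reads[bitwAnd(reads$flag, 4L + 256L + 2048L) == 0L &
                  reads$seq != "*" & reads$qual != "*" &
                  reads$cigar != "*", , drop = FALSE]
  # pass 1a: pileup
  pile <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(prim))) {
    sq <- strsplit(prim$seq[i], "")[[1]]
    qs <- utf8ToInt(prim$qual[i]) - 33L
    for (w in oracle_walk(prim$cigar[i], prim$pos[i])) {
      if (is.na(w$qi) || !w$op %in% c("M", "=", "X")) next
      b <- sq[w$qi + 1L]
      if (!b %in% OB) next
      key <- paste(prim$rname[i], w$rp)
      v <- if (is.null(pile[[key]])) numeric(32) else pile[[key]]
      s <- (match(b, OB) - 1L) * 8L + oracle_bin(qs[w$qi + 1L])
      v[s] <- v[s] + 1
      pile[[key]] <- v
    }
  }
  # pass 1b: majority bases -> sequence estimate and conditional counts
  N <- matrix(0, 4, 32)
  xhat <- list()
  for (key in ls(pile)) {
    v <- pile[[key]]
    bc <- vapply(1:4, function(j) sum(v[(8 * j - 7):(8 * j)]), numeric(1))
    maj <- which(bc / sum(bc) >= t_m)
    if (sum(bc) > 0 && length(maj) == 1L) {
      N[maj, ] <- N[maj, ] + v
      xhat[[key]] <- OB[maj]
    }
  }
  Pi <- matrix(0, 4, 32)
  for (j in 1:4) {
    if (sum(N[j, ]) > 0) Pi[j, ] <- N[j, ] / sum(N[j, ])
    else Pi[j, (8 * j - 7):(8 * j)] <- 1 / 8
  }
  # pass 1c: context counts over padded effective reads
  store <- new.env(parent = emptyenv())
  effs <- lapply(seq_len(nrow(prim)), function(i)
    oracle_effective(prim[i, ], k, xhat))
  for (eff in effs) {
    n <- length(eff)
    if (n < 2 * k + 1) next
    for (c in (k + 1):(n - k)) {
      ce <- eff[[c]]
      if (ce$pad || !ce$base %in% OB) next
      flanks <- eff[(c - k):(c + k)][-(k + 1)]
      if (!all(vapply(flanks, function(e) e$base %in% OB, logical(1)))) next
      key <- paste0(vapply(eff[(c - k):(c + k)][-(k + 1)], `[[`, "",
                           "base"), collapse = "")
      v <- if (is.null(store[[key]])) numeric(32) else store[[key]]
      s <- (match(ce$base, OB) - 1L) * 8L + ce$bin
      v[s] <- v[s] + 1
      store[[key]] <- v
    }
  }
  # pass 2: channel inversion position by position
  G <- MASS::ginv(Pi %*% t(Pi)) %*% Pi
  out_seq <- reads$seq
  out_qual <- reads$qual
  prim_rows <- match(prim$qname, reads$qname)
  for (i in seq_len(nrow(prim))) {
    eff <- effs[[i]]
    n <- length(eff)
    sq <- strsplit(prim$seq[i], "")[[1]]
    qs <- utf8ToInt(prim$qual[i]) - 33L
    for (c in seq_len(n)) {
      ce <- eff[[c]]
      if (ce$pad || !ce$base %in% OB) next
      p_i <- 1 - 10^(-ce$q / 10)
      if (p_i >= t_p) next
      if (c - k < 1 || c + k > n) next
      win <- eff[(c - k):(c + k)][-(k + 1)]
      if (!all(vapply(win, function(e) e$base %in% OB, logical(1)))) next
      key <- paste0(vapply(win, `[[`, "", "base"), collapse = "")
      m <- store[[key]]
      if (is.null(m)) next
      u <- pmax(as.vector(G %*% m), 0)
      obs <- (match(ce$base, OB) - 1L) * 8L + ce$bin
      qraw <- Pi[, obs] * u
      if (sum(qraw) <= 0) next
      qhat <- qraw / sum(qraw)
      best <- match(ce$base, OB)
      for (b in 1:4) if (qhat[b] > qhat[best]) best <- b
      p_max <- qhat[best]
      changed <- OB[best] != ce$base
      p_new <- if (changed) p_max else (p_i + p_max) / 2
      qt <- if (p_new >= 1) q_cap else
        min(q_cap, max(0L, floor(-10 * log10(1 - p_new) + 0.5)))
      sq[ce$ri + 1L] <- OB[best]
      qs[ce$ri + 1L] <- qt
    }
    out_seq[prim_rows[i]] <- paste(sq, collapse = "")
    out_qual[prim_rows[i]] <- intToUtf8(qs + 33L)
  }
  list(seq = out_seq, qual = out_qual, N = N, Pi = Pi, xhat = xhat,
       store = store)
}
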