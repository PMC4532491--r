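# Independent oracles used by unit and acceptance tests. These re-derive
# expected values by brute force (full enumeration / regular expressions)
# and share no code with the implementation paths they check.

# Overlapping WGCW matches via a lookahead regex.
oracle_count_wgcw <- function(seq) {
  m <- gregexpr("(?=[AT]GC[AT])", seq, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# Exhaustive tandem-repeat caller: enumerates every (start, end, period)
# segment, applies the same +2/-7 indel-free scoring, selects disjoint
# segments per period by (score desc, end asc, start asc), drops regions
# shorter than two motif copies, then resolves across periods by
# (score desc, period asc, start asc).
oracle_find_repeats <- function(seq, min_score, period_max = 12L,
                                match = 2, mismatch = -7) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  cands <- list()
  for (p in seq_len(period_max)) {
    if (n < 2 * p) next
    len <- n - p
    s <- numeric(len)
    for (j in seq_len(len)) {
      ok <- chars[j + p] == chars[j] && chars[j] != "N" && chars[j + p] != "N"
      s[j] <- if (ok) match else mismatch
    }
    # all segments and their scores
    segs <- list()
    for (a in seq_len(len)) {
      acc <- 0
      for (b in a:len) {
        acc <- acc + s[b]
        segs[[length(segs) + 1]] <- c(a = a, b = b, score = acc)
      }
    }
    segs <- do.call(rbind, segs)
    segs <- segs[segs[, "score"] >= min_score, , drop = FALSE]
    chosen <- list()
    while (nrow(segs) > 0) {
      ord <- order(-segs[, "score"], segs[, "b"], segs[, "a"])
      top <- segs[ord[1], ]
      chosen[[length(chosen) + 1]] <- top
      keep <- segs[, "b"] < top[["a"]] | segs[, "a"] > top[["b"]]
      segs <- segs[keep, , drop = FALSE]
    }
    for (ch in chosen) {
      reg_start <- ch[["a"]] - 1
      reg_end <- p + ch[["b"]]
      if (reg_end - reg_start >= 2 * p) {
        cands[[length(cands) + 1]] <-
          c(start = reg_start, end = reg_end, period = p,
            score = ch[["score"]])
      }
    }
  }
  if (length(cands) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          period = integer(), score = numeric()))
  }
  d <- tibble::as_tibble(do.call(rbind, cands))
  d <- d[order(-d$score, d$period, d$start), ]
  keep <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (d$start[i] < d$end[j] && d$end[i] > d$start[j]) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  d <- d[keep, ]
  d <- d[order(d$start), ]
  tibble::tibble(start = as.integer(d$start), end = as.integer(d$end),
                 period = as.integer(d$period), score = d$score)
}
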