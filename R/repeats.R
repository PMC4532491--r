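#' Count WGCW hotspot motifs in a sequence
#'
#' Scans the plus strand for all (possibly overlapping) matches of the
#' degenerate AID hotspot motif WGCW (W = A or T). The motif is
#' self-complementary as a degenerate pattern, so the reverse-complement
#' scan yields the same count. `N` never matches.
#'
#' @param seq A character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @return A list with `count` and 0-based match `positions`.
#' @export
count_wgcw <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (length(seq) < 4) return(list(count = 0L, positions = integer()))
  m <- Biostrings::matchPattern("WGCW", seq,
                                fixed = c(pattern = FALSE, subject = TRUE))
  list(count = length(m), positions = Biostrings::start(m) - 1L)
}

# Internal: per-period match/mismatch score vector. Position j (1-based in
# the vector) scores seq[p + j] against seq[j]; N always mismatches.
period_scores <- function(chars, p, match, mismatch) {
  n <- length(chars)
  if (n < p + 1) return(numeric(0))
  a <- chars[(p + 1):n]
  b <- chars[1:(n - p)]
  ifelse(a == b & a != "N" & b != "N", match, mismatch)
}

# Internal: recursive maximal-scoring segment decomposition (Kadane-style,
# vectorised). Returns disjoint segments [a, b] (1-based, inclusive, in v)
# with score >= min_score; selection order: score desc, then smallest end,
# then smallest start.
max_segments <- function(v, min_score) {
  n <- length(v)
  if (n == 0) return(list())
  P <- c(0, cumsum(v))
  cm <- cummin(P[1:n])
  M <- P[2:(n + 1)] - cm
  b <- which.max(M)
  score <- M[b]
  if (score < min_score) return(list())
  a <- which.min(P[1:b])          # P[a] minimal => segment starts at a
  seg <- list(list(start = a, end = b, score = score))
  left <- if (a > 1) max_segments(v[1:(a - 1)], min_score) else list()
  right <- if (b < n) lapply(max_segments(v[(b + 1):n], min_score),
                             function(s) { s$start <- s$start + b
                                           s$end <- s$end + b; s })
           else list()
  c(left, seg, right)
}

# Internal: fraction of dinucleotide steps equal to CA/AC/TG/GT.
ca_step_fraction <- function(chars) {
  n <- length(chars)
  if (n < 2) return(0)
  steps <- paste0(chars[-n], chars[-1])
  mean(steps %in% c("CA", "AC", "TG", "GT"))
}

# Internal: majority-base consensus per phase class.
phase_consensus <- function(chars, p) {
  paste(vapply(seq_len(p), function(k) {
    obs <- chars[seq.int(k, length(chars), by = p)]
    obs <- obs[obs != "N"]
    if (length(obs) == 0) return("N")
    tab <- table(factor(obs, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]
  }, character(1)), collapse = "")
}

#' Find tandem repeats by indel-free periodic alignment
#'
#' For each period p up to `period_max`, positions are scored `match` when
#' the base equals the base p positions earlier and `mismatch` otherwise
#' (no gap states; N always mismatches). Maximal-scoring contiguous
#' segments with score at least `min_score` become candidate repeats
#' spanning `[segment_start - p, segment_end)`; candidates overlapping
#' across periods are resolved by keeping the highest score, ties to the
#' smallest period. A pure array of a period-p motif of length L scores
#' exactly `match * (L - p)`.
#'
#' @param seq Character string or [Biostrings::DNAString].
#' @param min_score Minimum alignment score for a call.
#' @param period_max Largest period searched (default 12, covering both the
#'   WGCW pentamer and CA dinucleotide classes).
#' @param match,mismatch Per-position scores (defaults +2 / -7).
#' @return A tibble with one row per repeat: `start`, `end` (0-based
#'   half-open), `period`, `consensus`, `copy_number`, `score`,
#'   `ca_fraction`, `wgcw_count`, `wgcw_density` (per 100 bp) and
#'   `repeat_class`.
#' @export
find_tandem_repeats <- function(seq, min_score, period_max = 12L,
                                match = 2, mismatch = -7) {
  stopifnot(min_score > 0)
  if (!is.character(seq)) seq <- as.character(seq)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  empty <- tibble(start = integer(), end = integer(), period = integer(),
                  consensus = character(), copy_number = numeric(),
                  score = numeric(), ca_fraction = numeric(),
                  wgcw_count = integer(), wgcw_density = numeric(),
                  repeat_class = character())
  cands <- purrr::map_dfr(seq_len(period_max), function(p) {
    if (n < 2 * p) return(tibble())
    v <- period_scores(chars, p, match, mismatch)
    segs <- max_segments(v, min_score)
    if (length(segs) == 0) return(tibble())
    out <- tibble(
      start = vapply(segs, function(s) s$start - 1L, numeric(1)),
      end = vapply(segs, function(s) p + s$end, numeric(1)),
      period = p,
      score = vapply(segs, `[[`, numeric(1), "score"))
    out[out$end - out$start >= 2 * p, ]   # region at least two motif copies
  })
  if (nrow(cands) == 0) return(empty)
  cands <- cands[order(-cands$score, cands$period, cands$start), ]
  keep <- logical(nrow(cands))
  taken <- IRanges::IRanges()
  for (i in seq_len(nrow(cands))) {
    r <- IRanges::IRanges(cands$start[i] + 1L, cands$end[i])
    if (length(taken) == 0 ||
        sum(IRanges::countOverlaps(r, taken)) == 0) {
      keep[i] <- TRUE
      taken <- c(taken, r)
    }
  }
  reps <- cands[keep, ]
  reps <- reps[order(reps$start), ]
  info <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
    region <- chars[(reps$start[i] + 1):reps$end[i]]
    len <- length(region)
    wg <- count_wgcw(paste(region, collapse = ""))
    tibble(consensus = phase_consensus(region, reps$period[i]),
           copy_number = len / reps$period[i],
           ca_fraction = ca_step_fraction(region),
           wgcw_count = wg$count,
           wgcw_density = wg$count / len * 100)
  })
  reps <- dplyr::bind_cols(reps, info)
  reps$repeat_class <- classify_repeat(reps$ca_fraction, reps$wgcw_density)
  reps$start <- as.integer(reps$start)
  reps$end <- as.integer(reps$end)
  reps[c("start", "end", "period", "consensus", "copy_number", "score",
         "ca_fraction", "wgcw_count", "wgcw_density", "repeat_class")]
}

#' Classify a tandem repeat as CA, WGCW or OTHER
#'
#' A repeat is `CA` when at least 90% of its dinucleotide steps are
#' CA/AC/TG/GT; otherwise `WGCW` when it holds at least 2.0 WGCW motifs per
#' 100 bp; otherwise `OTHER`. CA takes precedence, so no repeat is both.
#'
#' @param ca_fraction Fraction of CA/TG dinucleotide steps.
#' @param wgcw_density WGCW motifs per 100 bp.
#' @param ca_min,wgcw_density_min Class thresholds (defaults 0.90 and 2.0).
#' @return Character vector of classes.
#' @export
classify_repeat <- function(ca_fraction, wgcw_density,
                            ca_min = 0.90, wgcw_density_min = 2.0) {
  dplyr::case_when(
    ca_fraction >= ca_min ~ "CA",
    wgcw_density >= wgcw_density_min ~ "WGCW",
    TRUE ~ "OTHER")
}

#' Summarise tandem-repeat content of called sites
#'
#' Runs [find_tandem_repeats()] twice over each site's sequence — once at
#' `min_score_wgcw` (default 100) for the WGCW classification pass and once
#' at `min_score_ca` (default 60) for the CA pass — and totals the repeat
#' length per class. A site "has" WGCW repeats when their summed length
#' reaches `wgcw_bp` (default 400 bp) and CA repeats at `ca_bp` (default
#' 100 bp).
#'
#' @param sites Site tibble with extended intervals.
#' @param genome [Biostrings::DNAStringSet] covering the sites.
#' @param min_score_wgcw,min_score_ca Pass-specific minimum scores.
#' @param wgcw_bp,ca_bp Site-level length thresholds in bp.
#' @param interval `"extended"` (default) or `"window"`.
#' @return `sites` with `wgcw_repeat_bp`, `ca_repeat_bp`, `other_repeat_bp`,
#'   `max_wgcw_density`, `has_wgcw`, `has_ca`, `has_either` added.
#' @export
summarize_site_repeats <- function(sites, genome, min_score_wgcw = 100,
                                   min_score_ca = 60, wgcw_bp = 400,
                                   ca_bp = 100,
                                   interval = c("extended", "window")) {
  interval <- match.arg(interval)
  se <- site_interval(sites, interval)
  res <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    s <- site_sequence(genome, sites$chrom[i], se$start[i], se$end[i])
    pass_w <- find_tandem_repeats(s, min_score = min_score_wgcw)
    pass_c <- find_tandem_repeats(s, min_score = min_score_ca)
    wg <- pass_w[pass_w$repeat_class == "WGCW", ]
    ca <- pass_c[pass_c$repeat_class == "CA", ]
    ot <- pass_w[pass_w$repeat_class == "OTHER", ]
    tibble(wgcw_repeat_bp = sum(wg$end - wg$start),
           ca_repeat_bp = sum(ca$end - ca$start),
           other_repeat_bp = sum(ot$end - ot$start),
           max_wgcw_density = if (nrow(pass_w)) max(pass_w$wgcw_density) else 0)
  })
  sites <- dplyr::bind_cols(sites, res)
  sites$has_wgcw <- sites$wgcw_repeat_bp >= wgcw_bp
  sites$has_ca <- sites$ca_repeat_bp >= ca_bp
  sites$has_either <- sites$has_wgcw | sites$has_ca
  sites
}

site_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome) ||
      end > Biostrings::width(genome[names(genome) == chrom])[1]) {
    abort(sprintf("Sequence unavailable for interval %s:%d-%d.", chrom, start, end))
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Accumulation curve over per-site values
#'
#' Fraction of sites whose value meets or exceeds each threshold — the
#' non-increasing step function used to display repeat lengths and WGCW
#' densities across site sets.
#'
#' @param values Per-site lengths or densities.
#' @param thresholds Thresholds to evaluate; defaults to `0` plus the sorted
#'   distinct values.
#' @return Tibble with `threshold` and `fraction`.
#' @export
accumulation_curve <- function(values, thresholds = NULL) {
  stopifnot(length(values) >= 1)
  if (is.null(thresholds)) thresholds <- sort(unique(c(0, values)))
  tibble(threshold = thresholds,
         fraction = vapply(thresholds, function(t) mean(values >= t), numeric(1)))
}

#' Tandem-repeat background over matched random genomic intervals
#'
#' Draws `n_intervals` random intervals matched to a length and chromosome
#' distribution (taken from a site set, or uniform 2-kb intervals with
#' chromosomes weighted by length when no sites are given), summarises each
#' with [summarize_site_repeats()], and reports the fraction carrying
#' site-level WGCW and CA repeats plus the mean WGCW density within
#' detected repeats.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param n_intervals Number of random intervals (default 10000).
#' @param sites Optional site tibble supplying the length/chromosome
#'   distribution.
#' @param length_default Interval length when no sites are given.
#' @param seed Optional integer seed for reproducibility.
#' @inheritParams summarize_site_repeats
#' @return A list with `summary` (one-row tibble: `wgcw_fraction`,
#'   `ca_fraction`, `mean_wgcw_density`, `n_intervals`) and `intervals`
#'   (per-interval tibble).
#' @export
genome_background <- function(genome, n_intervals = 10000L, sites = NULL,
                              length_default = 2000L, seed = NULL,
                              min_score_wgcw = 100, min_score_ca = 60,
                              wgcw_bp = 400, ca_bp = 100) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- genome_sizes(genome)
  lens <- if (!is.null(sites)) {
    se <- site_interval(sites, "extended")
    se$end - se$start
  } else rep(length_default, 1L)
  chrs <- if (!is.null(sites)) sites$chrom else NULL
  draw_chrom <- function(n) {
    if (!is.null(chrs)) sample(chrs, n, replace = TRUE)
    else sample(sizes$chrom, n, replace = TRUE, prob = sizes$size)
  }
  lookup <- chrom_size_lookup(sizes)
  draw_len <- function(n) lens[sample.int(length(lens), n, replace = TRUE)]
  chrom <- draw_chrom(n_intervals)
  len <- draw_len(n_intervals)
  bad <- len > lookup[chrom]
  while (any(bad)) {        # resample draws whose length exceeds the chromosome
    chrom[bad] <- draw_chrom(sum(bad))
    len[bad] <- draw_len(sum(bad))
    bad <- len > lookup[chrom]
  }
  start <- floor(runif(n_intervals, 0, lookup[chrom] - len + 1))
  iv <- tibble(chrom = chrom, start = as.integer(start),
               end = as.integer(start + len))
  iv <- summarize_site_repeats(iv, genome, min_score_wgcw, min_score_ca,
                               wgcw_bp, ca_bp, interval = "window")
  dens <- iv$max_wgcw_density[iv$wgcw_repeat_bp + iv$ca_repeat_bp +
                                iv$other_repeat_bp > 0]
  list(summary = tibble(wgcw_fraction = mean(iv$has_wgcw),
                        ca_fraction = mean(iv$has_ca),
                        mean_wgcw_density = if (length(dens)) mean(dens) else 0,
                        n_intervals = n_intervals),
       intervals = iv)
}
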