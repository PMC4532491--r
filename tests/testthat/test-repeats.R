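test_that("WGCW counting matches the printed examples", {
  w <- count_wgcw("AGCAAGCAAGCA")
  expect_equal(w$count, 3L)
  expect_equal(w$positions, c(0L, 4L, 8L))
  expect_equal(count_wgcw("CCCCGGGG")$count, 0L)
  # 20 tandem CAGCA copies: 20 matches, i.e. 20 per 100 bp
  w2 <- count_wgcw(strrep("CAGCA", 20))
  expect_equal(w2$count, 20L)
  # N never matches
  expect_equal(count_wgcw("AGCNAGCA")$count, 1L)
})

test_that("WGCW is self-complementary as a degenerate pattern", {
  seqs <- random_dna(50, 120, seed = 21)
  for (s in seqs) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(count_wgcw(s)$count, count_wgcw(rc)$count)
  }
})

test_that("WGCW counter equals the regex oracle on random sequences", {
  seqs <- random_dna(500, 200, seed = 22)
  impl <- vapply(seqs, function(s) count_wgcw(s)$count, integer(1),
                 USE.NAMES = FALSE)
  orac <- vapply(seqs, oracle_count_wgcw, integer(1), USE.NAMES = FALSE)
  expect_identical(impl, orac)
})

test_that("pure arrays score 2(L - p) and are reported once", {
  # (CA)30: period 2, score 2 x 58 = 116, full-length region, pure CA steps
  r <- find_tandem_repeats(strrep("CA", 30), min_score = 60)
  expect_equal(nrow(r), 1)
  expect_equal(r$period, 2L)
  expect_equal(r$score, 116)
  expect_equal(c(r$start, r$end), c(0L, 60L))
  expect_equal(r$ca_fraction, 1)
  expect_equal(r$repeat_class, "CA")
  # (CAGCA)100: period 5, score 2 x 495 = 990, WGCW class
  r2 <- find_tandem_repeats(strrep("CAGCA", 100), min_score = 100)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$period, 5L)
  expect_equal(r2$score, 990)
  expect_equal(r2$wgcw_count, 100L)
  expect_equal(r2$repeat_class, "WGCW")
  # general pure-array property over assorted motifs
  for (m in c("A", "AT", "ATT", "CAGG", "GAGCT")) {
    L <- nchar(m) * 12
    r3 <- find_tandem_repeats(strrep(m, 12), min_score = 10)
    expect_equal(nrow(r3), 1)
    expect_equal(r3$score, 2 * (L - nchar(m)))
  }
})

test_that("random short sequence yields no call at the working thresholds", {
  s <- random_dna(1, 60, seed = 23)
  expect_equal(nrow(find_tandem_repeats(s, min_score = 60)), 0)
})

test_that("repeat finder matches the exhaustive oracle on short sequences", {
  set.seed(24)
  for (i in 1:200) {
    len <- sample(8:30, 1)
    # low-complexity alphabet so repeats actually arise at this length
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    min_score <- sample(c(6, 10, 16), 1)
    got <- find_tandem_repeats(s, min_score = min_score)
    want <- oracle_find_repeats(s, min_score = min_score)
    expect_equal(got[c("start", "end", "period", "score")], want,
                 info = paste(s, min_score))
  }
})

test_that("repeat classification applies CA-before-WGCW precedence", {
  expect_equal(classify_repeat(1.0, 0), "CA")
  expect_equal(classify_repeat(0.6, 20), "WGCW")    # (CAGCA)n-like
  expect_equal(classify_repeat(0, 0), "OTHER")      # (ATT)n-like
  expect_equal(classify_repeat(0.95, 25), "CA")     # precedence: never both
  expect_equal(classify_repeat(0.89, 1.9), "OTHER")
})

test_that("site summaries apply the 400/100-bp thresholds", {
  set.seed(25)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  mk_genome <- function(insert) {
    Biostrings::DNAStringSet(c(chrS = paste0(bg(2775), insert,
                                             bg(6000 - 2775 - nchar(insert)))))
  }
  site <- tibble::tibble(chrom = "chrS", start = 2750L, end = 3250L,
                         ext_start = 2000L, ext_end = 4000L, center = 3000L)
  # 450-bp CAGCA array: WGCW-positive, CA-negative
  s1 <- summarize_site_repeats(site, mk_genome(strrep("CAGCA", 90)))
  expect_true(s1$has_wgcw); expect_false(s1$has_ca)
  expect_gte(s1$wgcw_repeat_bp, 400)
  # 120-bp CA array: CA-positive, WGCW-negative
  s2 <- summarize_site_repeats(site, mk_genome(strrep("CA", 60)))
  expect_true(s2$has_ca); expect_false(s2$has_wgcw)
  # plain background: neither
  s3 <- summarize_site_repeats(site, mk_genome(""))
  expect_false(s3$has_wgcw); expect_false(s3$has_ca)
  expect_false(s3$has_either)
  # sequence unavailable errors name the interval
  expect_error(summarize_site_repeats(
    tibble::tibble(chrom = "chrZ", start = 0L, end = 10L,
                   ext_start = 0L, ext_end = 10L), mk_genome("")), "chrZ")
})

test_that("accumulation curves are non-increasing step functions", {
  ac <- accumulation_curve(c(0, 100, 400, 400), thresholds = c(0, 100, 400))
  expect_equal(ac$fraction, c(1, 0.75, 0.5))
  expect_true(all(diff(accumulation_curve(rpois(50, 5))$fraction) <= 0))
  z <- accumulation_curve(rep(0, 4), thresholds = c(0, 1, 10))
  expect_equal(z$fraction, c(1, 0, 0))
})

test_that("genome background is seeded, deterministic and calibrated", {
  # genome with zero planted repeats: fractions are ~0
  cfg0 <- simulation_config(seed = 31,
                            chrom_sizes = tibble::tibble(chrom = "chr1",
                                                         size = 300000L),
                            n_two_ended = 0L, n_one_ended = 0L,
                            n_independent = 0L, n_tf = 0L,
                            n_wgcw_at_sites = 0L, n_ca_at_sites = 0L,
                            n_wgcw_standalone = 0L, n_ca_standalone = 0L)
  g0 <- simulate_genome(cfg0)
  b0 <- genome_background(g0$genome, n_intervals = 100, seed = 5)
  expect_equal(b0$summary$wgcw_fraction, 0)
  expect_equal(b0$summary$ca_fraction, 0)
  # determinism under a fixed seed
  b0b <- genome_background(g0$genome, n_intervals = 100, seed = 5)
  expect_identical(b0$summary, b0b$summary)

  # planted CA arrays: observed hit fraction matches a direct tiling oracle
  cfg1 <- simulation_config(seed = 32,
                            chrom_sizes = tibble::tibble(chrom = "chr1",
                                                         size = 200000L),
                            n_two_ended = 0L, n_one_ended = 0L,
                            n_independent = 0L, n_tf = 0L,
                            n_wgcw_at_sites = 0L, n_ca_at_sites = 0L,
                            n_wgcw_standalone = 0L, n_ca_standalone = 10L,
                            ca_array_bp = 150L, mutation_rate = 0)
  g1 <- simulate_genome(cfg1)
  # oracle: a 2-kb interval is CA-positive iff it covers >= 100 bp of an
  # array; count qualifying start positions exhaustively
  L <- 200000L; w <- 2000L
  hit <- logical(L - w + 1)
  for (i in seq_len(nrow(g1$truth$repeats))) {
    a <- g1$truth$repeats$start[i]; b <- g1$truth$repeats$end[i]
    starts <- max(0L, a + 100L - w):min(L - w, b - 100L)
    hit[starts + 1L] <- TRUE
  }
  p_oracle <- mean(hit)
  b1 <- genome_background(g1$genome, n_intervals = 600, seed = 6)
  expect_lt(abs(b1$summary$ca_fraction - p_oracle), 0.05)
})
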