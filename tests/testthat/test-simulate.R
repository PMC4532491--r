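small_cfg <- function(seed = 41, ...) {
  simulation_config(seed = seed,
                    chrom_sizes = tibble::tibble(chrom = "chr1",
                                                 size = 400000L),
                    n_two_ended = 8L, n_one_ended = 2L, n_independent = 2L,
                    n_tf = 2L, n_wgcw_at_sites = 2L, n_ca_at_sites = 2L,
                    n_wgcw_standalone = 1L, n_ca_standalone = 1L, ...)
}

test_that("the generator is byte-deterministic per seed", {
  g1 <- simulate_genome(small_cfg())
  g2 <- simulate_genome(small_cfg())
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth, g2$truth)
  r1 <- simulate_reads(g1)
  r2 <- simulate_reads(g2)
  expect_identical(tibble::as_tibble(r1$wt), tibble::as_tibble(r2$wt))
  expect_identical(tibble::as_tibble(r1$control),
                   tibble::as_tibble(r2$control))
  # a different seed changes the data
  g3 <- simulate_genome(small_cfg(seed = 42))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("planted arrays are written at their truth positions", {
  g <- simulate_genome(small_cfg())
  tr <- g$truth$repeats
  seqs <- as.character(g$genome)
  for (i in seq_len(nrow(tr))) {
    frag <- substr(seqs[[tr$chrom[i]]], tr$start[i] + 1, tr$end[i])
    # mutated arrays still match their motif at >= 90% of positions
    pure <- substr(strrep(tr$motif[i], ceiling(nchar(frag) / nchar(tr$motif[i]))),
                   1, nchar(frag))
    agree <- mean(strsplit(frag, "")[[1]] == strsplit(pure, "")[[1]])
    expect_gte(agree, 0.90)
  }
  # with mutation rate zero the array is an exact motif power
  g0 <- simulate_genome(small_cfg(seed = 43, mutation_rate = 0))
  tr0 <- g0$truth$repeats[1, ]
  frag0 <- substr(as.character(g0$genome)[[tr0$chrom]], tr0$start + 1, tr0$end)
  pure0 <- substr(strrep(tr0$motif, ceiling(nchar(frag0) / nchar(tr0$motif))),
                  1, nchar(frag0))
  expect_identical(frag0, pure0)
  # a site carrying a WGCW array summarises as WGCW-positive
  wg <- g0$truth$repeats[g0$truth$repeats$class == "WGCW", ][1, ]
  site <- tibble::tibble(chrom = wg$chrom,
                         start = wg$start - 100L, end = wg$start + 400L,
                         ext_start = pmax(wg$start - 775L, 0L),
                         ext_end = wg$start + 1225L)
  expect_true(summarize_site_repeats(site, g0$genome)$has_wgcw)
})

test_that("truth serialises to text and reloads losslessly", {
  sim <- simulate_dataset(small_cfg())
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_truth(dir)
  expect_equal(back$sites, sim$truth$sites)
  expect_equal(back$repeats, sim$truth$repeats)
  # tag files round-trip through the BED conventions
  wt_back <- read_tags(file.path(dir, "wt.tagAlign"))
  expect_equal(nrow(wt_back), nrow(sim$wt))
  expect_equal(wt_back$pos, sim$wt$pos)
})

test_that("read model produces the break-pattern by construction", {
  cfg <- small_cfg(seed = 44, background_rate = 0)
  sim <- simulate_dataset(cfg)
  truth <- truth_as_sites(sim$truth$sites)
  cl <- classify_sites(truth, sim$wt)
  two <- cl[cl$type == "aid_dep_two_ended", ]
  # two-ended: minus centroid left of plus centroid, no strand bias
  expect_true(all(two$minus_centroid < two$plus_centroid))
  expect_true(all(two$orientation == "dsb_like"))
  expect_true(all(!two$one_ended))
  # one-ended: tags on one strand only (no background), flagged one-ended
  one <- cl[cl$type == "aid_dep_one_ended", ]
  expect_true(all(one$one_ended))
  # TF pattern: mirror orientation
  tf <- cl[cl$type == "tf_like", ]
  expect_true(all(tf$orientation == "tf_like"))
  # AID-independent sites appear in both libraries with equal intensity
  ind <- truth[truth$type == "aid_independent", ]
  for (i in seq_len(nrow(ind))) {
    wt_n <- count_tags(sim$wt, ind$chrom[i], ind$ext_start[i], ind$ext_end[i])
    ctl_n <- count_tags(sim$control, ind$chrom[i], ind$ext_start[i],
                        ind$ext_end[i])
    expect_gt(wt_n, 0); expect_gt(ctl_n, 0)
    expect_lt(abs(log2(wt_n / ctl_n)), 0.5)
  }
})

test_that("mirroring the genome swaps strand roles and keeps classifications", {
  sim <- simulate_dataset(small_cfg(seed = 45))
  L <- sim$chrom_sizes$size[1]
  mirror <- tag_library(tibble::tibble(
    chrom = sim$wt$chrom, pos = L - 1L - sim$wt$pos,
    strand = ifelse(sim$wt$strand == "+", "-", "+")))
  truth <- truth_as_sites(sim$truth$sites)
  m_truth <- truth
  m_truth$pos <- L - 1L - truth$pos
  m_truth <- truth_as_sites(m_truth[, c("chrom", "pos", "type", "strand",
                                        "lambda")])
  a <- classify_sites(truth, sim$wt)
  b <- classify_sites(m_truth, mirror)
  expect_equal(a$plus_count, b$minus_count)
  expect_equal(a$one_ended, b$one_ended)
  fin <- is.finite(a$log2_ratio)
  expect_equal(a$log2_ratio[fin], -b$log2_ratio[fin])
  swap <- c(dsb_like = "dsb_like", tf_like = "tf_like",
            indeterminate = "indeterminate")
  expect_equal(unname(swap[a$orientation]), b$orientation)
})

test_that("recovery scoring handles exact calls, no calls and matching", {
  truth <- tibble::tibble(chrom = "chr1", pos = c(1000L, 5000L),
                          type = "aid_dep_two_ended", strand = NA, lambda = 30)
  exact <- tibble::tibble(chrom = "chr1", start = truth$pos - 250L,
                          end = truth$pos + 250L, center = truth$pos)
  r <- evaluate_recovery(exact, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall_by_type$recall, 1)
  # no calls: recall 0, precision reported 1 with zero support and flagged
  r0 <- evaluate_recovery(exact[0, ], truth)
  expect_equal(r0$recall_by_type$recall, 0)
  expect_equal(r0$precision, 1)
  expect_true(r0$precision_no_support)
  # matching is one-to-one: two calls near one planted site match once
  dup <- tibble::tibble(chrom = "chr1", start = c(750L, 850L),
                        end = c(1250L, 1350L), center = c(1000L, 1100L))
  r2 <- evaluate_recovery(dup, truth[1, ])
  expect_equal(r2$n_matched, 1)
  expect_equal(r2$precision, 0.5)
})

test_that("recall rises with site read intensity", {
  recall_at <- function(lam) {
    cfg <- simulation_config(seed = 46,
                             chrom_sizes = tibble::tibble(chrom = "chr1",
                                                          size = 2000000L),
                             n_two_ended = 30L, n_one_ended = 0L,
                             n_independent = 0L, n_tf = 0L, lambda = lam,
                             n_wgcw_at_sites = 0L, n_ca_at_sites = 0L,
                             n_wgcw_standalone = 0L, n_ca_standalone = 0L)
    sim <- simulate_dataset(cfg)
    wt <- deduplicate(sim$wt, 3)
    ctl <- deduplicate(sim$control, 3)
    attr(wt, "fragment_length") <- 200L
    attr(ctl, "fragment_length") <- 200L
    dep <- call_aid_dependent_sites(wt, ctl, sim$chrom_sizes, tiers = "exp1")
    evaluate_recovery(dep, sim$truth$sites)$recall_by_type$recall
  }
  rec <- vapply(c(5, 10, 20, 40), recall_at, numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_lt(rec[1], 0.5)   # lambda 5 sits below the tier floor
  expect_gt(rec[4], 0.9)
})
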