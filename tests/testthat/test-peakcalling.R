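test_that("tier profiles encode the published thresholds and validate", {
  e1 <- tier_profile("exp1")
  expect_equal(nrow(e1), 4)
  expect_equal(e1$min_tags, c(18, 16, 14, 13))
  expect_equal(e1$combine, c("or", "and", "and", "and"))
  e2 <- tier_profile("exp2")
  expect_equal(e2$min_tags, c(53, 22, 19))
  # overlapping tag ranges are a configuration error
  bad <- tibble::tibble(min_tags = c(10, 15), max_tags = c(20, 30),
                        ratio = 2, background = 4, combine = "and")
  expect_error(tier_profile(bad), "overlap")
  # custom tier tables load from TSV
  p <- withr::local_tempfile()
  readr::write_tsv(tibble::tibble(min_tags = 10, max_tags = NA, ratio = 2,
                                  background = 4, combine = "or"), p)
  expect_equal(tier_profile(p)$max_tags, Inf)
  # the packaged profile files agree with the built-in tables
  for (pr in c("exp1", "exp2")) {
    f <- system.file("extdata", paste0("tiers_", pr, ".tsv"),
                     package = "dsbmapr")
    expect_equal(as.data.frame(tier_profile(f)),
                 as.data.frame(tier_profile(pr)))
  }
})

test_that("tier filter applies the experiment 1 rules at the boundaries", {
  mk <- function(tags, ratio, bg) {
    tibble::tibble(chrom = "chr1", start = 10000L, end = 10500L,
                   center = 10250L, wt_tags = tags, control_tags_norm = 1,
                   fold_vs_control = ratio, local_background_ratio = bg)
  }
  pass <- function(cand, tiers = "exp1")
    nrow(apply_tier_filter(cand, tiers, tiny_sizes(1000000L))) == 1
  # >= 18 tags: OR tier
  expect_true(pass(mk(18, 2.0, 3.0)))
  expect_true(pass(mk(18, 1.0, 6.0)))
  expect_false(pass(mk(18, 1.9, 5.9)))
  # 16-17: AND tier (2.5, 4.0)
  expect_true(pass(mk(16, 2.5, 4.0)))
  expect_false(pass(mk(16, 2.6, 3.9)))
  # 14-15: AND (3.6, 4.0)
  expect_true(pass(mk(15, 3.6, 4.0)))
  expect_false(pass(mk(14, 3.5, 50)))
  # 13: AND (9.0, 8.0)
  expect_true(pass(mk(13, 9.0, 8.0)))
  expect_false(pass(mk(13, 8.9, 50)))
  # below the lowest tier: always rejected
  expect_false(pass(mk(12, 50, 50)))
})

test_that("tier filter applies the experiment 2 rules at the boundaries", {
  mk <- function(tags, ratio, bg) {
    tibble::tibble(chrom = "chr1", start = 10000L, end = 10500L,
                   center = 10250L, wt_tags = tags, control_tags_norm = 1,
                   fold_vs_control = ratio, local_background_ratio = bg)
  }
  pass <- function(cand) nrow(apply_tier_filter(cand, "exp2",
                                                tiny_sizes(1000000L))) == 1
  expect_true(pass(mk(53, 2.2, 0)))    # > 52: OR
  expect_true(pass(mk(53, 0.1, 6.0)))
  expect_true(pass(mk(52, 2.2, 6.0)))  # 22-52: AND
  expect_false(pass(mk(52, 2.2, 5.9)))
  expect_true(pass(mk(22, 2.2, 6.0)))
  expect_true(pass(mk(19, 4.0, 10.0))) # 19-21: AND
  expect_false(pass(mk(21, 3.9, 50)))
  expect_false(pass(mk(18, 50, 50)))   # below all tiers
})

test_that("sites gain a clamped 2-kb extension and the aid_dependent flag", {
  cand <- tibble::tibble(chrom = "chr1", start = 200L, end = 700L,
                         center = 450L, wt_tags = 20L, control_tags_norm = 1,
                         fold_vs_control = 5, local_background_ratio = 10)
  s <- apply_tier_filter(cand, "exp1", tiny_sizes(1000L))
  expect_equal(s$ext_start, 0L)     # clamped, shortened not shifted
  expect_equal(s$ext_end, 1000L)
  expect_true(s$aid_dependent)
  expect_false(s$aid_independent)
})

test_that("local background matches the density-ratio definition", {
  cs <- tiny_sizes(1000000L)
  # 20 tags inside the window, none outside: (20/500)/((0+0.5)/9500) = 760
  tl <- make_tags("chr1", seq(500100, 500480, length.out = 20), rep("+", 20))
  r <- local_background(tl, "chr1", 500000, 500500, cs)
  expect_equal(r, (20 / 500) / (0.5 / 9500))
  # uniform density gives a ratio near 1
  set.seed(42)
  u <- make_tags("chr1", sort(sample(0:999999, 20000)), rep("+", 20000))
  r_u <- local_background(u, "chr1", 500000, 500500, cs)
  expect_gt(r_u, 0.5); expect_lt(r_u, 2)
  # window at the chromosome start: denominator uses the available 4750 bp
  tl2 <- make_tags("chr1", seq(10, 480, length.out = 20), rep("+", 20))
  r2 <- local_background(tl2, "chr1", 0, 500, cs)
  expect_equal(r2, (20 / 500) / (0.5 / 4750))
})

test_that("candidate calling finds a planted site at the expected fold", {
  cs <- tiny_sizes(200000L)
  set.seed(7)
  # planted site: 40 WT tags within 300 bp; uniform control whose scaled
  # count averages ~1 tag per 500-bp window
  wt_bg <- sort(sample(0:199999, 400))
  site <- as.integer(seq(100100, 100400, length.out = 40))
  wt <- make_tags("chr1", c(wt_bg, site),
                  sample(c("+", "-"), 440, replace = TRUE),
                  fragment_length = 0L)
  ctl <- make_tags("chr1", sort(sample(0:199999, 440)),
                   sample(c("+", "-"), 440, replace = TRUE),
                   fragment_length = 0L)
  cand <- call_candidates(wt, ctl, cs)
  hit <- cand[abs(cand$center - 100250) <= 250, ]
  expect_equal(nrow(hit), 1)
  expect_gte(hit$wt_tags, 40)
  expect_gt(hit$fold_vs_control, 10)  # ~40 / (1 + 0.5) ~ 27
  # two planted sites 10 kb apart give two distinct candidates
  site2 <- site + 10000L
  wt2 <- make_tags("chr1", c(wt_bg, site, site2),
                   sample(c("+", "-"), 480, replace = TRUE),
                   fragment_length = 0L)
  cand2 <- call_candidates(wt2, ctl, cs)
  expect_equal(sum(abs(cand2$center - 100250) <= 100), 1)
  expect_equal(sum(abs(cand2$center - 110250) <= 100), 1)
})

test_that("calling a library against itself yields nothing", {
  sim <- default_sim()
  libs <- default_libs()
  dep <- call_aid_dependent_sites(libs$wt, libs$wt, sim$chrom_sizes,
                                  tiers = "exp1")
  expect_equal(nrow(dep), 0)
})

test_that("called windows never overlap and thresholds act monotonically", {
  sim <- default_sim()
  libs <- default_libs()
  called <- default_called()
  for (s in list(called$dep, called$indep)) {
    by_chrom <- split(s, s$chrom)
    for (d in by_chrom) {
      d <- d[order(d$start), ]
      if (nrow(d) > 1) expect_true(all(diff(d$start) >= 500))
    }
  }
  # raising the fold threshold never increases the candidate count
  c2 <- call_candidates(libs$wt, libs$control, sim$chrom_sizes,
                        fold_threshold = 2.0)
  c4 <- call_candidates(libs$wt, libs$control, sim$chrom_sizes,
                        fold_threshold = 4.0)
  expect_lte(nrow(c4), nrow(c2))
  # raising a tier threshold never increases retained sites
  t1 <- tier_profile("exp1")
  t_hard <- t1; t_hard$ratio <- t_hard$ratio * 2
  expect_lte(nrow(apply_tier_filter(c2, t_hard, sim$chrom_sizes)),
             nrow(apply_tier_filter(c2, t1, sim$chrom_sizes)))
})

test_that("degenerate inputs are handled per contract", {
  cs <- tiny_sizes()
  empty <- make_tags(character(), integer(), character(),
                     fragment_length = 200L)
  ctl <- make_tags("chr1", 1:2000, rep(c("+", "-"), 1000),
                   fragment_length = 200L)
  expect_equal(nrow(call_candidates(empty, ctl, cs)), 0)
  expect_error(call_candidates(ctl, NULL, cs), "call_aid_independent")
  expect_error(call_aid_independent(ctl, NULL, cs), "control")
})

test_that("AID-independent calling separates shared from WT-only sites", {
  sim <- default_sim()
  called <- default_called()
  truth <- sim$truth$sites
  indep_truth <- truth[truth$type == "aid_independent", ]
  # every planted AID-independent site is recovered in the independent set
  rec <- evaluate_recovery(called$indep, indep_truth)
  expect_equal(rec$recall_by_type$recall, 1)
  # and none of them leaks into the AID-dependent set
  leaked <- vapply(seq_len(nrow(indep_truth)), function(i)
    any(called$dep$chrom == indep_truth$chrom[i] &
          abs(called$dep$center - indep_truth$pos[i]) <= 500), logical(1))
  expect_false(any(leaked))
  # WT-only planted sites are excluded from the AID-independent set
  dep_truth <- truth[truth$type == "aid_dep_two_ended", ]
  in_indep <- vapply(seq_len(nrow(dep_truth)), function(i)
    any(called$indep$chrom == dep_truth$chrom[i] &
          abs(called$indep$center - dep_truth$pos[i]) <= 500), logical(1))
  expect_false(any(in_indep))
})
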