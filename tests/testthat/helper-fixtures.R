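# Shared fixtures. The default simulation and its called sites are expensive
# (~20 s), so they are computed once per test session and cached.

tiny_sizes <- function(size = 100000L, chroms = "chr1") {
  tibble::tibble(chrom = chroms, size = rep(size, length(chroms)))
}

make_tags <- function(chrom, pos, strand, read_length = 36L,
                      fragment_length = NULL) {
  tag_library(tibble::tibble(chrom = chrom, pos = as.integer(pos),
                             strand = strand),
              read_length = read_length, fragment_length = fragment_length)
}

random_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

.fixture_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_dataset(simulation_config(seed = 1))
  }
  .fixture_cache$sim
}

# deduplicated WT/control with fragment lengths (WT estimate shared, as the
# control has too few enriched sites to anchor its own)
default_libs <- function() {
  if (is.null(.fixture_cache$libs)) {
    sim <- default_sim()
    wt <- deduplicate(sim$wt, 3)
    ctl <- deduplicate(sim$control, 3)
    wt <- with_fragment_length(wt, sim$chrom_sizes)
    attr(ctl, "fragment_length") <- fragment_length(wt)
    .fixture_cache$libs <- list(wt = wt, control = ctl)
  }
  .fixture_cache$libs
}

default_called <- function() {
  if (is.null(.fixture_cache$called)) {
    sim <- default_sim()
    libs <- default_libs()
    dep <- call_aid_dependent_sites(libs$wt, libs$control, sim$chrom_sizes,
                                    tiers = "exp1")
    dep <- classify_sites(dep, libs$wt)
    indep <- call_aid_independent(libs$wt, libs$control, sim$chrom_sizes)
    .fixture_cache$called <- list(dep = dep, indep = indep)
  }
  .fixture_cache$called
}

# truth site positions dressed as site intervals (window = center +/- 250,
# extension +/- 1000) for classifier tests that bypass the caller
truth_as_sites <- function(truth_sites) {
  dplyr::mutate(truth_sites,
                start = pos - 250L, end = pos + 250L,
                ext_start = pos - 1000L, ext_end = pos + 1000L,
                center = pos)
}
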