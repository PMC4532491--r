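#' Extend intervals symmetrically from their centers
#'
#' Replaces each interval by `[center - flank, center + flank)`, where the
#' center is `floor((start + end) / 2)`, clamped to chromosome bounds (the
#' interval is shortened at an edge, never shifted).
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, other columns kept).
#' @param flank Flank in bp (> 0; default 1000, giving 2-kb intervals).
#' @param chrom_sizes Chrom-sizes tibble for clamping.
#' @return The tibble with extended `start`/`end`.
#' @export
extend_from_center <- function(x, flank = 1000L, chrom_sizes) {
  if (flank <= 0) abort("`flank` must be positive.")
  check_intervals(x, chrom_sizes)
  sizes <- chrom_size_lookup(chrom_sizes)
  center <- interval_center(x$start, x$end)
  x$start <- as.integer(pmax(center - flank, 0))
  x$end <- as.integer(pmin(center + flank, sizes[x$chrom]))
  x
}

# Internal: split a tibble of intervals into per-chrom IRanges (1-based).
split_iranges <- function(x) {
  lapply(split(x, x$chrom), function(d) IRanges::IRanges(d$start + 1L, d$end))
}

#' Merge overlapping intervals across one or more sets
#'
#' Coalesces intervals that overlap by at least 1 bp into merged intervals,
#' recording which source sets contributed to each. Idempotent and
#' order-independent.
#'
#' @param ... Interval tibbles; name the arguments to label provenance
#'   (unnamed sets are labelled `set1`, `set2`, ...).
#' @return Sorted tibble with `chrom`, `start`, `end`, `sources` (comma-
#'   separated contributing set labels) and `n_sources`.
#' @export
merge_overlapping <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  labels <- names(sets) %||% rep("", length(sets))
  labels[!nzchar(labels)] <- paste0("set", which(!nzchar(labels)))
  all <- dplyr::bind_rows(purrr::map2(sets, labels, function(s, l) {
    check_intervals(s)
    tibble(chrom = s$chrom, start = s$start, end = s$end, source = l)
  }))
  if (nrow(all) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  sources = character(), n_sources = integer()))
  }
  out <- purrr::map_dfr(sort(unique(all$chrom)), function(ch) {
    d <- all[all$chrom == ch, ]
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    tibble(chrom = ch,
           start = IRanges::start(red) - 1L,
           end = IRanges::end(red),
           sources = vapply(revmap, function(i)
             paste(sort(unique(d$source[i])), collapse = ","), character(1)),
           n_sources = vapply(revmap, function(i)
             length(unique(d$source[i])), integer(1)))
  })
  out[order(out$chrom, out$start), ]
}

#' Derive reproducible sites from two experiments
#'
#' Merges the (extended) site intervals of two experiments and keeps the
#' merged intervals to which both experiments contributed — the definition
#' of a reproducible site. The merging explains why reproducible sites are
#' on average longer than single-experiment sites.
#'
#' @param exp1_sites,exp2_sites Extended-interval tibbles (`chrom`,
#'   `start`, `end`); use the `ext_start`/`ext_end` columns of called sites
#'   or [extend_from_center()].
#' @return Merged tibble restricted to both-experiment provenance.
#' @export
reproducible_sites <- function(exp1_sites, exp2_sites) {
  merged <- merge_overlapping(exp1 = exp1_sites, exp2 = exp2_sites)
  merged[grepl("exp1", merged$sources) & grepl("exp2", merged$sources), ]
}

#' Count query intervals overlapping a target set
#'
#' @param query,target Interval tibbles.
#' @return Number of query intervals with >= 1 bp overlap to any target
#'   interval (each query counted once).
#' @export
intersect_count <- function(query, target) {
  check_intervals(query); check_intervals(target)
  if (nrow(query) == 0 || nrow(target) == 0) return(0L)
  qs <- split_iranges(query)
  ts <- split_iranges(target)
  sum(vapply(names(qs), function(ch) {
    if (!ch %in% names(ts)) return(0L)
    sum(IRanges::countOverlaps(qs[[ch]], ts[[ch]]) > 0)
  }, integer(1)))
}

#' Matched-random-interval permutation test of interval co-occurrence
#'
#' Compares the observed number of query intervals overlapping the target
#' set with a null built by redrawing, in each of `n_trials` trials, a
#' randomized set preserving every interval's length and chromosome
#' (uniform start positions; collisions permitted). The empirical p-value
#' uses the +1 correction, `(1 + #{null >= observed}) / (n_trials + 1)`,
#' so it is never zero.
#'
#' @param query,target Interval tibbles.
#' @param chrom_sizes Chrom-sizes tibble covering both sets.
#' @param n_trials Number of randomization trials (default 1000).
#' @param seed Optional integer seed.
#' @param randomize Which set is redrawn each trial: `"target"` (default,
#'   matching the randomized intervals to the target set) or `"query"`.
#' @return An `intersection_result` object; see [tidy.intersection_result()].
#' @export
randomization_test <- function(query, target, chrom_sizes, n_trials = 1000L,
                               seed = NULL, randomize = c("target", "query")) {
  randomize <- match.arg(randomize)
  check_intervals(query, chrom_sizes)
  check_intervals(target, chrom_sizes)
  if (!is.null(seed)) set.seed(seed)
  sizes <- chrom_size_lookup(chrom_sizes)
  rnd_src <- if (randomize == "target") target else query
  len <- rnd_src$end - rnd_src$start
  if (any(len > sizes[rnd_src$chrom])) {
    abort("Randomized interval longer than its chromosome.")
  }
  observed <- intersect_count(query, target)
  max_start <- sizes[rnd_src$chrom] - len
  # fixed set as per-chromosome IRanges, built once
  fixed <- if (randomize == "target") query else target
  fixed_ir <- split_iranges(fixed)
  rnd_idx <- split(seq_len(nrow(rnd_src)), rnd_src$chrom)
  chroms <- intersect(names(fixed_ir), names(rnd_idx))
  null_counts <- vapply(seq_len(n_trials), function(t) {
    s <- floor(runif(nrow(rnd_src), 0, max_start + 1))
    total <- 0L
    for (ch in chroms) {
      i <- rnd_idx[[ch]]
      ir <- IRanges::IRanges(s[i] + 1L, s[i] + len[i])
      total <- total + if (randomize == "target") {
        sum(IRanges::countOverlaps(fixed_ir[[ch]], ir) > 0)
      } else {
        sum(IRanges::countOverlaps(ir, fixed_ir[[ch]]) > 0)
      }
    }
    total
  }, integer(1))
  structure(
    list(observed = observed, n_trials = n_trials, null_counts = null_counts,
         p_value = (1 + sum(null_counts >= observed)) / (n_trials + 1),
         enrichment = if (mean(null_counts) > 0) observed / mean(null_counts)
                      else NA_real_,
         n_query = nrow(query), n_target = nrow(target),
         randomized = randomize),
    class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf(paste0("<intersection_result> observed %d of %d query intervals ",
                     "overlap the target\n  null mean %.2f (%d trials, %s ",
                     "randomized), enrichment %.2f, p = %.4g\n"),
              x$observed, x$n_query, mean(x$null_counts), x$n_trials,
              x$randomized, x$enrichment, x$p_value))
  invisible(x)
}

#' Tidy a permutation-test result
#'
#' @param x An `intersection_result`.
#' @param ... Unused.
#' @return One-row tibble with observed count, null mean, enrichment and
#'   empirical p-value.
#' @method tidy intersection_result
#' @export
tidy.intersection_result <- function(x, ...) {
  tibble(observed = x$observed, n_query = x$n_query, n_target = x$n_target,
         null_mean = mean(x$null_counts), enrichment = x$enrichment,
         p_value = x$p_value, n_trials = x$n_trials)
}

#' @rdname tidy.intersection_result
#' @method glance intersection_result
#' @export
glance.intersection_result <- function(x, ...) tidy.intersection_result(x)

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
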