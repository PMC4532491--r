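#' Cap duplicate tags per position
#'
#' Retains at most `max_per_position` tags per (chromosome, 5'-end position,
#' strand) key, keeping the first occurrences in input order. With the default
#' cap of 1 all duplicate mappings are removed; a cap of 3 keeps the original
#' plus two duplicates, the retention used for deeper libraries.
#'
#' @param tags A [tag_library()].
#' @param max_per_position Maximum tags retained per position key (>= 1).
#' @return A deduplicated [tag_library()]; idempotent at a fixed cap.
#' @export
deduplicate <- function(tags, max_per_position = 1L) {
  stopifnot(max_per_position >= 1)
  if (nrow(tags) == 0) return(tags)
  key <- paste(tags$chrom, tags$pos, tags$strand, sep = "\r")
  ord <- seq_len(nrow(tags))
  dup_rank <- ave(ord, key, FUN = seq_along)
  out <- tags[dup_rank <= max_per_position, ]
  res <- tag_library(out, read_length = attr(tags, "read_length") %||% 36L,
                     fragment_length = attr(tags, "fragment_length"))
  attr(res, "max_duplicates") <- as.integer(max_per_position)
  res
}

#' Count tags with 5' ends in an interval
#'
#' @param tags A [tag_library()].
#' @param chrom,start,end Interval (0-based half-open).
#' @param strand Optional strand filter (`"+"` or `"-"`).
#' @return Number of retained tags whose 5' position lies in `[start, end)`.
#' @export
count_tags <- function(tags, chrom, start, end, strand = NULL) {
  stopifnot(start >= 0, end > start)
  keep <- tags$chrom == chrom & tags$pos >= start & tags$pos < end
  if (!is.null(strand)) keep <- keep & tags$strand == strand
  sum(keep)
}

# Internal: cross-strand pair-difference counts for one chromosome.
# Returns, for every shift d in [0, max_shift], the number of (plus, minus)
# tag pairs with minus_pos - plus_pos == d; this is the cross-covariance
# kernel of the two 1-bp binned 5'-end densities, computed sparsely.
strand_pair_counts <- function(plus_pos, minus_pos, max_shift) {
  plus_pos <- sort(plus_pos)
  minus_pos <- sort(minus_pos)
  lo <- findInterval(minus_pos - max_shift - 0.5, plus_pos) + 1L
  hi <- findInterval(minus_pos + 0.5, plus_pos)
  npairs <- pmax(hi - lo + 1L, 0L)
  keep <- npairs > 0
  if (!any(keep)) return(integer(max_shift + 1L))
  m_rep <- rep(minus_pos[keep], npairs[keep])
  p_idx <- sequence(npairs[keep], from = lo[keep])
  d <- m_rep - plus_pos[p_idx]
  tabulate(d + 1L, nbins = max_shift + 1L)
}

#' Estimate the ChIP fragment length by strand cross-correlation
#'
#' Finds the shift `d` maximizing the Pearson correlation between the
#' plus-strand 5'-end density and the minus-strand density shifted left by
#' `d` bp (1-bp bins), searched over `[read_length, max_shift]`; ties break
#' to the smallest shift. The correlation is computed exactly but sparsely
#' from tag positions (pair-difference counts), restricted to chromosomes
#' holding at least `min_chrom_tags` tags, and lightly smoothed with a
#' centred running mean before the argmax to suppress 1-bp shot noise.
#'
#' @param tags A [tag_library()] (deduplicated).
#' @param max_shift Largest shift considered (bp).
#' @param min_chrom_tags Only chromosomes with at least this many tags enter
#'   the estimate.
#' @param smooth Half-width of the triangular smoothing kernel (bp); 0
#'   disables. A triangular kernel preserves the location of isolated peaks.
#' @param chrom_sizes Chrom-sizes tibble (needed for the density length).
#' @return The estimated fragment length in bp (integer). Use
#'   [with_fragment_length()] to attach it to the library in a pipe.
#' @export
estimate_fragment_length <- function(tags, chrom_sizes, max_shift = 500L,
                                     min_chrom_tags = 10000L, smooth = 10L) {
  check_chrom_sizes(chrom_sizes)
  rl <- attr(tags, "read_length") %||% 36L
  if (sum(tags$strand == "+") < 1000 || sum(tags$strand == "-") < 1000) {
    abort(paste("Too few tags to estimate the fragment length (need >= 1000",
                "per strand); set it manually via tag_library(fragment_length=)."))
  }
  counts <- table(tags$chrom)
  use <- names(counts)[counts >= min_chrom_tags]
  if (length(use) == 0) use <- names(counts)[which.max(counts)]
  sizes <- chrom_size_lookup(chrom_sizes)

  num <- numeric(max_shift + 1L)   # sum over chroms of covariance numerators
  den_x <- 0; den_y <- 0
  for (ch in use) {
    d <- tags[tags$chrom == ch, ]
    p <- d$pos[d$strand == "+"]
    m <- d$pos[d$strand == "-"]
    L <- sizes[[ch]]
    sxy <- strand_pair_counts(p, m, max_shift)
    # Pearson pieces for 0/1-ish densities: covariance numerator is the pair
    # count minus the product of means; the d-dependence of the overlap
    # length (L - d vs L, d <= max_shift << L) is negligible and the
    # denominator is constant in d, so the argmax is exact in practice.
    num <- num + sxy - length(p) * length(m) / L
    den_x <- den_x + (length(p) - length(p)^2 / L)
    den_y <- den_y + (length(m) - length(m)^2 / L)
  }
  r <- num / sqrt(den_x * den_y)
  if (smooth > 0L) {
    k <- (smooth + 1) - abs(seq.int(-smooth, smooth))
    k <- k / sum(k)
    r <- as.numeric(stats::filter(r, k, sides = 2))
  }
  window <- seq.int(rl, max_shift) + 1L
  rw <- r[window]
  rw[is.na(rw)] <- -Inf
  as.integer(rl + which.max(rw) - 1L)
}

#' Attach an estimated fragment length to a tag library
#'
#' Pipe-friendly wrapper around [estimate_fragment_length()].
#'
#' @inheritParams estimate_fragment_length
#' @param ... Passed on to [estimate_fragment_length()].
#' @return The library with its `fragment_length` attribute set.
#' @export
with_fragment_length <- function(tags, chrom_sizes, ...) {
  attr(tags, "fragment_length") <- estimate_fragment_length(tags, chrom_sizes, ...)
  tags
}
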