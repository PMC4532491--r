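#' Strand bias of called sites
#'
#' Separates the WT tags by strand over each site's interval and computes
#' the log2 plus:minus ratio. A site is one-ended when the absolute log2
#' ratio exceeds `bias_threshold_log2` (the default 1.5 corresponds to a
#' 2^1.5 ~ 2.8-fold bias in either direction). If one strand has zero tags
#' the ratio is infinite; the site is then called one-ended only when the
#' other strand holds at least `min_total` tags, otherwise the call is
#' indeterminate (`NA`), as it is when both strands are empty.
#'
#' @param sites Site tibble with `chrom` and interval columns.
#' @param wt WT [tag_library()].
#' @param bias_threshold_log2 One-endedness threshold on |log2 ratio|.
#' @param min_total Minimum tag count on the populated strand for a
#'   one-ended call when the other strand is empty.
#' @param interval `"extended"` (default) to count over the 2-kb extended
#'   interval, `"window"` for the called 500-bp window.
#' @return `sites` with `plus_count`, `minus_count`, `log2_ratio` and
#'   `one_ended` columns added.
#' @export
strand_bias <- function(sites, wt, bias_threshold_log2 = 1.5, min_total = 10L,
                        interval = c("extended", "window")) {
  interval <- match.arg(interval)
  se <- site_interval(sites, interval)
  cnt <- function(strand) {
    vapply(seq_len(nrow(sites)), function(i) {
      p <- sort(wt$pos[wt$chrom == sites$chrom[i] & wt$strand == strand])
      count_in(p, se$start[i], se$end[i])
    }, numeric(1))
  }
  p <- cnt("+"); m <- cnt("-")
  log2_ratio <- dplyr::case_when(
    p >= 1 & m >= 1 ~ log2(p / m),
    p == 0 & m == 0 ~ NA_real_,
    p == 0 ~ -Inf,
    m == 0 ~ Inf)
  one_ended <- dplyr::case_when(
    p >= 1 & m >= 1 ~ abs(log2_ratio) > bias_threshold_log2,
    p == 0 & m == 0 ~ NA,
    pmax(p, m) >= min_total ~ TRUE,
    TRUE ~ NA)
  sites$plus_count <- as.integer(p)
  sites$minus_count <- as.integer(m)
  sites$log2_ratio <- log2_ratio
  sites$one_ended <- one_ended
  sites
}

site_interval <- function(sites, interval) {
  if (interval == "extended" && all(c("ext_start", "ext_end") %in% names(sites))) {
    list(start = sites$ext_start, end = sites$ext_end)
  } else {
    list(start = sites$start, end = sites$end)
  }
}

#' Read-orientation signature of called sites
#'
#' At a two-ended DSB the ChIP reads pile up at the break: minus-strand
#' tags immediately left of it and plus-strand tags immediately right, so
#' the minus-strand centroid sits left of the plus-strand centroid
#' (`dsb_like`). A transcription-factor footprint gives the mirror pattern
#' (`tf_like`: plus tags left, minus tags right). The call is
#' `indeterminate` when either strand holds fewer than
#' `min_tags_per_strand` tags or the centroid gap is below `gap_min`.
#'
#' @inheritParams strand_bias
#' @param min_tags_per_strand Minimum tags per strand for a determinate call.
#' @param gap_min Minimum |plus centroid - minus centroid| in bp.
#' @param interval `"window"` (default) or `"extended"`: centroids are
#'   taken over the called window by default, where the break-proximal
#'   pileup dominates; over the 2-kb extension sparse flanking background
#'   tags get large leverage on the centroids.
#' @return `sites` with `minus_centroid`, `plus_centroid` and `orientation`
#'   columns added.
#' @export
orientation_signature <- function(sites, wt, min_tags_per_strand = 5L,
                                  gap_min = 20, interval = c("window", "extended")) {
  interval <- match.arg(interval)
  se <- site_interval(sites, interval)
  centroid <- function(strand) {
    vapply(seq_len(nrow(sites)), function(i) {
      p <- wt$pos[wt$chrom == sites$chrom[i] & wt$strand == strand]
      p <- p[p >= se$start[i] & p < se$end[i]]
      if (length(p) == 0) NA_real_ else mean(p)
    }, numeric(1))
  }
  cnt <- function(strand) {
    vapply(seq_len(nrow(sites)), function(i) {
      p <- sort(wt$pos[wt$chrom == sites$chrom[i] & wt$strand == strand])
      count_in(p, se$start[i], se$end[i])
    }, numeric(1))
  }
  pc <- centroid("+"); mc <- centroid("-")
  np <- cnt("+"); nm <- cnt("-")
  gap <- pc - mc
  sites$minus_centroid <- mc
  sites$plus_centroid <- pc
  sites$orientation <- dplyr::case_when(
    np < min_tags_per_strand | nm < min_tags_per_strand ~ "indeterminate",
    abs(gap) < gap_min ~ "indeterminate",
    gap > 0 ~ "dsb_like",
    TRUE ~ "tf_like")
  sites
}

#' Classify sites by strand bias and orientation
#'
#' Convenience wrapper adding both the [strand_bias()] and the
#' [orientation_signature()] columns.
#'
#' @inheritParams strand_bias
#' @inheritParams orientation_signature
#' @return The annotated site tibble.
#' @export
classify_sites <- function(sites, wt, bias_threshold_log2 = 1.5,
                           min_total = 10L, min_tags_per_strand = 5L,
                           gap_min = 20, interval = c("extended", "window")) {
  interval <- match.arg(interval)
  sites <- strand_bias(sites, wt, bias_threshold_log2, min_total, interval)
  orientation_signature(sites, wt, min_tags_per_strand, gap_min,
                        interval = "window")
}

#' Distribution of per-site strand-bias log2 ratios
#'
#' @inheritParams strand_bias
#' @return A list with `ratios` (tibble of finite per-site log2 ratios,
#'   suitable for a histogram), `fraction_one_ended` (fraction of
#'   classifiable sites with |log2 ratio| above the threshold, infinite
#'   ratios included) and `n_classifiable`.
#' @export
bias_distribution <- function(sites, wt, bias_threshold_log2 = 1.5,
                              min_total = 10L,
                              interval = c("extended", "window")) {
  stopifnot(nrow(sites) >= 1)
  interval <- match.arg(interval)
  sb <- strand_bias(sites, wt, bias_threshold_log2, min_total, interval)
  classifiable <- !is.na(sb$one_ended)
  list(
    ratios = tibble(log2_ratio = sb$log2_ratio[is.finite(sb$log2_ratio)]),
    fraction_one_ended = if (any(classifiable))
      mean(sb$one_ended[classifiable]) else NA_real_,
    n_classifiable = sum(classifiable))
}
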