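#' Tier filter profiles
#'
#' The empirical retention rules combining a candidate peak's total tag
#' count, its WT:control enrichment ratio and its local-background ratio.
#' Two named profiles ship with the package:
#' * `"exp1"` (shallow library, all duplicates removed): >= 18 tags needs
#'   ratio >= 2.0 OR background >= 6.0; 16-17 tags needs >= 2.5 AND >= 4.0;
#'   14-15 tags needs >= 3.6 AND >= 4.0; 13 tags needs >= 9.0 AND >= 8.0.
#' * `"exp2"` (deeper library): > 52 tags needs >= 2.2 OR >= 6.0; 22-52 tags
#'   needs >= 2.2 AND >= 6.0; 19-21 tags needs >= 4.0 AND >= 10.0.
#' Candidates below the lowest tier are rejected outright. The same tables
#' ship as editable TSVs under `system.file("extdata", package = "dsbmapr")`.
#'
#' @param profile `"exp1"`, `"exp2"`, or a path to a TSV with columns
#'   `min_tags`, `max_tags` (`Inf` or `NA` for unbounded), `ratio`,
#'   `background`, `combine` (`"and"`/`"or"`).
#' @return A tier tibble.
#' @export
tier_profile <- function(profile = "exp1") {
  if (is.data.frame(profile)) return(validate_tiers(as_tibble(profile)))
  tiers <- switch(profile,
    exp1 = tibble(
      min_tags = c(18, 16, 14, 13), max_tags = c(Inf, 17, 15, 13),
      ratio = c(2.0, 2.5, 3.6, 9.0), background = c(6.0, 4.0, 4.0, 8.0),
      combine = c("or", "and", "and", "and")),
    exp2 = tibble(
      min_tags = c(53, 22, 19), max_tags = c(Inf, 52, 21),
      ratio = c(2.2, 2.2, 4.0), background = c(6.0, 6.0, 10.0),
      combine = c("or", "and", "and")),
    {
      x <- readr::read_tsv(profile, col_types = "ddddc", progress = FALSE)
      x$max_tags[is.na(x$max_tags)] <- Inf
      x
    })
  validate_tiers(tiers)
}

validate_tiers <- function(tiers) {
  stopifnot(all(c("min_tags", "max_tags", "ratio", "background", "combine")
                %in% names(tiers)))
  if (!all(tiers$combine %in% c("and", "or"))) {
    abort("Tier `combine` must be \"and\" or \"or\".")
  }
  if (any(tiers$max_tags < tiers$min_tags)) {
    abort("Tier with max_tags < min_tags.")
  }
  t2 <- tiers[order(tiers$min_tags), ]
  if (nrow(t2) > 1 && any(t2$max_tags[-nrow(t2)] >= t2$min_tags[-1])) {
    abort("Tier tag-count ranges overlap.")
  }
  tiers
}

# Internal: shifted 5'-end positions (toward the fragment midpoint).
shifted_positions <- function(tags, shift) {
  ifelse(tags$strand == "+", tags$pos + shift, tags$pos - shift)
}

# Internal: count sorted positions falling in [start, end) (integer coords).
count_in <- function(pos_sorted, start, end) {
  findInterval(end - 0.5, pos_sorted) - findInterval(start - 0.5, pos_sorted)
}

# Internal: greedy selection of non-overlapping maximal windows.
# cnt[s + 1] = tag count of the window starting at 0-based s. Repeatedly
# takes the highest-count window (ties to the leftmost) and masks all
# windows whose center lies within `window` bp of an accepted center.
greedy_select <- function(cnt, window, floor) {
  cnt <- as.numeric(cnt)
  starts <- integer(0)
  counts <- integer(0)
  repeat {
    i <- which.max(cnt)
    v <- cnt[i]
    if (!is.finite(v) || v < floor) break
    starts <- c(starts, i - 1L)
    counts <- c(counts, as.integer(v))
    lo <- max(1L, i - (window - 1L))
    hi <- min(length(cnt), i + window - 1L)
    cnt[lo:hi] <- -Inf
  }
  ord <- order(starts)
  list(start = starts[ord], count = counts[ord])
}

#' Local-background enrichment of a window
#'
#' Ratio of the tag density inside `[start, end)` to the density in the
#' surrounding `span` centred on the window's center, excluding the window
#' itself; the denominator carries a pseudocount. At chromosome edges the
#' span is clamped and the density renormalised by the available length.
#'
#' @param tags A [tag_library()] (or any tibble with `chrom`, `pos`).
#' @param chrom,start,end Window (0-based half-open).
#' @param chrom_sizes Chrom-sizes tibble.
#' @param span Total background span in bp (default 10 kb).
#' @param pseudocount Added to the outside count (default 0.5).
#' @return The density ratio (window / local background).
#' @export
local_background <- function(tags, chrom, start, end, chrom_sizes,
                             span = 10000L, pseudocount = 0.5) {
  check_chrom_sizes(chrom_sizes)
  L <- chrom_size_lookup(chrom_sizes)[[chrom]]
  pos <- sort(tags$pos[tags$chrom == chrom])
  center <- interval_center(start, end)
  lo <- max(0L, center - span %/% 2L)
  hi <- min(L, center + span %/% 2L)
  inside <- count_in(pos, start, end)
  total <- count_in(pos, lo, hi)
  avail <- (hi - lo) - (min(hi, end) - max(lo, start))
  outside <- total - inside
  (inside / (end - start)) / ((outside + pseudocount) / avail)
}

#' Call candidate peaks against a control library
#'
#' Slides a `window`-bp window at 1-bp steps over each chromosome counting
#' WT 5' ends (both strands, each shifted half a fragment length toward the
#' fragment midpoint), greedily keeps local maxima with centers at least
#' `window` bp apart, and retains windows with at least `tag_floor` WT tags
#' and a fold enrichment over the library-scaled control of at least
#' `fold_threshold`. The scaled control count carries a pseudocount.
#'
#' @param wt,control [tag_library()]s, deduplicated, with fragment lengths
#'   set (see [with_fragment_length()]).
#' @param chrom_sizes Chrom-sizes tibble.
#' @param window Window width W in bp (default 500).
#' @param fold_threshold Minimum WT:control fold change (default 2.0).
#' @param tag_floor Minimum WT tags per window for candidate formation
#'   (default 10, below the lowest tier of either filter profile so the tier
#'   filter is the binding constraint).
#' @param pseudocount Added to the scaled control count and to background
#'   denominators (default 0.5).
#' @param span Local-background span in bp (default 10 kb).
#' @return A tibble of candidate peaks: window coordinates, `center`,
#'   `wt_tags`, `control_tags_norm`, `fold_vs_control`,
#'   `local_background_ratio`.
#' @export
call_candidates <- function(wt, control, chrom_sizes, window = 500L,
                            fold_threshold = 2.0, tag_floor = 10L,
                            pseudocount = 0.5, span = 10000L) {
  if (is.null(control)) {
    abort(paste("No control library supplied; for control-free calling of",
                "AID-independent sites use call_aid_independent()."))
  }
  cand <- scan_windows(wt, chrom_sizes, window, tag_floor, span, pseudocount)
  if (nrow(cand) == 0) return(cand_with_control(cand, scale = 1, pseudocount))
  ctl_shift <- (attr(control, "fragment_length") %||%
                  abort("Control library needs a fragment length.")) %/% 2L
  ctl_pos <- shifted_positions(control, ctl_shift)
  scale <- nrow(wt) / max(nrow(control), 1L)
  ctl_raw <- vapply(seq_len(nrow(cand)), function(i) {
    p <- sort(ctl_pos[control$chrom == cand$chrom[i]])
    count_in(p, cand$start[i], cand$end[i])
  }, numeric(1))
  cand$control_tags_norm <- ctl_raw * scale
  cand$fold_vs_control <- cand$wt_tags / (cand$control_tags_norm + pseudocount)
  cand[cand$fold_vs_control >= fold_threshold, ]
}

cand_with_control <- function(cand, scale, pseudocount) {
  cand$control_tags_norm <- numeric(nrow(cand))
  cand$fold_vs_control <- numeric(nrow(cand))
  cand
}

# Internal: windowed WT scan shared by both calling paths.
scan_windows <- function(wt, chrom_sizes, window, tag_floor, span, pseudocount) {
  check_chrom_sizes(chrom_sizes)
  if (nrow(wt) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  center = integer(), wt_tags = integer(),
                  local_background_ratio = numeric()))
  }
  fl <- attr(wt, "fragment_length")
  if (is.null(fl)) {
    abort("WT library needs a fragment length (with_fragment_length()).")
  }
  shift <- fl %/% 2L
  sizes <- chrom_size_lookup(chrom_sizes)
  pos_all <- shifted_positions(wt, shift)
  out <- purrr::map_dfr(sort(names(sizes)), function(ch) {
    L <- sizes[[ch]]
    pos <- pos_all[wt$chrom == ch]
    pos <- pos[pos >= 0 & pos < L]
    if (length(pos) < tag_floor) return(tibble())
    tab <- tabulate(pos + 1L, nbins = L)
    cs <- c(0L, cumsum(tab))
    nwin <- L - window + 1L
    cnt <- cs[(window + 1L):(L + 1L)] - cs[1:nwin]
    sel <- greedy_select(cnt, window, tag_floor)
    if (length(sel$start) == 0) return(tibble())
    spos <- sort(pos)
    bg <- vapply(seq_along(sel$start), function(i) {
      s <- sel$start[i]; e <- s + window
      center <- s + window %/% 2L
      lo <- max(0L, center - span %/% 2L)
      hi <- min(L, center + span %/% 2L)
      outside <- count_in(spos, lo, hi) - sel$count[i]
      avail <- (hi - lo) - window
      (sel$count[i] / window) / ((outside + pseudocount) / avail)
    }, numeric(1))
    tibble(chrom = ch, start = sel$start, end = sel$start + window,
           center = sel$start + window %/% 2L,
           wt_tags = sel$count, local_background_ratio = bg)
  })
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  center = integer(), wt_tags = integer(),
                  local_background_ratio = numeric())
  }
  out
}

# Internal: per-strand raw 5'-end counts over extended intervals.
strand_counts <- function(tags, sites) {
  if (nrow(sites) == 0) {
    sites$wt_plus <- integer(0); sites$wt_minus <- integer(0)
    return(sites)
  }
  counts <- function(strand) {
    vapply(seq_len(nrow(sites)), function(i) {
      p <- sort(tags$pos[tags$chrom == sites$chrom[i] & tags$strand == strand])
      count_in(p, sites$ext_start[i], sites$ext_end[i])
    }, numeric(1))
  }
  sites$wt_plus <- as.integer(counts("+"))
  sites$wt_minus <- as.integer(counts("-"))
  sites
}

#' Apply a tier filter to candidate peaks
#'
#' Each candidate is assigned to the tier whose tag-count range contains its
#' raw WT window count and retained iff the tier's ratio/background
#' conditions hold under the tier's AND/OR rule; candidates below every tier
#' are rejected. Survivors become called sites flagged `aid_dependent`, with
#' the window extended 1000 bp either side of its center (clamped at
#' chromosome edges).
#'
#' @param candidates Output of [call_candidates()].
#' @param tiers A tier tibble or profile name (see [tier_profile()]).
#' @param chrom_sizes Chrom-sizes tibble (for clamping the extension).
#' @param wt Optional WT [tag_library()]; when given, per-strand raw 5'-end
#'   counts over the extended interval are added (`wt_plus`, `wt_minus`).
#' @param flank Extension flank in bp (default 1000).
#' @return A site tibble with called window, extended interval and flags.
#' @export
apply_tier_filter <- function(candidates, tiers = "exp1", chrom_sizes = NULL,
                              wt = NULL, flank = 1000L) {
  tiers <- tier_profile(tiers)
  n <- nrow(candidates)
  keep <- logical(n)
  for (i in seq_len(nrow(tiers))) {
    in_tier <- candidates$wt_tags >= tiers$min_tags[i] &
      candidates$wt_tags <= tiers$max_tags[i]
    ok_ratio <- candidates$fold_vs_control >= tiers$ratio[i]
    ok_bg <- candidates$local_background_ratio >= tiers$background[i]
    pass <- if (tiers$combine[i] == "or") ok_ratio | ok_bg else ok_ratio & ok_bg
    keep <- keep | (in_tier & pass)
  }
  sites <- candidates[keep, ]
  as_called_sites(sites, chrom_sizes, wt, flank,
                  aid_dependent = TRUE, aid_independent = FALSE)
}

as_called_sites <- function(sites, chrom_sizes, wt, flank,
                            aid_dependent, aid_independent) {
  sizes <- if (!is.null(chrom_sizes)) chrom_size_lookup(chrom_sizes)
  sites$ext_start <- pmax(sites$center - flank, 0L)
  sites$ext_end <- if (is.null(sizes)) sites$center + flank else
    pmin(sites$center + flank, as.integer(sizes[sites$chrom]))
  sites$aid_dependent <- rep(aid_dependent, nrow(sites))
  sites$aid_independent <- rep(aid_independent, nrow(sites))
  if (!is.null(wt)) sites <- strand_counts(wt, sites)
  sites <- sites[order(sites$chrom, sites$start), ]
  sites
}

#' Call AID-dependent sites (candidates + tier filter)
#'
#' Convenience wrapper running [call_candidates()] then
#' [apply_tier_filter()].
#'
#' @inheritParams call_candidates
#' @inheritParams apply_tier_filter
#' @return A site tibble flagged `aid_dependent`.
#' @export
call_aid_dependent_sites <- function(wt, control, chrom_sizes, tiers = "exp1",
                                     window = 500L, fold_threshold = 2.0,
                                     tag_floor = 10L, pseudocount = 0.5,
                                     span = 10000L, flank = 1000L) {
  cand <- call_candidates(wt, control, chrom_sizes, window, fold_threshold,
                          tag_floor, pseudocount, span)
  apply_tier_filter(cand, tiers, chrom_sizes, wt = wt, flank = flank)
}

#' Call AID-independent sites (no-control calling with a ratio cap)
#'
#' Candidates are called against the WT local background only (window tag
#' floor plus a local-background ratio threshold); survivors are kept iff
#' their library-normalised WT:control tag-count ratio over the called
#' window does not exceed `max_ratio`, i.e. the site is equally present in
#' both libraries.
#'
#' @inheritParams call_candidates
#' @param max_ratio Maximum WT:control normalised tag ratio (default 1.4).
#' @param background_threshold Minimum local-background ratio (default 4.0).
#' @param flank Extension flank in bp (default 1000).
#' @return A site tibble flagged `aid_independent`.
#' @export
call_aid_independent <- function(wt, control, chrom_sizes, window = 500L,
                                 max_ratio = 1.4, background_threshold = 4.0,
                                 tag_floor = 10L, pseudocount = 0.5,
                                 span = 10000L, flank = 1000L) {
  if (is.null(control)) {
    abort("call_aid_independent() needs the control library for the ratio cap.")
  }
  cand <- scan_windows(wt, chrom_sizes, window, tag_floor, span, pseudocount)
  cand <- cand[cand$local_background_ratio >= background_threshold, ]
  if (nrow(cand) > 0) {
    # the ratio cap is taken over the center-extended interval so it
    # reflects the whole site rather than the WT-optimal window placement
    sizes <- chrom_size_lookup(chrom_sizes)
    lo <- pmax(cand$center - flank, 0L)
    hi <- pmin(cand$center + flank, as.integer(sizes[cand$chrom]))
    scale <- nrow(wt) / max(nrow(control), 1L)
    cnt_ext <- function(lib) {
      vapply(seq_len(nrow(cand)), function(i) {
        p <- sort(lib$pos[lib$chrom == cand$chrom[i]])
        count_in(p, lo[i], hi[i])
      }, numeric(1))
    }
    wt_ext <- cnt_ext(wt)
    cand$control_tags_norm <- cnt_ext(control) * scale
    cand$fold_vs_control <- wt_ext / (cand$control_tags_norm + pseudocount)
    cand <- cand[cand$fold_vs_control <= max_ratio, ]
  } else {
    cand <- cand_with_control(cand, 1, pseudocount)
  }
  as_called_sites(cand, chrom_sizes, wt, flank,
                  aid_dependent = FALSE, aid_independent = TRUE)
}
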