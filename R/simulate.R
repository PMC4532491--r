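#' Simulation configuration
#'
#' Defines the study conditions the synthetic data emulate: a small random
#' genome with planted WGCW-pentamer and CA-dinucleotide tandem arrays,
#' break sites of four types with the DSB read-orientation model, and
#' uniform sonication background reads in both libraries.
#'
#' Default layout (per seed): 3 chromosomes x 5 Mb at GC 0.42; 100
#' AID-dependent two-ended sites, 10 AID-dependent one-ended sites, 20
#' AID-independent sites and 10 transcription-factor-pattern sites, each
#' with expected site reads `lambda = 30`; 30 of the two-ended sites carry
#' a 450-bp CAGCA array and 20 a 150-bp CA array at the break, plus 10
#' standalone arrays of each class elsewhere; background 0.002 tags/bp per
#' library; fragment length 200 +/- 50 bp; 36-bp reads.
#'
#' @param seed Integer seed controlling every random draw.
#' @param chrom_sizes Tibble (`chrom`, `size`); default 3 x 5 Mb.
#' @param gc GC content of the background sequence.
#' @param n_two_ended,n_one_ended,n_independent,n_tf Site counts per type.
#' @param lambda Expected site reads per site.
#' @param n_wgcw_at_sites,n_ca_at_sites Two-ended sites carrying an array.
#' @param n_wgcw_standalone,n_ca_standalone Arrays planted away from sites.
#' @param wgcw_array_bp,ca_array_bp Array lengths in bp.
#' @param mutation_rate Per-base point-mutation rate within planted arrays.
#' @param background_rate Background tags per bp per library.
#' @param fragment_mean,fragment_sd Sonication fragment length (bp).
#' @param read_length Read length (bp).
#' @param jitter_sd SD of the break-proximal 5'-end jitter (bp).
#' @param end_offset_mean,end_offset_sd End-processing offset of break-end
#'   5' ends away from the break (bp): minus-strand tags sit just left of
#'   the break and plus-strand tags just right, producing the minus-left /
#'   plus-right orientation signature that distinguishes breaks from
#'   transcription-factor footprints.
#' @param sonication_rate Sonication-end tags emitted per break-end tag.
#'   Break-end reads dominate in Nbs1 ChIP (the observed one-ended sites
#'   carry tags on a single strand), so this is well below 1.
#' @param min_spacing Minimum distance between planted features (bp).
#' @param site_read_mode `"poisson"` (independent Poisson halves) or
#'   `"binomial"` (total Poisson split Binomial(n, 0.5) between sides).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_sizes = tibble(
                                chrom = c("chr1", "chr2", "chr3"),
                                size = rep(5000000L, 3)),
                              gc = 0.42,
                              n_two_ended = 100L, n_one_ended = 10L,
                              n_independent = 20L, n_tf = 10L,
                              lambda = 30,
                              n_wgcw_at_sites = 30L, n_ca_at_sites = 20L,
                              n_wgcw_standalone = 10L, n_ca_standalone = 10L,
                              wgcw_array_bp = 450L, ca_array_bp = 150L,
                              mutation_rate = 0.03,
                              background_rate = 0.002,
                              fragment_mean = 200, fragment_sd = 50,
                              read_length = 36L, jitter_sd = 5,
                              end_offset_mean = 60, end_offset_sd = 20,
                              sonication_rate = 0.05,
                              min_spacing = 5000L,
                              site_read_mode = c("poisson", "binomial")) {
  check_chrom_sizes(chrom_sizes)
  stopifnot(background_rate >= 0, lambda >= 0, mutation_rate >= 0,
            n_wgcw_at_sites + n_ca_at_sites <= n_two_ended)
  structure(list(
    seed = as.integer(seed), chrom_sizes = chrom_sizes, gc = gc,
    n_two_ended = n_two_ended, n_one_ended = n_one_ended,
    n_independent = n_independent, n_tf = n_tf, lambda = lambda,
    n_wgcw_at_sites = n_wgcw_at_sites, n_ca_at_sites = n_ca_at_sites,
    n_wgcw_standalone = n_wgcw_standalone, n_ca_standalone = n_ca_standalone,
    wgcw_array_bp = wgcw_array_bp, ca_array_bp = ca_array_bp,
    mutation_rate = mutation_rate, background_rate = background_rate,
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    read_length = read_length, jitter_sd = jitter_sd,
    end_offset_mean = end_offset_mean, end_offset_sd = end_offset_sd,
    sonication_rate = sonication_rate, min_spacing = min_spacing,
    site_read_mode = match.arg(site_read_mode)), class = "sim_config")
}

# Internal: draw n feature positions pairwise >= spacing apart, margin bp
# away from chromosome edges, chromosomes weighted by length.
draw_positions <- function(n, chrom_sizes, spacing, margin = 10000L) {
  sizes <- chrom_size_lookup(chrom_sizes)
  placed_chrom <- character(0)
  placed_pos <- integer(0)
  tries <- 0
  while (length(placed_pos) < n) {
    ch <- sample(chrom_sizes$chrom, 1, prob = chrom_sizes$size)
    pos <- floor(runif(1, margin, sizes[[ch]] - margin))
    same <- placed_chrom == ch
    if (!any(same) || all(abs(placed_pos[same] - pos) >= spacing)) {
      placed_chrom <- c(placed_chrom, ch)
      placed_pos <- c(placed_pos, as.integer(pos))
    }
    tries <- tries + 1
    if (tries > 1000 * n) abort("Could not place features with the requested spacing.")
  }
  tibble(chrom = placed_chrom, pos = placed_pos)
}

# Internal: tandem array sequence with per-base point mutations.
array_sequence <- function(motif, length_bp, mutation_rate) {
  chars <- strsplit(strrep(motif, ceiling(length_bp / nchar(motif))), "")[[1]]
  chars <- chars[seq_len(length_bp)]
  mut <- which(runif(length_bp) < mutation_rate)
  if (length(mut) > 0) {
    chars[mut] <- vapply(chars[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  chars
}

#' Simulate a genome with planted tandem-repeat arrays
#'
#' Background bases are i.i.d. at the configured GC content; WGCW (CAGCA
#' motif) and CA arrays are written at recorded positions with per-copy
#' point mutations. Deterministic: the same config (seed included) yields
#' byte-identical sequence and truth.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `truth`
#'   (list of `sites` and `repeats` tibbles) and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- chrom_size_lookup(config$chrom_sizes)

  n_feat <- with(config, n_two_ended + n_one_ended + n_independent + n_tf +
                   n_wgcw_standalone + n_ca_standalone)
  feat <- draw_positions(n_feat, config$chrom_sizes, config$min_spacing)
  types <- with(config, c(rep("aid_dep_two_ended", n_two_ended),
                          rep("aid_dep_one_ended", n_one_ended),
                          rep("aid_independent", n_independent),
                          rep("tf_like", n_tf),
                          rep("wgcw_array", n_wgcw_standalone),
                          rep("ca_array", n_ca_standalone)))
  feat$type <- types
  sites <- feat[!feat$type %in% c("wgcw_array", "ca_array"), ]
  sites$lambda <- config$lambda
  sites$strand <- NA_character_
  one <- sites$type == "aid_dep_one_ended"
  sites$strand[one] <- sample(c("+", "-"), sum(one), replace = TRUE)

  # arrays: the first n_wgcw_at_sites two-ended sites carry a WGCW array at
  # the break, the next n_ca_at_sites a CA array, plus standalone arrays
  two_idx <- which(sites$type == "aid_dep_two_ended")
  arr <- dplyr::bind_rows(
    tibble(chrom = sites$chrom[two_idx[seq_len(config$n_wgcw_at_sites)]],
           center = sites$pos[two_idx[seq_len(config$n_wgcw_at_sites)]],
           class = "WGCW"),
    tibble(chrom = sites$chrom[two_idx[config$n_wgcw_at_sites +
                                         seq_len(config$n_ca_at_sites)]],
           center = sites$pos[two_idx[config$n_wgcw_at_sites +
                                        seq_len(config$n_ca_at_sites)]],
           class = "CA"),
    tibble(chrom = feat$chrom[feat$type == "wgcw_array"],
           center = feat$pos[feat$type == "wgcw_array"], class = "WGCW"),
    tibble(chrom = feat$chrom[feat$type == "ca_array"],
           center = feat$pos[feat$type == "ca_array"], class = "CA"))
  arr$motif <- ifelse(arr$class == "WGCW", "CAGCA", "CA")
  arr$length_bp <- ifelse(arr$class == "WGCW", config$wgcw_array_bp,
                          config$ca_array_bp)
  arr$start <- as.integer(arr$center - arr$length_bp %/% 2L)
  arr$end <- as.integer(arr$start + arr$length_bp)

  gc <- config$gc
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- lapply(config$chrom_sizes$chrom, function(ch) {
    chars <- sample(names(base_prob), sizes[[ch]], replace = TRUE,
                    prob = base_prob)
    a <- arr[arr$chrom == ch, ]
    for (i in seq_len(nrow(a))) {
      chars[(a$start[i] + 1):a$end[i]] <-
        array_sequence(a$motif[i], a$length_bp[i], config$mutation_rate)
    }
    paste(chars, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(setNames(unlist(seqs),
                                              config$chrom_sizes$chrom))
  truth_sites <- sites[c("chrom", "pos", "type", "strand", "lambda")]
  truth_repeats <- tibble(chrom = arr$chrom, start = arr$start, end = arr$end,
                          class = arr$class, motif = arr$motif)
  list(genome = genome,
       truth = list(sites = truth_sites, repeats = truth_repeats),
       config = config)
}

# Internal: emit tags for one side of a break.
# The fragment end at the break is trimmed by an end-processing offset; the
# left fragment then yields break-end tags on the minus strand just left of
# the break and sonication-end tags on the plus strand a fragment length
# further left (side = +1 is the mirror image). Tying the sonication end to
# the processed end keeps the strand cross-correlation peak at the true
# fragment length.
break_side_tags <- function(chrom, b, n_break, n_soni, side, config) {
  jit <- function(n) as.integer(round(rnorm(n, 0, config$jitter_sd)))
  off <- function(n) as.integer(round(abs(rnorm(n, config$end_offset_mean,
                                                config$end_offset_sd))))
  frag <- function(n) as.integer(round(rnorm(n, config$fragment_mean,
                                             config$fragment_sd)))
  if (side < 0) {
    dplyr::bind_rows(
      tibble(chrom = chrom, pos = b - 1L - off(n_break) + jit(n_break),
             strand = rep("-", n_break)),
      tibble(chrom = chrom, pos = b - off(n_soni) - frag(n_soni),
             strand = rep("+", n_soni)))
  } else {
    dplyr::bind_rows(
      tibble(chrom = chrom, pos = b + off(n_break) + jit(n_break),
             strand = rep("+", n_break)),
      tibble(chrom = chrom, pos = b + off(n_soni) + frag(n_soni),
             strand = rep("-", n_soni)))
  }
}

# Internal: site tags for one library. `n_total` fixes each site's total
# break-end read count (used to emit the same breakage intensity into both
# libraries for AID-independent sites); placement noise stays per-library.
site_tags <- function(sites, config, n_total = NULL) {
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    b <- sites$pos[i]; ch <- sites$chrom[i]
    lam <- sites$lambda[i]
    type <- sites$type[i]
    halves <- if (!is.null(n_total)) {
      nl <- rbinom(1, n_total[i], 0.5); c(nl, n_total[i] - nl)
    } else if (config$site_read_mode == "binomial") {
      n <- rpois(1, lam); nl <- rbinom(1, n, 0.5); c(nl, n - nl)
    } else {
      rpois(2, lam / 2)
    }
    soni <- rpois(2, config$sonication_rate * lam / 2)
    if (type == "tf_like") {
      # transcription-factor pattern: plus tags left of the site center,
      # minus tags right (mirror of the DSB pattern)
      d <- function(n) as.integer(round(abs(rnorm(n, config$fragment_mean / 2,
                                                  config$fragment_sd / 2))))
      return(dplyr::bind_rows(
        tibble(chrom = ch, pos = b - d(halves[1]), strand = rep("+", halves[1])),
        tibble(chrom = ch, pos = b + d(halves[2]), strand = rep("-", halves[2]))))
    }
    if (type == "aid_dep_one_ended") {
      side <- if (sites$strand[i] == "-") -1L else 1L
      return(break_side_tags(ch, b, halves[1], soni[1], side, config))
    }
    dplyr::bind_rows(
      break_side_tags(ch, b, halves[1], soni[1], -1L, config),
      break_side_tags(ch, b, halves[2], soni[2], +1L, config))
  })
}

# Internal: uniform background tags for one library.
background_tags <- function(config) {
  sizes <- chrom_size_lookup(config$chrom_sizes)
  purrr::map_dfr(names(sizes), function(ch) {
    n <- rpois(1, config$background_rate * sizes[[ch]])
    tibble(chrom = ch, pos = as.integer(floor(runif(n, 0, sizes[[ch]]))),
           strand = sample(c("+", "-"), n, replace = TRUE))
  })
}

#' Simulate WT and control ChIP tag libraries
#'
#' Background sonication reads are Poisson-uniform in both libraries.
#' Two-ended break sites emit minus-strand break-end tags immediately left
#' of the break and plus-strand tags immediately right (small positional
#' jitter), plus a minority of sonication-end tags a fragment length away
#' on the opposite strand. One-ended sites emit a single side.
#' AID-independent sites emit into both libraries (independent draws);
#' AID-dependent and TF-pattern sites into the WT library only. Tags are
#' emitted directly as aligned genomic 5'-end positions.
#'
#' @param sim Output of [simulate_genome()] (truth + config), or a
#'   `sim_config` (the genome itself is not needed to place reads).
#' @return A list with `wt` and `control` [tag_library()]s (clamped to the
#'   chromosome bounds, sorted by coordinate).
#' @export
simulate_reads <- function(sim) {
  config <- if (inherits(sim, "sim_config")) sim else sim$config
  truth <- if (inherits(sim, "sim_config")) {
    simulate_genome(sim)$truth
  } else sim$truth
  set.seed(config$seed + 1L)
  sizes <- chrom_size_lookup(config$chrom_sizes)
  s <- truth$sites
  indep <- s[s$type == "aid_independent", ]
  # AID-independent breaks are the same sites at the same per-culture
  # frequency in both genotypes: one intensity draw per site, shared by the
  # two libraries; tag placement and background stay library-specific
  indep_n <- rpois(nrow(indep), indep$lambda)
  wt <- dplyr::bind_rows(
    background_tags(config),
    site_tags(s[s$type != "aid_independent", ], config),
    site_tags(indep, config, n_total = indep_n))
  ctl <- dplyr::bind_rows(
    background_tags(config),
    site_tags(indep, config, n_total = indep_n))
  tidy_lib <- function(d) {
    d$pos <- pmin(pmax(d$pos, 0L), as.integer(sizes[d$chrom]) - 1L)
    d <- d[order(d$chrom, d$pos, d$strand), ]
    tag_library(d, read_length = config$read_length)
  }
  list(wt = tidy_lib(wt), control = tidy_lib(ctl))
}

#' Simulate a complete dataset
#'
#' Genome, truth and both tag libraries from one config; fully
#' deterministic per seed.
#'
#' @param config A [simulation_config()].
#' @return List with `genome`, `chrom_sizes`, `truth`, `wt`, `control`,
#'   `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  g <- simulate_genome(config)
  reads <- simulate_reads(g)
  list(genome = g$genome, chrom_sizes = config$chrom_sizes, truth = g$truth,
       wt = reads$wt, control = reads$control, config = config)
}

#' Write simulation artifacts to a directory
#'
#' Emits `genome.fa`, `chrom.sizes`, `wt.tagAlign`, `control.tagAlign`,
#' `truth_sites.tsv` and `truth_repeats.bed`; truth files round-trip
#' losslessly through [read_truth()].
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_chrom_sizes(sim$chrom_sizes, file.path(dir, "chrom.sizes"))
  write_tags(sim$wt, file.path(dir, "wt.tagAlign"))
  write_tags(sim$control, file.path(dir, "control.tagAlign"))
  readr::write_tsv(sim$truth$sites, file.path(dir, "truth_sites.tsv"))
  tr <- sim$truth$repeats
  readr::write_tsv(tibble(chrom = tr$chrom, start = tr$start, end = tr$end,
                          name = paste(tr$class, tr$motif, sep = "|")),
                   file.path(dir, "truth_repeats.bed"), col_names = FALSE)
  invisible(dir)
}

#' Reload simulation truth written by [write_simulation()]
#'
#' @param dir Directory holding `truth_sites.tsv` and `truth_repeats.bed`.
#' @return List of `sites` and `repeats` tibbles.
#' @export
read_truth <- function(dir) {
  sites <- readr::read_tsv(file.path(dir, "truth_sites.tsv"),
                           col_types = "ciccd", progress = FALSE)
  rb <- read_bed(file.path(dir, "truth_repeats.bed"))
  parts <- strsplit(rb$name, "|", fixed = TRUE)
  list(sites = sites,
       repeats = tibble(chrom = rb$chrom, start = rb$start, end = rb$end,
                        class = vapply(parts, `[[`, "", 1),
                        motif = vapply(parts, `[[`, "", 2)))
}

#' Score called sites against simulation truth
#'
#' A called site matches a planted site when their centers lie within
#' `match_distance` bp; matching is one-to-one and greedy by distance.
#' Precision with zero calls is reported as 1 with zero support and
#' flagged. If classification columns are present on the called sites,
#' one-endedness and orientation accuracy among matched sites are scored
#' against the planted types.
#'
#' @param called Site tibble (called windows; centers from `center` or the
#'   window midpoint).
#' @param truth Truth site tibble (from [simulate_genome()]), or the subset
#'   of types the call set targets.
#' @param match_distance Maximum center distance for a match (bp).
#' @return A `recovery_result` list; see [tidy.recovery_result()].
#' @export
evaluate_recovery <- function(called, truth, match_distance = 500) {
  center <- if ("center" %in% names(called)) called$center
            else interval_center(called$start, called$end)
  pairs <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    j <- which(called$chrom == truth$chrom[i] &
                 abs(center - truth$pos[i]) <= match_distance)
    if (length(j) == 0) return(tibble())
    tibble(truth_idx = i, called_idx = j,
           dist = abs(center[j] - truth$pos[i]))
  })
  matched <- tibble(truth_idx = integer(), called_idx = integer())
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(pairs$dist), ]
    used_t <- logical(nrow(truth)); used_c <- logical(nrow(called))
    for (k in seq_len(nrow(pairs))) {
      ti <- pairs$truth_idx[k]; ci <- pairs$called_idx[k]
      if (!used_t[ti] && !used_c[ci]) {
        used_t[ti] <- TRUE; used_c[ci] <- TRUE
        matched <- dplyr::bind_rows(matched,
                                    tibble(truth_idx = ti, called_idx = ci))
      }
    }
  }
  recall_by_type <- truth |>
    mutate(matched = seq_len(nrow(truth)) %in% matched$truth_idx) |>
    group_by(.data$type) |>
    summarise(n_planted = n(), n_recovered = sum(.data$matched),
              recall = mean(.data$matched), .groups = "drop")
  no_support <- nrow(called) == 0
  precision <- if (no_support) 1 else nrow(matched) / nrow(called)

  class_acc <- NULL
  if (nrow(matched) > 0 && "one_ended" %in% names(called)) {
    truth_one <- truth$type[matched$truth_idx] == "aid_dep_one_ended"
    called_one <- called$one_ended[matched$called_idx]
    ok <- !is.na(called_one)
    class_acc <- tibble(
      one_ended_accuracy = mean(called_one[ok] == truth_one[ok]),
      n_one_ended_scored = sum(ok))
    if ("orientation" %in% names(called)) {
      t_type <- truth$type[matched$truth_idx]
      expect <- dplyr::case_when(t_type == "tf_like" ~ "tf_like",
                                 t_type == "aid_dep_one_ended" ~ NA_character_,
                                 TRUE ~ "dsb_like")
      o <- called$orientation[matched$called_idx]
      keep <- !is.na(expect)
      class_acc$orientation_accuracy <- mean(o[keep] == expect[keep])
      class_acc$n_orientation_scored <- sum(keep)
    }
  }
  structure(list(precision = precision, precision_no_support = no_support,
                 n_called = nrow(called), n_matched = nrow(matched),
                 recall_by_type = recall_by_type,
                 classification = class_acc, matched = matched),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %d called, %d matched; precision %.3f%s\n",
              x$n_called, x$n_matched, x$precision,
              if (x$precision_no_support) " (no calls: reported 1 by convention)"
              else ""))
  print(x$recall_by_type)
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}

#' Tidy a recovery result
#'
#' @param x A `recovery_result`.
#' @param ... Unused.
#' @return Per-type recall tibble with overall precision attached.
#' @method tidy recovery_result
#' @export
tidy.recovery_result <- function(x, ...) {
  out <- x$recall_by_type
  out$precision <- x$precision
  out
}

#' @rdname tidy.recovery_result
#' @method glance recovery_result
#' @export
glance.recovery_result <- function(x, ...) {
  tibble(n_called = x$n_called, n_matched = x$n_matched,
         precision = x$precision,
         recall = sum(x$recall_by_type$n_recovered) /
           sum(x$recall_by_type$n_planted))
}
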