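#' Run the full break-mapping pipeline
#'
#' Orchestrates the stages end to end: duplicate capping, fragment-length
#' estimation, control-referenced calling with the tier filter
#' (AID-dependent sites), no-control calling with the ratio cap
#' (AID-independent sites), strand-bias and orientation classification,
#' tandem-repeat summarisation, the matched-random-interval background and
#' permutation tests against any annotation sets. Outputs are
#' deterministic given the seed; each stage's input/output counts are
#' logged and collected in the report.
#'
#' @param wt,control WT and control tag libraries ([tag_library()]s or
#'   tagAlign paths).
#' @param genome [Biostrings::DNAStringSet] or FASTA path (`NULL` skips the
#'   repeat stage).
#' @param chrom_sizes Chrom-sizes tibble or path.
#' @param tiers Tier profile for the AID-dependent filter (see
#'   [tier_profile()]).
#' @param annotations Named list of interval tibbles (or BED paths) to test
#'   for co-occurrence with the AID-dependent sites.
#' @param max_duplicates Duplicate cap per position (default 1).
#' @param fold_threshold,tag_floor,pseudocount,span Candidate-calling
#'   parameters (see [call_candidates()]).
#' @param max_ratio,background_threshold AID-independent calling parameters
#'   (see [call_aid_independent()]).
#' @param bias_threshold_log2 One-endedness threshold (see [strand_bias()]).
#' @param n_background Random intervals for the repeat background.
#' @param n_trials Permutation trials per annotation set.
#' @param seed Seed for the background draw and permutation tests.
#' @param out_dir Optional directory; when given, site tables (TSV + BED),
#'   coverage tracks and the report are written there.
#' @param verbose Print stage logs?
#' @return A `pipeline_report` list; see [tidy.pipeline_report()].
#' @export
run_pipeline <- function(wt, control, genome = NULL, chrom_sizes,
                         tiers = "exp1", annotations = list(),
                         max_duplicates = 1L, fold_threshold = 2.0,
                         tag_floor = 10L, pseudocount = 0.5, span = 10000L,
                         max_ratio = 1.4, background_threshold = 4.0,
                         bias_threshold_log2 = 1.5, n_background = 2000L,
                         n_trials = 1000L, seed = 1L, out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (is.character(wt)) wt <- read_tags(wt, chrom_sizes)
  if (is.null(control)) {
    abort("Missing control library: AID-dependent calling needs one.")
  }
  if (is.character(control)) control <- read_tags(control, chrom_sizes)
  if (is.character(genome)) genome <- read_genome(genome)
  annotations <- lapply(annotations, function(a)
    if (is.character(a)) read_bed(a) else a)

  n_raw <- c(wt = nrow(wt), control = nrow(control))
  wt <- deduplicate(wt, max_duplicates)
  control <- deduplicate(control, max_duplicates)
  say("dedup: WT %d -> %d tags, control %d -> %d tags",
      n_raw["wt"], nrow(wt), n_raw["control"], nrow(control))

  # sonication is common to both ChIPs, and the control library has no
  # enriched sites to anchor a cross-correlation peak, so the WT estimate
  # is shared with the control
  wt <- with_fragment_length(wt, chrom_sizes)
  attr(control, "fragment_length") <- fragment_length(wt)
  say("fragment length: %d bp (WT estimate, shared with the control)",
      fragment_length(wt))

  cand <- call_candidates(wt, control, chrom_sizes, fold_threshold = fold_threshold,
                          tag_floor = tag_floor, pseudocount = pseudocount,
                          span = span)
  dep <- apply_tier_filter(cand, tiers, chrom_sizes, wt = wt)
  say("calling: %d candidates -> %d AID-dependent sites after the tier filter",
      nrow(cand), nrow(dep))
  indep <- call_aid_independent(wt, control, chrom_sizes,
                                max_ratio = max_ratio,
                                background_threshold = background_threshold,
                                tag_floor = tag_floor,
                                pseudocount = pseudocount, span = span)
  # sites already claimed as AID-dependent are not offered as independent
  if (nrow(indep) > 0 && nrow(dep) > 0) {
    dep_iv <- tibble(chrom = dep$chrom, start = dep$ext_start, end = dep$ext_end)
    ind_iv <- tibble(chrom = indep$chrom, start = indep$ext_start,
                     end = indep$ext_end)
    overl <- vapply(seq_len(nrow(indep)), function(i)
      intersect_count(ind_iv[i, ], dep_iv) > 0, logical(1))
    indep <- indep[!overl, ]
  }
  say("AID-independent calling: %d sites", nrow(indep))

  dep <- classify_sites(dep, wt, bias_threshold_log2 = bias_threshold_log2)
  indep <- classify_sites(indep, wt, bias_threshold_log2 = bias_threshold_log2)
  one_ended_fraction <- if (nrow(dep) > 0) {
    cl <- !is.na(dep$one_ended)
    if (any(cl)) mean(dep$one_ended[cl]) else NA_real_
  } else NA_real_
  say("strand classification: one-ended fraction %.3f among AID-dependent sites",
      one_ended_fraction)

  repeat_summary <- NULL; background <- NULL
  if (!is.null(genome)) {
    dep <- summarize_site_repeats(dep, genome)
    indep <- summarize_site_repeats(indep, genome)
    repeat_summary <- dplyr::bind_rows(
      site_class_summary(dep, "aid_dependent"),
      site_class_summary(indep, "aid_independent"))
    background <- genome_background(genome, n_intervals = n_background,
                                    sites = if (nrow(dep)) dep else NULL,
                                    seed = seed)
    repeat_summary <- dplyr::bind_rows(
      repeat_summary,
      tibble(set = "random_background", n_sites = background$summary$n_intervals,
             pct_wgcw = 100 * background$summary$wgcw_fraction,
             pct_ca = 100 * background$summary$ca_fraction,
             pct_either = 100 * mean(background$intervals$has_either)))
    say("repeats: %.1f%% of AID-dependent sites carry WGCW arrays, %.1f%% CA",
        repeat_summary$pct_wgcw[1], repeat_summary$pct_ca[1])
  }

  intersections <- NULL
  if (length(annotations) > 0 && nrow(dep) > 0) {
    dep_ext <- tibble(chrom = dep$chrom, start = dep$ext_start,
                      end = dep$ext_end)
    intersections <- purrr::imap_dfr(annotations, function(a, nm) {
      r <- randomization_test(dep_ext, a, chrom_sizes, n_trials = n_trials,
                              seed = seed)
      out <- tidy(r)
      out$target <- nm
      out
    })
    say("intersections: %d annotation set(s) tested", length(annotations))
  }

  report <- structure(list(
    stage_counts = tibble(
      stage = c("wt_tags_raw", "wt_tags_dedup", "control_tags_raw",
                "control_tags_dedup", "candidates", "aid_dependent_sites",
                "aid_independent_sites"),
      count = unname(c(n_raw["wt"], nrow(wt), n_raw["control"],
                       nrow(control), nrow(cand), nrow(dep), nrow(indep)))),
    fragment_length = c(wt = fragment_length(wt),
                        control = fragment_length(control)),
    sites = dplyr::bind_rows(dep, indep),
    one_ended_fraction = one_ended_fraction,
    repeat_summary = repeat_summary,
    background = background$summary,
    intersections = intersections,
    params = list(tiers = tiers, fold_threshold = fold_threshold,
                  tag_floor = tag_floor, max_ratio = max_ratio,
                  bias_threshold_log2 = bias_threshold_log2, seed = seed)),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(report$sites, file.path(out_dir, "sites.tsv"))
    write_sites_bed(report$sites, file.path(out_dir, "sites.bed"), chrom_sizes)
    write_coverage_bedgraph(wt, file.path(out_dir, "wt_coverage.bedGraph"),
                            chrom_sizes)
    write_coverage_bedgraph(wt, file.path(out_dir, "wt_stranded.bedGraph"),
                            chrom_sizes, stranded = TRUE, extend = FALSE)
    readr::write_tsv(report$stage_counts, file.path(out_dir, "stage_counts.tsv"))
    if (!is.null(report$repeat_summary)) {
      readr::write_tsv(report$repeat_summary,
                       file.path(out_dir, "repeat_summary.tsv"))
    }
    if (!is.null(report$intersections)) {
      readr::write_tsv(report$intersections,
                       file.path(out_dir, "intersections.tsv"))
    }
  }
  report
}

site_class_summary <- function(sites, label) {
  tibble(set = label, n_sites = nrow(sites),
         pct_wgcw = if (nrow(sites)) 100 * mean(sites$has_wgcw) else NA_real_,
         pct_ca = if (nrow(sites)) 100 * mean(sites$has_ca) else NA_real_,
         pct_either = if (nrow(sites)) 100 * mean(sites$has_either) else NA_real_)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$stage_counts)
  cat(sprintf("one-ended fraction (AID-dependent): %.3f\n",
              x$one_ended_fraction))
  if (!is.null(x$repeat_summary)) print(x$repeat_summary)
  if (!is.null(x$intersections)) print(x$intersections)
  invisible(x)
}

#' Tidy a pipeline report
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return The stage-count tibble.
#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) x$stage_counts

#' @rdname tidy.pipeline_report
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    n_aid_dependent = x$stage_counts$count[x$stage_counts$stage ==
                                             "aid_dependent_sites"],
    n_aid_independent = x$stage_counts$count[x$stage_counts$stage ==
                                               "aid_independent_sites"],
    one_ended_fraction = x$one_ended_fraction,
    pct_wgcw = if (!is.null(x$repeat_summary)) x$repeat_summary$pct_wgcw[1]
               else NA_real_,
    pct_ca = if (!is.null(x$repeat_summary)) x$repeat_summary$pct_ca[1]
             else NA_real_)
}
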