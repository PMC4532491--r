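#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join row_number n desc across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois rnorm rbinom runif median setNames
NULL

# Internal: validate a chrom-sizes tibble (chrom, size).
check_chrom_sizes <- function(chrom_sizes) {
  if (!is.data.frame(chrom_sizes) ||
      !all(c("chrom", "size") %in% names(chrom_sizes))) {
    abort("`chrom_sizes` must be a data frame with columns `chrom` and `size`.")
  }
  if (any(chrom_sizes$size <= 0)) {
    abort("All chromosome sizes must be positive.")
  }
  if (anyDuplicated(chrom_sizes$chrom)) {
    abort("Duplicated chromosome names in `chrom_sizes`.")
  }
  invisible(chrom_sizes)
}

chrom_size_lookup <- function(chrom_sizes) {
  setNames(chrom_sizes$size, chrom_sizes$chrom)
}

# Internal: validate an interval tibble (chrom, start, end) against sizes.
check_intervals <- function(x, chrom_sizes = NULL) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort("Interval tables need columns `chrom`, `start`, `end`.")
  }
  if (nrow(x) > 0 && any(x$start < 0 | x$end <= x$start)) {
    abort("Intervals must satisfy 0 <= start < end (0-based half-open).")
  }
  if (!is.null(chrom_sizes)) {
    sizes <- chrom_size_lookup(chrom_sizes)
    if (nrow(x) > 0) {
      unknown <- setdiff(unique(x$chrom), names(sizes))
      if (length(unknown) > 0) {
        abort(paste0("Unknown chromosome(s): ", paste(unknown, collapse = ", ")))
      }
      if (any(x$end > sizes[x$chrom])) {
        abort("Interval end exceeds chromosome length.")
      }
    }
  }
  invisible(x)
}

interval_center <- function(start, end) floor((start + end) / 2)
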