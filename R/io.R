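#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a tab-separated file with chromosome name and length.
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       col_types = readr::cols(readr::col_character(),
                                               readr::col_double()),
                       progress = FALSE)
  check_chrom_sizes(x)
  x
}

#' Write a chromosome-sizes table
#'
#' @param chrom_sizes Tibble with columns `chrom`, `size`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  check_chrom_sizes(chrom_sizes)
  readr::write_tsv(chrom_sizes, path, col_names = FALSE)
  invisible(path)
}

#' Construct a tag library
#'
#' A tag library is a tibble of aligned-read 5' ends — one row per tag with
#' columns `chrom`, `pos` (0-based 5'-end position) and `strand` (`"+"` or
#' `"-"`) — carrying the library size (its row count), the read length and,
#' once estimated, the fragment length as attributes.
#'
#' @param tags Data frame with columns `chrom`, `pos`, `strand`.
#' @param read_length Read length in bp (default 36).
#' @param fragment_length Optional known fragment length in bp.
#' @return A `tag_library` tibble.
#' @export
tag_library <- function(tags, read_length = 36L, fragment_length = NULL) {
  tags <- as_tibble(tags)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tags)))
  if (nrow(tags) > 0 && !all(tags$strand %in% c("+", "-"))) {
    abort("Tag strand must be '+' or '-'.")
  }
  structure(
    tags[c("chrom", "pos", "strand")],
    class = c("tag_library", class(tags)),
    read_length = as.integer(read_length),
    fragment_length = if (!is.null(fragment_length)) as.integer(fragment_length)
  )
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("<tag_library> %d tags, read length %d bp, fragment length %s\n",
              nrow(x), attr(x, "read_length"),
              if (is.null(attr(x, "fragment_length"))) "unset"
              else paste0(attr(x, "fragment_length"), " bp")))
  NextMethod()
}

#' Library size of a tag library
#' @param tags A `tag_library`.
#' @return Number of retained tags.
#' @export
library_size <- function(tags) nrow(tags)

#' Fragment length stored on a tag library
#' @param tags A `tag_library`.
#' @return Fragment length in bp, or `NULL` if not yet estimated.
#' @export
fragment_length <- function(tags) attr(tags, "fragment_length")

#' Read aligned tags from a tagAlign/BED6 file
#'
#' The 5' end of a plus-strand read is the BED start; of a minus-strand read
#' the BED end minus one (half-open BED intervals). Records on chromosomes
#' absent from `chrom_sizes` are dropped with a warning reporting how many.
#'
#' @param path tagAlign/BED6 file (>= 6 tab-separated columns).
#' @param chrom_sizes Optional chrom-sizes tibble used to reject records on
#'   unknown chromosomes.
#' @param read_length Read length recorded on the library (bp).
#' @return A [tag_library()].
#' @export
read_tags <- function(path, chrom_sizes = NULL, read_length = 36L) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tag_library(tibble(chrom = character(), pos = integer(),
                              strand = character()),
                       read_length = read_length))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf("Malformed tagAlign/BED6 record at line %d: %d column(s), need >= 6.",
                  which(nf < 6)[1], nf[which(nf < 6)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  strand <- vapply(fields, `[[`, "", 6L)
  bad <- which(is.na(start) | is.na(end) | end <= start | !strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("Malformed tagAlign/BED6 record at line %d: %s",
                  bad[1], lines[bad[1]]))
  }
  tags <- tibble(chrom = chrom,
                 pos = ifelse(strand == "+", start, end - 1L),
                 strand = strand)
  if (!is.null(chrom_sizes)) {
    check_chrom_sizes(chrom_sizes)
    keep <- tags$chrom %in% chrom_sizes$chrom
    if (any(!keep)) {
      warn(sprintf("Dropped %d tag(s) on chromosome(s) absent from chrom_sizes.",
                   sum(!keep)))
      tags <- tags[keep, ]
    }
  }
  tag_library(tags, read_length = read_length)
}

#' Write a tag library as tagAlign/BED6
#'
#' Inverse of [read_tags()]: a plus-strand tag becomes the interval
#' `[pos, pos + read_length)`, a minus-strand tag `[pos - read_length + 1,
#' pos + 1)`, so a read-then-write round trip preserves every 5' position.
#'
#' @param tags A [tag_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  rl <- attr(tags, "read_length") %||% 36L
  start <- ifelse(tags$strand == "+", tags$pos, tags$pos - rl + 1L)
  out <- tibble(chrom = tags$chrom, start = pmax(start, 0L),
                end = start + rl, name = "tag", score = 0L,
                strand = tags$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

# Internal: encode site flags into a BED name token.
site_name <- function(sites) {
  flag <- function(cond, token) ifelse(!is.na(cond) & cond, token, NA_character_)
  mat <- cbind(sprintf("site%04d", seq_len(nrow(sites))),
               flag(sites$aid_dependent %||% rep(FALSE, nrow(sites)), "aid_dependent"),
               flag(sites$aid_independent %||% rep(FALSE, nrow(sites)), "aid_independent"),
               flag(sites$one_ended %||% rep(NA, nrow(sites)), "one_ended"),
               if ("orientation" %in% names(sites)) sites$orientation else NULL)
  apply(mat, 1, function(r) paste(r[!is.na(r)], collapse = "|"))
}

#' Write called sites as BED6
#'
#' The 500-bp called window is the BED interval, the score column carries the
#' WT tag count, and the name column encodes the site's classification flags
#' (`aid_dependent`, `aid_independent`, `one_ended`, orientation) separated by
#' `|` so a round trip preserves them.
#'
#' @param sites Site tibble (see [call_aid_dependent_sites()]).
#' @param path Output path.
#' @param chrom_sizes Optional chrom-sizes tibble; intervals outside it error.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, chrom_sizes = NULL) {
  if (nrow(sites) > 0) check_intervals(sites, chrom_sizes)
  out <- tibble(chrom = sites$chrom, start = sites$start, end = sites$end,
                name = if (nrow(sites)) site_name(sites) else character(),
                score = if ("wt_tags" %in% names(sites)) sites$wt_tags
                        else rep(0L, nrow(sites)),
                strand = ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a sites BED6 written by [write_sites_bed()]
#'
#' @param path BED6 path.
#' @return Tibble with window coordinates, `wt_tags` and decoded flags.
#' @export
read_sites_bed <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom", "start", "end", "name", "score", "strand"),
                       col_types = "ciicic", progress = FALSE)
  tibble(chrom = x$chrom, start = x$start, end = x$end,
         wt_tags = x$score,
         aid_dependent = grepl("aid_dependent", x$name, fixed = TRUE),
         aid_independent = grepl("aid_independent", x$name, fixed = TRUE),
         one_ended = grepl("one_ended", x$name, fixed = TRUE),
         orientation = dplyr::case_when(
           grepl("dsb_like", x$name) ~ "dsb_like",
           grepl("tf_like", x$name) ~ "tf_like",
           grepl("indeterminate", x$name) ~ "indeterminate",
           TRUE ~ NA_character_))
}

#' Read a plain BED file of intervals
#'
#' @param path BED3+ path.
#' @return Tibble with `chrom`, `start`, `end` and, if present, `name`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  out <- tibble(chrom = x[[1]], start = as.integer(x[[2]]), end = as.integer(x[[3]]))
  if (ncol(x) >= 4) out$name <- x[[4]]
  check_intervals(out)
  out
}

#' Write intervals as BED
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  readr::write_tsv(x[cols], path, col_names = FALSE)
  invisible(path)
}

#' Write fragment-extended coverage as bedGraph
#'
#' Each tag is extended from its 5' end to `fragment_length` bp in the read
#' direction (clamped at chromosome edges, never an error) and per-base
#' coverage is emitted as bedGraph runs; adjacent equal values merge and
#' zero-coverage runs are omitted. With `stranded = TRUE` two files are
#' written (suffixes `.plus` / `.minus` before the extension), using extended
#' or raw 5'-end coverage per `extend`.
#'
#' @param tags A [tag_library()].
#' @param path Output path (basename used for stranded pair).
#' @param chrom_sizes Chrom-sizes tibble.
#' @param fragment_length Extension length in bp; defaults to the library's
#'   stored fragment length.
#' @param stranded Write one file per strand?
#' @param extend Extend reads to `fragment_length`? (Stranded break-end views
#'   are often clearer unextended.)
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_coverage_bedgraph <- function(tags, path, chrom_sizes,
                                    fragment_length = NULL, stranded = FALSE,
                                    extend = TRUE) {
  check_chrom_sizes(chrom_sizes)
  fl <- fragment_length %||% attr(tags, "fragment_length")
  if (extend && is.null(fl)) {
    abort("Need `fragment_length` (argument or estimated on the library).")
  }
  emit <- function(df, out_path) {
    sizes <- chrom_size_lookup(chrom_sizes)
    runs <- purrr::map_dfr(sort(unique(df$chrom)), function(ch) {
      d <- df[df$chrom == ch, ]
      len <- if (extend) fl else attr(tags, "read_length") %||% 1L
      start <- ifelse(d$strand == "+", d$pos, d$pos - len + 1L)
      end <- start + len
      start <- pmax(start, 0L)
      end <- pmin(end, sizes[[ch]])
      keep <- end > start
      cov <- IRanges::coverage(IRanges::IRanges(start[keep] + 1L, end[keep]),
                               width = sizes[[ch]])
      rl <- S4Vectors::runLength(cov)
      rv <- S4Vectors::runValue(cov)
      ends <- cumsum(rl)
      starts <- ends - rl
      keep_run <- rv > 0
      tibble(chrom = ch, start = starts[keep_run], end = ends[keep_run],
             value = rv[keep_run])
    })
    readr::write_tsv(runs, out_path, col_names = FALSE)
    out_path
  }
  if (!stranded) {
    invisible(emit(tags, path))
  } else {
    ext <- tools::file_ext(path)
    stem <- if (nzchar(ext)) sub(paste0("\\.", ext, "$"), "", path) else path
    suffix <- function(s) if (nzchar(ext)) paste0(stem, s, ".", ext) else paste0(stem, s)
    paths <- c(emit(tags[tags$strand == "+", ], suffix(".plus")),
               emit(tags[tags$strand == "-", ], suffix(".minus")))
    invisible(paths)
  }
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome sizes of a genome
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @return Tibble with `chrom`, `size`.
#' @export
genome_sizes <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    tibble(chrom = names(genome), size = Biostrings::width(genome))
  } else {
    tibble(chrom = names(genome), size = nchar(genome))
  }
}
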