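#' Read one cell's contact list
#'
#' Parses the plain pairs format emitted by scHi-C processing pipelines:
#' whitespace- or tab-separated columns `chromA posA chromB posB`, one
#' ligation per line. Extra columns are ignored, as are blank lines and
#' lines starting with `#`. Intrachromosomal contacts (`chromA == chromB`)
#' are kept: they do not become network edges but mark their bins as active.
#'
#' @param path Path to a per-cell contacts file.
#' @param chrom_sizes Chromosome-sizes tibble (see [read_chrom_sizes()]);
#'   used to validate chromosome names and position ranges.
#' @param policy `"strict"` errors on a contact with an unknown chromosome or
#'   an out-of-range position; `"skip"` drops such records and counts them in
#'   the `n_skipped` attribute of the result.
#' @param cell_id Cell identifier; defaults to the file name without
#'   extension.
#' @return A tibble with columns `chromA`, `posA`, `chromB`, `posB`,
#'   `cell_id`, and attribute `n_skipped` (number of dropped records under
#'   `policy = "skip"`).
#' @export
read_cell_contacts <- function(path, chrom_sizes, policy = c("strict", "skip"),
                               cell_id = NULL) {
  policy <- match.arg(policy)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  if (!file.exists(path)) abort_input("contacts file not found: %s", path)
  cell_id <- cell_id %||% sub("\\.[^.]*$", "", basename(path))

  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- tibble::tibble(chromA = character(), posA = double(),
                          chromB = character(), posB = double(),
                          cell_id = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }

  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    abort_parse("line %d of %s has fewer than 4 columns",
                lineno[which(nf < 4L)[1L]], path)
  }
  chromA <- vapply(fields, `[[`, "", 1L)
  chromB <- vapply(fields, `[[`, "", 3L)
  posA <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  posB <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(posA) | is.na(posB) |
                 posA != trunc(posA) | posB != trunc(posB))
  if (length(bad) > 0L) {
    abort_parse("line %d of %s has a non-integer position", lineno[bad[1L]], path)
  }

  lenA <- chrom_sizes$length[match(chromA, chrom_sizes$chrom)]
  lenB <- chrom_sizes$length[match(chromB, chrom_sizes$chrom)]
  invalid <- is.na(lenA) | is.na(lenB) |
    posA < 0 | posA >= lenA | posB < 0 | posB >= lenB
  if (any(invalid) && policy == "strict") {
    i <- which(invalid)[1L]
    abort_input("line %d of %s: unknown chromosome or out-of-range position (%s:%s - %s:%s)",
                lineno[i], path, chromA[i], format(posA[i]), chromB[i], format(posB[i]))
  }

  out <- tibble::tibble(chromA = chromA, posA = posA,
                        chromB = chromB, posB = posB,
                        cell_id = cell_id)[!invalid, ]
  attr(out, "n_skipped") <- sum(invalid)
  out
}

#' Read a directory of per-cell contact files
#'
#' Each file is one cell; the cell id is the file name without extension.
#'
#' @param dir Directory containing per-cell pairs files.
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param policy See [read_cell_contacts()].
#' @param pattern Regular expression selecting contact files; the default
#'   takes `.txt`/`.tsv`/`.pairs` files not starting with `_` (so simulator
#'   ledgers are ignored).
#' @return A tibble of all contacts (columns as in [read_cell_contacts()])
#'   with attribute `n_skipped` summed over files.
#' @export
read_contacts_dir <- function(dir, chrom_sizes, policy = c("strict", "skip"),
                              pattern = "^[^_].*\\.(txt|tsv|pairs)$") {
  policy <- match.arg(policy)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) abort_input("no contact files matching '%s' in %s", pattern, dir)
  parts <- purrr::map(files, read_cell_contacts,
                      chrom_sizes = chrom_sizes, policy = policy)
  out <- dplyr::bind_rows(parts)
  attr(out, "n_skipped") <- sum(vapply(parts, attr, 0L, "n_skipped"))
  out
}

#' Read a genomic feature track (BED3+)
#'
#' @param path Path to a BED file; only the first three columns are used.
#'   Coordinates are 0-based half-open. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param name Track name; defaults to the file name without extension.
#' @return A tibble with columns `chrom`, `start`, `end` and attribute
#'   `track_name`.
#' @export
read_feature_track <- function(path, name = NULL) {
  if (!file.exists(path)) abort_input("feature track not found: %s", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort_parse("line %d of %s has fewer than 3 columns", lineno[which(nf < 3L)[1L]], path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort_parse("non-numeric coordinate in %s", path)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0L) {
    abort_parse("line %d of %s: interval start must be < end and >= 0",
                lineno[bad[1L]], path)
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  attr(out, "track_name") <- name
  out
}

#' Write identified regions as BED
#'
#' One row per identified region (bin touched by at least one significant
#' edge): `chrom start end node_<i> <significant-edge count>`, sorted by
#' chromosome order of the binning scheme then start. A header comment line
#' is always written, so an empty result yields a file with the header only.
#'
#' @param result A `schic_result` from [call_frequent_edges()] or
#'   [schic_call()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(result, path) {
  stopifnot(inherits(result, "schic_result"))
  regions <- result$regions
  header <- "#chrom\tstart\tend\tname\tsig_edges"
  body <- sprintf("%s\t%d\t%d\tnode_%d\t%d",
                  regions$chrom, as.integer(regions$start),
                  as.integer(regions$end), regions$node, regions$degree)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a regions BED written by [write_regions_bed()]
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `node`, `degree`.
#' @export
read_regions_bed <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = double(), end = double(),
                          node = integer(), degree = integer()))
  }
  fields <- strsplit(lines, "\t")
  tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    node = as.integer(sub("^node_", "", vapply(fields, `[[`, "", 4L))),
    degree = as.integer(vapply(fields, `[[`, "", 5L))
  )
}

#' Write significant edges as a Circos link file
#'
#' One line per significant edge: the two bin intervals followed by the
#' recurrence count and the Bonferroni-adjusted p-value as annotation
#' fields, e.g. `chr1 0 500000 chr2 500000 1000000 t=12 padj=1.00000e-06`.
#' Lines are ordered by adjusted p-value, ties broken by node-pair order,
#' so repeated runs produce byte-identical files.
#'
#' @inheritParams write_regions_bed
#' @return `path`, invisibly.
#' @export
write_links <- function(result, path) {
  stopifnot(inherits(result, "schic_result"))
  e <- dplyr::filter(result$edges, .data$significant)
  body <- sprintf("%s %d %d %s %d %d t=%d padj=%s",
                  e$chromA, as.integer(e$startA), as.integer(e$endA),
                  e$chromB, as.integer(e$startB), as.integer(e$endB),
                  e$t, format_pval(e$p_adj))
  writeLines(body, path)
  invisible(path)
}

#' Read back a Circos link file written by [write_links()]
#'
#' @param path Path to the link file.
#' @return A tibble with the two intervals, `t` and `p_adj`.
#' @export
read_links <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chromA = character(), startA = double(), endA = double(),
                          chromB = character(), startB = double(), endB = double(),
                          t = integer(), p_adj = double()))
  }
  f <- strsplit(lines, " +")
  tibble::tibble(
    chromA = vapply(f, `[[`, "", 1L),
    startA = as.numeric(vapply(f, `[[`, "", 2L)),
    endA = as.numeric(vapply(f, `[[`, "", 3L)),
    chromB = vapply(f, `[[`, "", 4L),
    startB = as.numeric(vapply(f, `[[`, "", 5L)),
    endB = as.numeric(vapply(f, `[[`, "", 6L)),
    t = as.integer(sub("^t=", "", vapply(f, `[[`, "", 7L))),
    p_adj = as.numeric(sub("^padj=", "", vapply(f, `[[`, "", 8L)))
  )
}

#' Write the full per-edge test report as TSV
#'
#' One row per tested edge (every cross-chromosome bin pair observed in at
#' least one cell) with its intervals, recurrence count `t`, pooled edge
#' probability `p`, raw binomial p-value, Bonferroni-adjusted p-value and
#' significance flag. Probabilities are printed in scientific notation with
#' six significant digits.
#'
#' @inheritParams write_regions_bed
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(result, path) {
  stopifnot(inherits(result, "schic_result"))
  e <- result$edges
  out <- data.frame(
    chromA = e$chromA, startA = as.integer(e$startA), endA = as.integer(e$endA),
    chromB = e$chromB, startB = as.integer(e$startB), endB = as.integer(e$endB),
    node_a = e$node_a, node_b = e$node_b, t = e$t,
    p = format_pval(e$p), p_value = format_pval(e$p_value),
    p_adj = format_pval(e$p_adj),
    significant = ifelse(e$significant, "TRUE", "FALSE")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back an edge report written by [write_edges_tsv()]
#'
#' @param path Path to the TSV report.
#' @return A tibble mirroring the `edges` table of a `schic_result`.
#' @export
read_edges_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    chromA = "c", startA = "d", endA = "d",
                    chromB = "c", startB = "d", endB = "d",
                    node_a = "i", node_b = "i", t = "i",
                    p = "d", p_value = "d", p_adj = "d", significant = "l"
                  ))
}
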