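#' Read a chromosome-sizes table
#'
#' Parses the standard two-column `chrom.sizes` format: chromosome name and
#' length in base pairs, whitespace separated, one chromosome per line.
#' Lines starting with `#` are ignored. The file order of chromosomes is
#' preserved and later governs global bin (node) indexing.
#'
#' @param path Path to a chrom.sizes file.
#' @return A tibble with columns `chrom` (character) and `length` (double,
#'   base pairs).
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1 2000000", "chr2 1500000"), f)
#' read_chrom_sizes(f)
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) abort_input("chrom.sizes file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort_input("chrom.sizes file is empty: %s", path)
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    abort_parse("chrom.sizes line %d has fewer than 2 columns", bad[1L])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len)) {
    abort_parse("chrom.sizes line %d has a non-numeric length",
                which(is.na(len))[1L])
  }
  validate_chrom_sizes(tibble::tibble(chrom = chrom, length = len))
}

validate_chrom_sizes <- function(chrom_sizes) {
  if (!is.data.frame(chrom_sizes) || nrow(chrom_sizes) == 0L) {
    abort_input("chrom_sizes must be a non-empty data frame")
  }
  if (!all(c("chrom", "length") %in% names(chrom_sizes))) {
    abort_input("chrom_sizes must have columns 'chrom' and 'length'")
  }
  if (anyDuplicated(chrom_sizes$chrom)) {
    abort_input("chromosome names must be unique")
  }
  if (any(chrom_sizes$length <= 0)) {
    abort_input("chromosome lengths must be positive")
  }
  tibble::as_tibble(chrom_sizes[c("chrom", "length")])
}

#' Partition a genome into equal-sized bins
#'
#' Divides each chromosome into consecutive bins of `bin_size` bp using
#' 0-based half-open intervals `[start, end)`. With `offset = 0` bin `k` of a
#' chromosome is `[k * bin_size, (k + 1) * bin_size)`, truncated at the
#' chromosome end. A sliding-window `offset` s shifts all interior boundaries
#' by s: the first bin is the partial interval `[0, s)` and the last bin may
#' be partial, so that every base of the genome stays covered and every
#' contact remains mappable. Bins are numbered by consecutive global node
#' indices starting at 0, in chromosome order then bin order.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `length`
#'   (see [read_chrom_sizes()]); its row order fixes the node indexing.
#' @param bin_size Bin width in bp (default 500 kb).
#' @param offset Sliding-window shift in bp, `0 <= offset < bin_size`.
#' @return A tibble of class `schic_binning` with one row per bin and columns
#'   `chrom`, `start`, `end`, `node`, carrying the binning parameters as
#'   attributes.
#' @export
#' @examples
#' sizes <- tibble::tibble(chrom = "chr1", length = 1200000)
#' make_binning(sizes, bin_size = 500000)
#' make_binning(sizes, bin_size = 500000, offset = 100000)
make_binning <- function(chrom_sizes, bin_size = 500000, offset = 0) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  if (!is_count(bin_size, min = 1)) abort_param("bin_size must be a positive integer")
  if (!is_count(offset) || offset >= bin_size) {
    abort_param("offset must satisfy 0 <= offset < bin_size (got offset=%s, bin_size=%s)",
                format(offset), format(bin_size))
  }
  bins <- purrr::map2_dfr(chrom_sizes$chrom, chrom_sizes$length, function(ch, len) {
    breaks <- if (offset == 0) {
      seq(0, len, by = bin_size)
    } else if (offset >= len) {
      c(0, len)
    } else {
      c(0, seq(offset, len, by = bin_size))
    }
    if (breaks[length(breaks)] < len) breaks <- c(breaks, len)
    breaks <- unique(breaks)
    tibble::tibble(
      chrom = ch,
      start = breaks[-length(breaks)],
      end = breaks[-1L]
    )
  })
  bins$node <- seq_len(nrow(bins)) - 1L
  structure(
    bins,
    class = c("schic_binning", class(tibble::tibble())),
    bin_size = bin_size,
    offset = offset,
    chrom_sizes = chrom_sizes
  )
}

binning_chrom_sizes <- function(binning) attr(binning, "chrom_sizes", exact = TRUE)

#' @export
print.schic_binning <- function(x, ...) {
  cat(sprintf("<schic_binning> %d bins, %d chromosomes, bin_size=%s, offset=%s\n",
              nrow(x), nrow(binning_chrom_sizes(x)),
              format(attr(x, "bin_size"), big.mark = ","),
              format(attr(x, "offset"), big.mark = ",")))
  NextMethod()
}

#' Map genomic positions to global bin indices
#'
#' @param binning A [make_binning()] scheme.
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based positions (recycled against `chrom`).
#' @return Integer vector of global node indices.
#' @export
#' @examples
#' b <- make_binning(tibble::tibble(chrom = c("chr1", "chr2"),
#'                                  length = c(1500000, 1500000)), 500000)
#' locus_to_bin(b, c("chr1", "chr2"), c(499999, 0))
locus_to_bin <- function(binning, chrom, pos) {
  sizes <- binning_chrom_sizes(binning)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  ci <- match(chrom, sizes$chrom)
  if (anyNA(ci)) {
    abort_input("unknown chromosome: %s", chrom[which(is.na(ci))[1L]])
  }
  len <- sizes$length[ci]
  bad <- which(pos < 0 | pos >= len)
  if (length(bad) > 0L) {
    abort_input("position %s out of range [0, %s) on %s",
                format(pos[bad[1L]]), format(len[bad[1L]]), chrom[bad[1L]])
  }
  out <- integer(n)
  for (ch in unique(chrom)) {
    rows <- which(binning$chrom == ch)
    sel <- which(chrom == ch)
    local <- findInterval(pos[sel], binning$start[rows])
    out[sel] <- binning$node[rows[local]]
  }
  out
}

#' Recover the genomic interval of a bin
#'
#' Inverse of [locus_to_bin()]: returns the chromosome and half-open
#' `[start, end)` interval of one or more global node indices.
#'
#' @param binning A [make_binning()] scheme.
#' @param node Integer vector of global node indices.
#' @return A tibble with columns `chrom`, `start`, `end`, `node`.
#' @export
bin_to_region <- function(binning, node) {
  total <- nrow(binning)
  bad <- which(node < 0 | node >= total | node != trunc(node))
  if (length(bad) > 0L) {
    abort_input("node index %s out of range [0, %d)", format(node[bad[1L]]), total)
  }
  tibble::as_tibble(binning)[node + 1L, c("chrom", "start", "end", "node")]
}
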