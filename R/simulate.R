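#' Simulate single-cell contact data with planted frequent edges
#'
#' Generates per-cell contact tables under the exact null of the recurrence
#' test, plus optional planted signal. For each cell, `n_background`
#' distinct cross-chromosome bin pairs are drawn uniformly from the full
#' pair space (Bernoulli edge occurrence, the assumption behind the
#' binomial test) and emitted as one contact each, with positions uniform
#' inside their bins. Each planted edge is independently included with its
#' prevalence. Same-bin intrachromosomal contacts are added at rate
#' `intra_rate` per cell (bins chosen uniformly) so that node activity, and
#' hence the search space, is controlled: with the default rate essentially
#' every bin is active. Rows are shuffled within each cell so downstream
#' code cannot rely on input order.
#'
#' @param chrom_sizes Chromosome-sizes tibble (>= 2 chromosomes).
#' @param bin_size Bin width in bp.
#' @param n_cells Number of cells N.
#' @param n_background Background trans edges per cell: a single count or a
#'   length-`n_cells` vector.
#' @param planted Optional tibble with columns `node_a`, `node_b`,
#'   `prevalence`: cross-chromosome node pairs (indices under the offset-0
#'   scheme) carried by each cell independently with probability
#'   `prevalence`.
#' @param intra_rate Expected same-bin intrachromosomal contacts per cell
#'   (Poisson).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param dir Optional directory: when given, one 4-column contacts file
#'   per cell (`<cell_id>.txt`), a `chrom.sizes` file and a
#'   `_ground_truth.tsv` ledger (the leading underscore keeps it out of
#'   [read_contacts_dir()]'s default file pattern) are written there.
#' @return A list of class `schic_sim`: `contacts` (tibble over all cells),
#'   `ground_truth` (planted edges with `prevalence`, `carried_t` = cells
#'   carrying the edge through the prevalence draw, `realized_t` = cells
#'   whose edge set contains the pair, including background collisions),
#'   `binning` (the offset-0 scheme), and `params`.
#' @export
simulate_cells <- function(chrom_sizes, bin_size = 500000, n_cells,
                           n_background, planted = NULL, intra_rate = 50,
                           seed = 1L, dir = NULL) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  if (nrow(chrom_sizes) < 2L) abort_param("need >= 2 chromosomes to simulate trans contacts")
  if (!is_count(n_cells, min = 1L)) abort_param("n_cells must be >= 1")
  binning <- make_binning(chrom_sizes, bin_size, offset = 0)
  n_bins <- nrow(binning)
  if (n_bins > 3000L) {
    abort_param("simulation enumerates all cross-chromosome bin pairs; %d bins is too many",
                n_bins)
  }
  chrom_of <- binning$chrom
  pairs <- utils::combn(seq_len(n_bins) - 1L, 2L)
  cross <- chrom_of[pairs[1L, ] + 1L] != chrom_of[pairs[2L, ] + 1L]
  pair_a <- pairs[1L, cross]
  pair_b <- pairs[2L, cross]
  n_pairs <- length(pair_a)

  n_background <- if (length(n_background) == 1L) {
    rep(as.integer(n_background), n_cells)
  } else if (length(n_background) == n_cells) {
    as.integer(n_background)
  } else {
    abort_param("n_background must be a scalar or length n_cells")
  }
  if (any(n_background < 0) || any(n_background > n_pairs)) {
    abort_param("n_background must lie in [0, %d] (the cross-chromosome pair count)",
                n_pairs)
  }

  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    if (!all(c("node_a", "node_b", "prevalence") %in% names(planted))) {
      abort_param("planted needs columns node_a, node_b, prevalence")
    }
    swap <- planted$node_a > planted$node_b
    tmp <- planted$node_a[swap]
    planted$node_a[swap] <- planted$node_b[swap]
    planted$node_b[swap] <- tmp
    if (any(planted$node_a < 0 | planted$node_b >= n_bins)) {
      abort_param("planted node indices out of range")
    }
    if (any(chrom_of[planted$node_a + 1L] == chrom_of[planted$node_b + 1L])) {
      abort_param("planted edges must join different chromosomes")
    }
    if (any(planted$prevalence < 0 | planted$prevalence > 1)) {
      abort_param("prevalences must lie in [0, 1]")
    }
  } else {
    planted <- tibble::tibble(node_a = integer(), node_b = integer(),
                              prevalence = double())
  }

  id_width <- max(3L, nchar(as.character(n_cells)))
  cell_ids <- sprintf(paste0("cell_%0", id_width, "d"), seq_len(n_cells))

  rand_pos <- function(node, n = length(node)) {
    start <- binning$start[node + 1L]
    end <- binning$end[node + 1L]
    floor(start + stats::runif(n) * (end - start))
  }

  n_planted <- nrow(planted)
  carried <- matrix(FALSE, nrow = n_planted, ncol = n_cells)
  realized <- matrix(FALSE, nrow = n_planted, ncol = n_cells)
  planted_key <- planted$node_a * n_bins + planted$node_b

  cells <- withr::with_seed(seed, {
    purrr::map(seq_len(n_cells), function(i) {
      idx <- sample.int(n_pairs, n_background[i])
      ea <- pair_a[idx]
      eb <- pair_b[idx]
      if (n_planted > 0L) {
        carry <- stats::runif(n_planted) < planted$prevalence
        carried[, i] <<- carry
        ea <- c(ea, planted$node_a[carry])
        eb <- c(eb, planted$node_b[carry])
        realized[, i] <<- planted_key %in% (ea * n_bins + eb)
      }
      keep <- !duplicated(ea * n_bins + eb)
      ea <- ea[keep]; eb <- eb[keep]
      trans <- tibble::tibble(
        chromA = chrom_of[ea + 1L], posA = rand_pos(ea),
        chromB = chrom_of[eb + 1L], posB = rand_pos(eb)
      )
      n_intra <- stats::rpois(1L, intra_rate)
      node <- sample.int(n_bins, n_intra, replace = TRUE) - 1L
      intra <- tibble::tibble(
        chromA = chrom_of[node + 1L], posA = rand_pos(node),
        chromB = chrom_of[node + 1L], posB = rand_pos(node)
      )
      out <- dplyr::bind_rows(trans, intra)
      out$cell_id <- cell_ids[i]
      out[sample.int(nrow(out)), ]
    })
  })

  ground_truth <- planted
  ground_truth$carried_t <- if (n_planted > 0L) as.integer(rowSums(carried)) else integer()
  ground_truth$realized_t <- if (n_planted > 0L) as.integer(rowSums(realized)) else integer()

  contacts <- dplyr::bind_rows(cells)
  sim <- structure(
    list(contacts = contacts, ground_truth = ground_truth, binning = binning,
         params = list(bin_size = bin_size, n_cells = n_cells,
                       n_background = n_background, intra_rate = intra_rate,
                       n_pairs = n_pairs, seed = seed)),
    class = "schic_sim"
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(sprintf("%s\t%d", chrom_sizes$chrom, as.integer(chrom_sizes$length)),
               file.path(dir, "chrom.sizes"))
    for (id in cell_ids) {
      cc <- contacts[contacts$cell_id == id, ]
      writeLines(sprintf("%s %d %s %d", cc$chromA, as.integer(cc$posA),
                         cc$chromB, as.integer(cc$posB)),
                 file.path(dir, paste0(id, ".txt")))
    }
    gt <- ground_truth
    writeLines(c("node_a\tnode_b\tprevalence\tcarried_t\trealized_t",
                 sprintf("%d\t%d\t%g\t%d\t%d", gt$node_a, gt$node_b,
                         gt$prevalence, gt$carried_t, gt$realized_t)),
               file.path(dir, "_ground_truth.tsv"))
  }
  sim
}

#' @export
print.schic_sim <- function(x, ...) {
  cat(sprintf("<schic_sim> %d cells, %d contacts, %d planted edge(s), %d-bin genome\n",
              x$params$n_cells, nrow(x$contacts), nrow(x$ground_truth),
              nrow(x$binning)))
  invisible(x)
}

#' Simulate a genomic feature track
#'
#' Builds a BED-like track of fixed-width intervals: `n_enriched` with
#' midpoints uniform inside the union of `enriched_regions`, and
#' `n_background` with midpoints uniform over the whole genome
#' (chromosomes weighted by length). Used to exercise the enrichment
#' analysis with known ground truth.
#'
#' @param binning A [make_binning()] scheme (defines the genome).
#' @param enriched_regions Tibble of regions (`chrom`, `start`, `end`);
#'   required when `n_enriched > 0`.
#' @param n_enriched,n_background Interval counts (>= 0).
#' @param width Interval width in bp (default 200).
#' @param seed Integer seed.
#' @return A tibble `chrom`, `start`, `end` with attribute
#'   `track_name = "synthetic"`.
#' @export
simulate_features <- function(binning, enriched_regions = NULL,
                              n_enriched = 0, n_background = 0,
                              width = 200, seed = 1L) {
  if (!is_count(n_enriched) || !is_count(n_background)) {
    abort_param("n_enriched and n_background must be nonnegative integers")
  }
  if (n_enriched > 0 && (is.null(enriched_regions) || nrow(enriched_regions) == 0L)) {
    abort_param("n_enriched > 0 needs non-empty enriched_regions")
  }
  sizes <- binning_chrom_sizes(binning)
  half <- width / 2
  withr::with_seed(seed, {
    rows <- list()
    if (n_enriched > 0) {
      er <- tibble::as_tibble(enriched_regions)
      pick <- sample.int(nrow(er), n_enriched, replace = TRUE)
      mid <- floor(er$start[pick] + stats::runif(n_enriched) *
                     (er$end[pick] - er$start[pick]))
      rows$enriched <- tibble::tibble(chrom = er$chrom[pick], mid = mid)
    }
    if (n_background > 0) {
      ci <- sample.int(nrow(sizes), n_background, replace = TRUE,
                       prob = sizes$length)
      mid <- floor(stats::runif(n_background) * sizes$length[ci])
      rows$background <- tibble::tibble(chrom = sizes$chrom[ci], mid = mid)
    }
    track <- dplyr::bind_rows(rows)
    if (nrow(track) == 0L) {
      out <- tibble::tibble(chrom = character(), start = double(), end = double())
    } else {
      len <- sizes$length[match(track$chrom, sizes$chrom)]
      mid <- pmin(pmax(track$mid, half), len - half)
      out <- tibble::tibble(chrom = track$chrom,
                            start = mid - half, end = mid + half)
    }
    attr(out, "track_name") <- "synthetic"
    out
  })
}
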