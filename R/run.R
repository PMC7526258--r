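#' Run the calling workflow on a directory of cells and write artifacts
#'
#' Reads the chromosome sizes and every per-cell contacts file, builds the
#' binning scheme and per-cell networks, runs the binomial recurrence test
#' and writes four artifacts to `out_dir`: `regions.bed` (identified
#' regions), `links.txt` (significant edges, Circos link format),
#' `edges.tsv` (all tested edges) and `provenance.json` (parameters plus
#' N, M and the tested/significant counts). Calling is fully
#' deterministic: repeated runs produce byte-identical files.
#'
#' @param cells_dir Directory of per-cell contacts files.
#' @param chrom_sizes Path to a chrom.sizes file, or a tibble.
#' @param out_dir Output directory (created if needed).
#' @param bin_size,offset Binning parameters, see [make_binning()].
#' @param func,alpha,bonferroni_universe,search_space See [schic_call()].
#' @param policy Contact-validation policy, see [read_cell_contacts()].
#' @return The `schic_result`, invisibly.
#' @export
run_call <- function(cells_dir, chrom_sizes, out_dir,
                     bin_size = 500000, offset = 0,
                     func = c("max", "mean", "min"), alpha = 0.05,
                     bonferroni_universe = c("observed", "search-space"),
                     search_space = c("active", "all"),
                     policy = c("skip", "strict")) {
  func <- match.arg(func)
  bonferroni_universe <- match.arg(bonferroni_universe)
  search_space <- match.arg(search_space)
  policy <- match.arg(policy)
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  binning <- make_binning(chrom_sizes, bin_size, offset)
  contacts <- read_contacts_dir(cells_dir, chrom_sizes, policy = policy)
  n_skipped <- attr(contacts, "n_skipped", exact = TRUE) %||% 0L
  if (n_skipped > 0L) {
    message(sprintf("skipped %d unmappable contact(s)", n_skipped))
  }
  result <- schic_call(contacts, binning, func = func, alpha = alpha,
                       bonferroni_universe = bonferroni_universe,
                       search_space = search_space)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_regions_bed(result, file.path(out_dir, "regions.bed"))
  write_links(result, file.path(out_dir, "links.txt"))
  write_edges_tsv(result, file.path(out_dir, "edges.tsv"))
  prov <- c(result$meta, list(n_skipped_contacts = n_skipped,
                              cells_dir = cells_dir))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("N=%d cells, M=%s, %d edges tested, %d significant, %d regions",
                  result$meta$n_cells, format(result$meta$M),
                  result$meta$n_tested, result$meta$n_significant,
                  nrow(result$regions)))
  invisible(result)
}

#' Reload a `schic_result` from a [run_call()] output directory
#'
#' Rebuilds the result from `edges.tsv` and `provenance.json`; p-values are
#' recovered at the printed six-significant-digit precision.
#'
#' @param dir A directory written by [run_call()].
#' @return A `schic_result`.
#' @export
read_result <- function(dir) {
  edges_path <- file.path(dir, "edges.tsv")
  prov_path <- file.path(dir, "provenance.json")
  if (!file.exists(edges_path) || !file.exists(prov_path)) {
    abort_input("%s does not look like a run_call() output directory", dir)
  }
  edges <- read_edges_tsv(edges_path)
  meta <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
  sig <- dplyr::filter(edges, .data$significant)
  nodes <- sort(unique(c(sig$node_a, sig$node_b)))
  degree <- as.integer(table(factor(c(sig$node_a, sig$node_b), levels = nodes)))
  ra <- dplyr::distinct(tibble::tibble(chrom = c(sig$chromA, sig$chromB),
                                       start = c(sig$startA, sig$startB),
                                       end = c(sig$endA, sig$endB),
                                       node = c(sig$node_a, sig$node_b)))
  regions <- dplyr::arrange(ra, .data$node)
  regions$degree <- degree[match(regions$node, nodes)]
  structure(list(edges = edges, regions = regions, meta = as.list(meta)),
            class = "schic_result")
}

as_result <- function(x) {
  if (inherits(x, "schic_result")) x else read_result(x)
}

#' Compare two runs (exact bins or both-ends overlap)
#'
#' `mode = "exact"` partitions the two identified-region sets bin by bin
#' (requires the same binning scheme); `mode = "overlap"` applies the
#' both-ends overlap rule to the significant edges, the comparison used
#' across sliding-window offsets, and reports the common fraction in each
#' direction.
#'
#' @param a,b `schic_result` objects or [run_call()] output directories.
#' @param mode `"exact"` or `"overlap"`.
#' @param out Optional path for a TSV report.
#' @return A one-row tibble: counts for `"exact"`, common fractions
#'   (`frac_a_common`, `frac_b_common`) for `"overlap"`.
#' @export
run_compare <- function(a, b, mode = c("exact", "overlap"), out = NULL) {
  mode <- match.arg(mode)
  a <- as_result(a)
  b <- as_result(b)
  report <- if (mode == "exact") {
    compare_region_sets(a, b)$counts
  } else {
    tibble::tibble(frac_a_common = compare_edges_by_overlap(a, b),
                   frac_b_common = compare_edges_by_overlap(b, a))
  }
  if (!is.null(out)) readr::write_tsv(report, out, progress = FALSE)
  report
}

#' Feature-enrichment analysis of a run's top regions
#'
#' Ranks the identified regions by significant-edge degree, then computes a
#' randomization z-score per feature track (see [enrichment_z()]).
#'
#' @param result A `schic_result` or a [run_call()] output directory.
#' @param tracks A single feature tibble, a path, or a (optionally named)
#'   list of either.
#' @param binning The [make_binning()] scheme of the run (required when
#'   `result` is a directory, to define the bin universe).
#' @param degree_cutoff Minimum significant-edge degree for a top region.
#' @param n_draws,seed,background See [enrichment_z()].
#' @param retained_nodes For `background = "retained"`.
#' @param out Optional path for a TSV report.
#' @return A tibble with one row per track; empty (with a warning) when no
#'   region passes the cutoff.
#' @export
run_enrich <- function(result, tracks, binning, degree_cutoff = 1L,
                       n_draws = 50000, seed = 1L,
                       background = c("all", "retained"),
                       retained_nodes = NULL, out = NULL) {
  result <- as_result(result)
  top <- rank_top_regions(result, degree_cutoff)
  if (!is.data.frame(tracks) && !is.list(tracks)) tracks <- list(tracks)
  if (is.data.frame(tracks)) tracks <- list(tracks)
  tracks <- purrr::imap(tracks, function(tr, nm) {
    tr <- if (is.character(tr)) read_feature_track(tr) else tr
    if (is.character(nm) && nzchar(nm)) attr(tr, "track_name") <- nm
    tr
  })
  if (nrow(top) == 0L) {
    warning("no region passes the degree cutoff; empty enrichment report")
    report <- tibble::tibble(feature = character(), observed = double(),
                             bg_mean = double(), bg_sd = double(), z = double(),
                             z_defined = logical(), n_draws = integer(),
                             seed = integer())
  } else {
    report <- purrr::map_dfr(tracks, function(tr) {
      enrichment_z(top, tr, binning, n_draws = n_draws, seed = seed,
                   background = background, retained_nodes = retained_nodes)
    })
  }
  if (!is.null(out)) readr::write_tsv(report, out, progress = FALSE)
  report
}

#' Write a synthetic single-cell dataset to disk
#'
#' Thin wrapper over [simulate_cells()] that always writes the per-cell
#' files, chrom.sizes and ground-truth ledger.
#'
#' @param out_dir Output directory.
#' @inheritParams simulate_cells
#' @return The `schic_sim`, invisibly.
#' @export
run_simulate <- function(out_dir, chrom_sizes, bin_size = 500000, n_cells,
                         n_background, planted = NULL, intra_rate = 50,
                         seed = 1L) {
  sim <- simulate_cells(chrom_sizes, bin_size = bin_size, n_cells = n_cells,
                        n_background = n_background, planted = planted,
                        intra_rate = intra_rate, seed = seed, dir = out_dir)
  message(sprintf("wrote %d cell files to %s", n_cells, out_dir))
  invisible(sim)
}
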