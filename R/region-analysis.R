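#' Rank identified regions by significant-edge degree
#'
#' Selects the regions touched by at least `degree_cutoff` significant
#' edges, the "top" regions used downstream for enrichment analysis.
#'
#' @param result A `schic_result`.
#' @param degree_cutoff Minimum number of significant edges (default 1, i.e.
#'   every identified region).
#' @return A tibble of regions sorted by degree descending, ties in genomic
#'   order.
#' @export
rank_top_regions <- function(result, degree_cutoff = 1L) {
  stopifnot(inherits(result, "schic_result"))
  if (!is_count(degree_cutoff, min = 1L)) {
    abort_param("degree_cutoff must be a positive integer")
  }
  out <- dplyr::filter(result$regions, .data$degree >= degree_cutoff)
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$node)
}

result_regions <- function(x) {
  if (inherits(x, "schic_result")) x$regions else tibble::as_tibble(x)
}

#' Compare two identified-region sets bin by bin
#'
#' Exact partition of two region sets produced under the same binning
#' scheme: regions present in both, only in the first, only in the second.
#' Results from different schemes (e.g. different sliding-window offsets)
#' cannot be compared bin-by-bin; use [compare_edges_by_overlap()] instead.
#'
#' @param a,b `schic_result` objects or region tibbles with a `node` column,
#'   from the same [make_binning()] scheme.
#' @return A list with tibbles `common`, `unique_a`, `unique_b` and a
#'   one-row `counts` tibble.
#' @export
compare_region_sets <- function(a, b) {
  if (inherits(a, "schic_result") && inherits(b, "schic_result")) {
    same <- a$meta$bin_size == b$meta$bin_size && a$meta$offset == b$meta$offset
    if (!same) {
      abort_param(paste0(
        "results use different binning schemes (bin_size/offset); ",
        "exact region comparison is undefined - use compare_edges_by_overlap()"))
    }
  }
  ra <- result_regions(a)
  rb <- result_regions(b)
  common <- dplyr::semi_join(ra, rb, by = "node")
  unique_a <- dplyr::anti_join(ra, rb, by = "node")
  unique_b <- dplyr::anti_join(rb, ra, by = "node")
  list(common = common, unique_a = unique_a, unique_b = unique_b,
       counts = tibble::tibble(common = nrow(common),
                               unique_a = nrow(unique_a),
                               unique_b = nrow(unique_b)))
}

interval_overlaps <- function(chrom1, start1, end1, chrom2, start2, end2) {
  # na x nb logical matrix of half-open interval intersection
  outer(chrom1, chrom2, "==") &
    outer(start1, end2, "<") &
    outer(end1, start2, ">")
}

#' Fraction of significant edges shared across binning schemes
#'
#' The both-ends overlap rule used to compare runs under different
#' sliding-window offsets: a significant edge of `a` counts as common with
#' `b` if some significant edge of `b` overlaps it at both ends (interval
#' intersection, in either end pairing). Returns the fraction of `a`'s
#' significant edges that are common.
#'
#' @param a,b `schic_result` objects over the same genome; their binning
#'   schemes may differ.
#' @return A fraction in `[0, 1]`; `NA` when `a` has no significant edges
#'   (undefined).
#' @export
compare_edges_by_overlap <- function(a, b) {
  stopifnot(inherits(a, "schic_result"), inherits(b, "schic_result"))
  ea <- dplyr::filter(a$edges, .data$significant)
  eb <- dplyr::filter(b$edges, .data$significant)
  if (nrow(ea) == 0L) return(NA_real_)
  if (nrow(eb) == 0L) return(0)
  # end pairings: (A-A & B-B) or (A-B & B-A)
  m_aa <- interval_overlaps(ea$chromA, ea$startA, ea$endA, eb$chromA, eb$startA, eb$endA)
  m_bb <- interval_overlaps(ea$chromB, ea$startB, ea$endB, eb$chromB, eb$startB, eb$endB)
  m_ab <- interval_overlaps(ea$chromA, ea$startA, ea$endA, eb$chromB, eb$startB, eb$endB)
  m_ba <- interval_overlaps(ea$chromB, ea$startB, ea$endB, eb$chromA, eb$startA, eb$endA)
  common <- rowSums((m_aa & m_bb) | (m_ab & m_ba)) > 0
  mean(common)
}

#' Randomization-based genomic-feature enrichment z-score
#'
#' Counts the feature intervals whose midpoint falls inside the selected
#' top regions, then draws `n_draws` random region sets of the same size
#' (bins sampled uniformly without replacement within a draw) to build an
#' empirical background. The z-score standardizes the observed count
#' against the background mean and standard deviation; z >= 1.97
#' (two-sided p = 0.05) is the conventional enrichment call.
#'
#' @param top_regions Tibble of regions with a `node` column, e.g. from
#'   [rank_top_regions()]. Must be non-empty.
#' @param track Feature tibble with `chrom`, `start`, `end` (see
#'   [read_feature_track()] or [simulate_features()]).
#' @param binning The [make_binning()] scheme defining the bin universe.
#' @param n_draws Number of random draws (default 50,000).
#' @param seed Integer seed; recorded in the result for reproducibility.
#' @param background `"all"` samples from every bin of the scheme;
#'   `"retained"` restricts to `retained_nodes` (supply via
#'   `retained_nodes`).
#' @param retained_nodes Integer node vector, required for
#'   `background = "retained"`.
#' @param feature_name Label for the output row; defaults to the track's
#'   `track_name` attribute or `"track"`.
#' @return A one-row tibble: `feature`, `observed`, `bg_mean`, `bg_sd`,
#'   `z` (`NA` and `z_defined = FALSE` when the background sd is 0 or
#'   `n_draws = 1`), `n_draws`, `seed`.
#' @export
enrichment_z <- function(top_regions, track, binning, n_draws = 50000,
                         seed = 1L, background = c("all", "retained"),
                         retained_nodes = NULL, feature_name = NULL) {
  background <- match.arg(background)
  if (!is_count(n_draws, min = 1L)) abort_param("n_draws must be >= 1")
  top_regions <- result_regions(top_regions)
  if (nrow(top_regions) == 0L) abort_param("top_regions must be non-empty")
  universe <- if (background == "all") {
    binning$node
  } else {
    if (is.null(retained_nodes)) {
      abort_param("background = 'retained' needs retained_nodes")
    }
    as.integer(retained_nodes)
  }
  k <- nrow(top_regions)
  if (k > length(universe)) {
    abort_param("more top regions (%d) than bins in the background universe (%d)",
                k, length(universe))
  }
  feature_name <- feature_name %||% attr(track, "track_name", exact = TRUE) %||% "track"

  sizes <- binning_chrom_sizes(binning)
  known <- track$chrom %in% sizes$chrom
  if (!all(known)) {
    warning(sprintf("dropping %d feature(s) on chromosomes absent from the scheme",
                    sum(!known)))
    track <- track[known, ]
  }
  counts <- integer(nrow(binning))
  if (nrow(track) > 0L) {
    mid <- floor((track$start + track$end) / 2)
    len <- sizes$length[match(track$chrom, sizes$chrom)]
    mid <- pmin(mid, len - 1)
    nodes <- locus_to_bin(binning, track$chrom, mid)
    tab <- table(nodes)
    counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
  }
  observed <- sum(counts[top_regions$node + 1L])

  cnt_universe <- counts[universe + 1L]
  n_universe <- length(universe)
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_draws),
           function(j) sum(cnt_universe[sample.int(n_universe, k)]),
           numeric(1))
  })
  bg_mean <- mean(draws)
  bg_sd <- if (n_draws > 1L) stats::sd(draws) else 0
  z_defined <- bg_sd > 0
  tibble::tibble(
    feature = feature_name,
    observed = observed,
    bg_mean = bg_mean,
    bg_sd = bg_sd,
    z = if (z_defined) (observed - bg_mean) / bg_sd else NA_real_,
    z_defined = z_defined,
    n_draws = as.integer(n_draws),
    seed = as.integer(seed)
  )
}
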