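#' Pool per-cell edge probabilities
#'
#' Collapses the per-cell edge probabilities n_i/M into a single success
#' probability for the recurrence test. `max` is the conservative choice
#' recommended for large genomes or shallow sequencing (fewest regions
#' called); `min` is the liberal choice (most regions); `mean` sits between
#' them.
#'
#' @param probs Numeric vector of per-cell probabilities in `[0, 1]`.
#' @param func One of `"max"`, `"mean"`, `"min"`.
#' @return A single probability.
#' @export
#' @examples
#' pool_probs(c(0.1, 0.2, 0.3), "max")
pool_probs <- function(probs, func = c("max", "mean", "min")) {
  func <- match.arg(func)
  if (length(probs) == 0L) abort_input("probs must be non-empty")
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_param("probs must lie in [0, 1]")
  }
  switch(func, max = max(probs), mean = mean(probs), min = min(probs))
}

#' Binomial upper-tail recurrence p-value
#'
#' Probability that an edge with per-cell occurrence probability `p` is seen
#' in at least `t` of `n_cells` independent cells:
#' P(X >= t) with X ~ Binomial(n_cells, p). Computed through the survival
#' function (`pbinom(t - 1, ..., lower.tail = FALSE)`), which is numerically
#' stable for thousands of cells and probabilities down to 1e-9 and below,
#' unlike naive term-by-term summation.
#'
#' @param n_cells Number of cells N.
#' @param t Observed recurrence count(s), `0 <= t <= n_cells`. Vectorized.
#' @param p Per-cell edge probability in `[0, 1]`.
#' @return Upper-tail probability, same length as `t`.
#' @export
#' @examples
#' binomial_tail(10, 3, 0.1)   # 0.0701908...
#' binomial_tail(5, 5, 0.2)    # 0.2^5
binomial_tail <- function(n_cells, t, p) {
  if (!is_count(n_cells, min = 0L)) abort_param("n_cells must be a nonnegative integer")
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort_param("p must be a single probability in [0, 1]")
  }
  if (any(t < 0 | t > n_cells | t != trunc(t))) {
    abort_param("t must be an integer in [0, n_cells]")
  }
  stats::pbinom(t - 1, size = n_cells, prob = p, lower.tail = FALSE)
}

#' Bonferroni family-wise adjustment
#'
#' @param p_value Raw p-value(s) in `[0, 1]`.
#' @param m_tests Number of tests in the family (>= 1).
#' @return `min(1, p_value * m_tests)`, vectorized.
#' @export
bonferroni_adjust <- function(p_value, m_tests) {
  if (!is_count(m_tests, min = 1L)) abort_param("m_tests must be a positive integer")
  if (any(is.na(p_value)) || any(p_value < 0) || any(p_value > 1)) {
    abort_param("p_value must lie in [0, 1]")
  }
  pmin(1, p_value * m_tests)
}

#' Test all observed edges for statistically frequent recurrence
#'
#' For every cross-chromosome bin pair observed in at least one cell, the
#' recurrence count t is compared with a Binomial(N, p) null, where p pools
#' the per-cell edge densities n_i/M with `func`. P-values are
#' Bonferroni-adjusted and edges with adjusted p-value <= `alpha` are
#' significant; the identified regions are the bins incident to at least
#' one significant edge, annotated with their significant-edge degree.
#'
#' @param freq Edge recurrence table from [tabulate_edge_frequencies()].
#' @param networks The list of `schic_network` objects the table came from.
#' @param space A [build_search_space()] object.
#' @param binning The common [make_binning()] scheme.
#' @param func Pooling function, see [pool_probs()].
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @param bonferroni_universe `"observed"` divides by the number of edges
#'   actually tested (those seen in >= 1 cell); `"search-space"` divides by
#'   M, the stricter alternative.
#' @return An object of class `schic_result`: list with `edges` (all tested
#'   edges with coordinates, `t`, `p`, `p_value`, `p_adj`, `significant`,
#'   ordered by adjusted p-value then node pair), `regions` (identified
#'   regions with degree, in genomic order) and `meta` (N, M, m_tests,
#'   func, alpha, universe, bin_size, offset, pooled p).
#' @export
call_frequent_edges <- function(freq, networks, space, binning,
                                func = c("max", "mean", "min"),
                                alpha = 0.05,
                                bonferroni_universe = c("observed", "search-space")) {
  func <- match.arg(func)
  bonferroni_universe <- match.arg(bonferroni_universe)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    abort_param("alpha must be a probability")
  }
  n_cells <- attr(freq, "n_cells") %||% length(networks)
  if (n_cells != length(networks)) {
    abort_input("frequency table was built from %d cells but %d networks supplied",
                n_cells, length(networks))
  }
  n_i <- vapply(networks, `[[`, 0L, "n_edges")
  if (any(n_i > space$M)) {
    abort_input("a cell has more edges than the search space allows; inconsistent inputs")
  }
  p <- pool_probs(n_i / space$M, func)
  p <- min(max(p, 0), 1)

  m_tests <- if (bonferroni_universe == "observed") nrow(freq) else space$M
  edges <- tibble::as_tibble(freq)
  edges$p <- p
  edges$p_value <- binomial_tail(n_cells, edges$t, p)
  edges$p_adj <- bonferroni_adjust(edges$p_value, m_tests)
  edges$significant <- edges$p_adj <= alpha

  ra <- bin_to_region(binning, edges$node_a)
  rb <- bin_to_region(binning, edges$node_b)
  edges$chromA <- ra$chrom; edges$startA <- ra$start; edges$endA <- ra$end
  edges$chromB <- rb$chrom; edges$startB <- rb$start; edges$endB <- rb$end
  edges <- edges[, c("chromA", "startA", "endA", "chromB", "startB", "endB",
                     "node_a", "node_b", "t", "p", "p_value", "p_adj", "significant")]
  edges <- dplyr::arrange(edges, .data$p_adj, .data$node_a, .data$node_b)

  sig <- dplyr::filter(edges, .data$significant)
  degree <- sort(table(c(sig$node_a, sig$node_b)), decreasing = FALSE)
  nodes <- sort(as.integer(names(degree)))
  regions <- bin_to_region(binning, nodes)
  regions$degree <- as.integer(table(factor(c(sig$node_a, sig$node_b), levels = nodes)))
  regions <- dplyr::arrange(regions, .data$node)

  structure(
    list(edges = edges,
         regions = regions,
         meta = list(n_cells = n_cells, M = space$M, m_tests = m_tests,
                     n_tested = nrow(edges), n_significant = nrow(sig),
                     func = func, alpha = alpha,
                     bonferroni_universe = bonferroni_universe,
                     bin_size = attr(binning, "bin_size"),
                     offset = attr(binning, "offset"),
                     pooled_p = p)),
    class = "schic_result"
  )
}

#' Run the full recurrence-calling pipeline on a contact table
#'
#' Convenience wrapper: per-cell networks, node-filtered search space, edge
#' recurrence table, binomial test and region selection in one call.
#'
#' @param contacts Tibble of contacts with a `cell_id` column (e.g. from
#'   [read_contacts_dir()] or [simulate_cells()]).
#' @param binning A [make_binning()] scheme.
#' @param search_space `"active"` (node-filtered, the default) or `"all"`
#'   (unfiltered), see [build_search_space()].
#' @inheritParams call_frequent_edges
#' @return A `schic_result`, see [call_frequent_edges()].
#' @export
#' @examples
#' sizes <- tibble::tibble(chrom = c("chrA", "chrB"), length = c(5e6, 5e6))
#' sim <- simulate_cells(sizes, bin_size = 5e5, n_cells = 30, n_background = 5,
#'                       planted = tibble::tibble(node_a = 0L, node_b = 10L,
#'                                                prevalence = 1),
#'                       seed = 1)
#' res <- schic_call(sim$contacts, sim$binning)
#' res
schic_call <- function(contacts, binning,
                       func = c("max", "mean", "min"),
                       alpha = 0.05,
                       bonferroni_universe = c("observed", "search-space"),
                       search_space = c("active", "all")) {
  networks <- build_networks(contacts, binning)
  space <- build_search_space(networks, binning, nodes = match.arg(search_space))
  freq <- tabulate_edge_frequencies(networks)
  call_frequent_edges(freq, networks, space, binning,
                      func = func, alpha = alpha,
                      bonferroni_universe = bonferroni_universe)
}
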