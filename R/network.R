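#' Build one cell's unweighted interchromosomal contact network
#'
#' Maps both ends of every contact to bins and records, for the one cell,
#' (i) the set of distinct cross-chromosome bin pairs as unweighted edges
#' and (ii) the set of active nodes, i.e. every bin touched by any contact,
#' intra- or interchromosomal. Contact multiplicity is deliberately
#' discarded: single-cell trans contacts are sparse and noisy, so only
#' presence/absence of a bin pair is informative. Intrachromosomal contacts
#' (including both ends in the same bin) contribute to node activity only,
#' never to edges. The per-cell edge count `n_edges` is the cell's n_i used
#' by the recurrence test.
#'
#' @param contacts Tibble of contacts for a single cell, with columns
#'   `chromA`, `posA`, `chromB`, `posB` (see [read_cell_contacts()]).
#' @param binning A [make_binning()] scheme.
#' @param cell_id Cell identifier; taken from a `cell_id` column when
#'   present and unique.
#' @return An object of class `schic_network`: a list with `cell_id`,
#'   `edges` (tibble `node_a < node_b`), `active_nodes` (sorted integer
#'   vector) and `n_edges`.
#' @export
build_cell_network <- function(contacts, binning, cell_id = NULL) {
  if (is.null(cell_id)) {
    ids <- unique(contacts$cell_id)
    if (length(ids) > 1L) {
      abort_input("contacts span %d cells; use build_networks()", length(ids))
    }
    cell_id <- if (length(ids) == 1L) ids else "cell"
  }
  if (nrow(contacts) == 0L) {
    return(structure(
      list(cell_id = cell_id,
           edges = tibble::tibble(node_a = integer(), node_b = integer()),
           active_nodes = integer(), n_edges = 0L),
      class = "schic_network"
    ))
  }
  na <- locus_to_bin(binning, contacts$chromA, contacts$posA)
  nb <- locus_to_bin(binning, contacts$chromB, contacts$posB)
  inter <- contacts$chromA != contacts$chromB
  edges <- tibble::tibble(node_a = pmin(na[inter], nb[inter]),
                          node_b = pmax(na[inter], nb[inter]))
  edges <- dplyr::arrange(dplyr::distinct(edges), .data$node_a, .data$node_b)
  structure(
    list(cell_id = cell_id,
         edges = edges,
         active_nodes = sort(unique(c(na, nb))),
         n_edges = nrow(edges)),
    class = "schic_network"
  )
}

#' @export
print.schic_network <- function(x, ...) {
  cat(sprintf("<schic_network> cell '%s': %d trans edges, %d active nodes\n",
              x$cell_id, x$n_edges, length(x$active_nodes)))
  invisible(x)
}

#' Build per-cell networks for a multi-cell contact table
#'
#' @param contacts Tibble of contacts with a `cell_id` column.
#' @param binning A [make_binning()] scheme.
#' @return A named list of `schic_network` objects, one per cell, in sorted
#'   cell-id order (deterministic).
#' @export
build_networks <- function(contacts, binning) {
  if (!"cell_id" %in% names(contacts)) abort_input("contacts need a cell_id column")
  ids <- sort(unique(contacts$cell_id))
  if (length(ids) == 0L) abort_input("no cells in contact table")
  grouped <- split(contacts, factor(contacts$cell_id, levels = ids))
  purrr::imap(grouped, function(df, id) build_cell_network(df, binning, cell_id = id))
}

#' Derive the node-filtered edge search space
#'
#' Nodes with no contact at all (neither intra- nor interchromosomal) in any
#' cell are removed before testing; this shrinks the edge search space M and
#' thereby avoids overestimating per-cell edge probabilities n_i/M, reducing
#' false positives. M counts the unordered cross-chromosome pairs among
#' retained nodes: M = sum over chromosome pairs (c, d), c != d, of
#' count(c) * count(d).
#'
#' @param networks List of `schic_network` objects.
#' @param binning The common [make_binning()] scheme.
#' @param nodes `"active"` retains the union of per-cell active nodes (the
#'   default, node-filtered space); `"all"` uses every bin of the scheme
#'   (the unfiltered space, for sensitivity comparisons).
#' @return An object of class `schic_search_space`: list with
#'   `retained_nodes`, `chrom_counts` (named integer vector in chromosome
#'   order) and `M`.
#' @export
build_search_space <- function(networks, binning, nodes = c("active", "all")) {
  nodes <- match.arg(nodes)
  if (length(networks) == 0L) abort_input("need at least one cell network")
  retained <- if (nodes == "active") {
    sort(unique(unlist(purrr::map(networks, "active_nodes"))))
  } else {
    binning$node
  }
  chrom <- factor(binning$chrom[retained + 1L],
                  levels = binning_chrom_sizes(binning)$chrom)
  counts <- table(chrom)
  s <- sum(counts)
  m <- (s^2 - sum(as.numeric(counts)^2)) / 2
  if (m == 0) {
    abort_degenerate("degenerate search space: retained nodes span fewer than 2 chromosomes")
  }
  structure(
    list(retained_nodes = retained,
         chrom_counts = stats::setNames(as.integer(counts), names(counts)),
         M = m,
         nodes = nodes),
    class = "schic_search_space"
  )
}

#' @export
print.schic_search_space <- function(x, ...) {
  cat(sprintf("<schic_search_space> %d retained nodes on %d chromosomes, M = %s (%s)\n",
              length(x$retained_nodes), sum(x$chrom_counts > 0),
              format(x$M, big.mark = ","), x$nodes))
  invisible(x)
}

#' Tabulate edge recurrence across cells
#'
#' Counts, for every cross-chromosome bin pair present in at least one
#' cell's network, the number of cells t whose edge set contains it. Pairs
#' never observed are not stored.
#'
#' @param networks List of `schic_network` objects.
#' @return A tibble with columns `node_a`, `node_b`, `t`, sorted by node
#'   pair, with attribute `n_cells`.
#' @export
tabulate_edge_frequencies <- function(networks) {
  if (length(networks) == 0L) abort_input("need at least one cell network")
  all_edges <- dplyr::bind_rows(purrr::map(networks, "edges"))
  freq <- dplyr::count(all_edges, .data$node_a, .data$node_b, name = "t")
  freq <- dplyr::arrange(freq, .data$node_a, .data$node_b)
  freq$t <- as.integer(freq$t)
  attr(freq, "n_cells") <- length(networks)
  freq
}
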