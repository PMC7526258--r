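#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @export
print.schic_result <- function(x, ...) {
  m <- x$meta
  cat("<schic_result>\n")
  cat(sprintf("  cells N = %d, search space M = %s, func = %s, alpha = %g (%s universe)\n",
              m$n_cells, format(m$M, big.mark = ","), m$func, m$alpha,
              m$bonferroni_universe))
  cat(sprintf("  bin size = %s, offset = %s\n",
              format(m$bin_size, big.mark = ","), format(m$offset, big.mark = ",")))
  cat(sprintf("  %d edges tested, %d significant, %d identified regions\n",
              m$n_tested, m$n_significant, nrow(x$regions)))
  invisible(x)
}

#' Tidy the per-edge test table of a result
#'
#' @param x A `schic_result`.
#' @param ... Unused.
#' @return The tibble of tested edges (coordinates, `t`, `p`, `p_value`,
#'   `p_adj`, `significant`), ordered by adjusted p-value.
#' @method tidy schic_result
#' @export
tidy.schic_result <- function(x, ...) {
  x$edges
}

#' One-row summary of a recurrence-calling run
#'
#' @param x A `schic_result`.
#' @param ... Unused.
#' @return A one-row tibble with N, M, the pooling function, cutoff,
#'   Bonferroni universe and the tested/significant/region counts.
#' @method glance schic_result
#' @export
glance.schic_result <- function(x, ...) {
  m <- x$meta
  tibble::tibble(
    n_cells = m$n_cells, M = m$M, func = m$func, alpha = m$alpha,
    bonferroni_universe = m$bonferroni_universe, pooled_p = m$pooled_p,
    m_tests = m$m_tests, n_tested = m$n_tested,
    n_significant = m$n_significant, n_regions = nrow(x$regions)
  )
}

#' Plot a recurrence-calling result
#'
#' `type = "edges"` shows each tested edge's recurrence count against its
#' Bonferroni-adjusted p-value (log scale), with the significance cutoff;
#' `type = "regions"` shows the significant-edge degree of each identified
#' region along the genome.
#'
#' @param object A `schic_result`.
#' @param type `"edges"` or `"regions"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot schic_result
#' @export
autoplot.schic_result <- function(object, type = c("edges", "regions"), ...) {
  type <- match.arg(type)
  if (type == "edges") {
    ggplot2::ggplot(object$edges,
                    ggplot2::aes(x = .data$t, y = .data$p_adj,
                                 colour = .data$significant)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::scale_y_log10() +
      ggplot2::geom_hline(yintercept = object$meta$alpha, linetype = "dashed") +
      ggplot2::labs(x = "cells carrying edge (t)",
                    y = "Bonferroni-adjusted p-value",
                    colour = "significant",
                    title = sprintf("Edge recurrence (N = %d, func = %s)",
                                    object$meta$n_cells, object$meta$func))
  } else {
    ggplot2::ggplot(object$regions,
                    ggplot2::aes(x = .data$start / 1e6, y = .data$degree)) +
      ggplot2::geom_col(width = object$meta$bin_size / 1e6) +
      ggplot2::facet_wrap(~chrom, scales = "free_x") +
      ggplot2::labs(x = "position (Mb)", y = "significant-edge degree",
                    title = "Identified regions")
  }
}

#' Plot an enrichment report
#'
#' Bar chart of feature enrichment z-scores with the z >= 1.97 significance
#' threshold (two-sided 0.05) marked.
#'
#' @param data An enrichment tibble from [enrichment_z()] or [run_enrich()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$feature, y = .data$z)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1.97, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "enrichment z-score")
}
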