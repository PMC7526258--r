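planted3 <- tibble::tibble(node_a = c(1L, 1L, 4L), node_b = c(11L, 14L, 17L),
                           prevalence = c(1, 1, 0.9))

fixture_result <- function(seed = 41) {
  sim <- toy_sim(seed, n_cells = 40, n_background = 5, planted = planted3)
  list(sim = sim, res = schic_call(sim$contacts, sim$binning))
}

test_that("top regions rank by significant-edge degree with a cutoff", {
  fx <- fixture_result()
  res <- fx$res
  all_regions <- rank_top_regions(res, 1L)
  expect_equal(sort(all_regions$node), sort(res$regions$node))
  expect_true(!is.unsorted(rev(all_regions$degree)))
  maxdeg <- max(res$regions$degree)
  expect_equal(rank_top_regions(res, maxdeg)$degree, rep(maxdeg, sum(res$regions$degree == maxdeg)))
  expect_equal(nrow(rank_top_regions(res, maxdeg + 1L)), 0L)
  # node 1 touches two planted edges
  expect_gte(all_regions$degree[all_regions$node == 1], 2L)
})

test_that("exact region-set comparison partitions and conserves counts", {
  fx <- fixture_result()
  a <- fx$res
  b <- schic_call(fx$sim$contacts, fx$sim$binning, alpha = 1e-8)
  cmp <- compare_region_sets(a, b)
  expect_equal(cmp$counts$common + cmp$counts$unique_a, nrow(a$regions))
  expect_equal(cmp$counts$common + cmp$counts$unique_b, nrow(b$regions))
  union_n <- length(union(a$regions$node, b$regions$node))
  expect_equal(sum(unlist(cmp$counts)), union_n)

  self <- compare_region_sets(a, a)
  expect_equal(self$counts$unique_a, 0)
  expect_equal(self$counts$unique_b, 0)

  # differing schemes are refused
  b2 <- schic_call(fx$sim$contacts,
                   make_binning(two_chrom_sizes(), 5e5, offset = 1e5))
  expect_error(compare_region_sets(a, b2), class = "schictrans_parameter_error")
})

test_that("both-ends overlap comparison is reflexive and end-order invariant", {
  fx <- fixture_result()
  a <- fx$res
  expect_equal(compare_edges_by_overlap(a, a), 1.0)

  # swap the two ends of every edge in b: fraction unchanged
  b <- a
  e <- b$edges
  b$edges <- dplyr::mutate(e,
    chromA = e$chromB, startA = e$startB, endA = e$endB,
    chromB = e$chromA, startB = e$startA, endB = e$endA)
  expect_equal(compare_edges_by_overlap(a, b), 1.0)

  # empty b -> 0; empty a -> undefined
  empty <- schic_call(fx$sim$contacts, fx$sim$binning, alpha = 0)
  expect_equal(nrow(dplyr::filter(empty$edges, significant)), 0L)
  expect_equal(compare_edges_by_overlap(a, empty), 0)
  expect_true(is.na(compare_edges_by_overlap(empty, a)))
})

test_that("shifted-bin edges overlapping at both ends count as common", {
  # hand-built one-edge results on shifted schemes
  mk_result <- function(binning, na, nb) {
    ra <- bin_to_region(binning, na)
    rb <- bin_to_region(binning, nb)
    edges <- tibble::tibble(
      chromA = ra$chrom, startA = ra$start, endA = ra$end,
      chromB = rb$chrom, startB = rb$start, endB = rb$end,
      node_a = na, node_b = nb, t = 10L, p = 0.01, p_value = 1e-9,
      p_adj = 1e-8, significant = TRUE)
    structure(list(edges = edges,
                   regions = dplyr::bind_rows(ra, rb),
                   meta = list(bin_size = attr(binning, "bin_size"),
                               offset = attr(binning, "offset"))),
              class = "schic_result")
  }
  b0 <- tiny_binning(offset = 0)
  b1 <- tiny_binning(offset = 1e5)
  a <- mk_result(b0, 0L, 10L)          # chrA [0,500k) - chrB [0,500k)
  b <- mk_result(b1, 1L, 12L)          # chrA [100k,600k) - chrB [100k,600k)
  expect_equal(compare_edges_by_overlap(a, b), 1.0)
  # non-overlapping at one end -> not common
  b_far <- mk_result(b0, 5L, 10L)
  expect_equal(compare_edges_by_overlap(a, b_far), 0)
})

test_that("enrichment z is seeded, standardized, and flags degenerate draws", {
  bn <- tiny_binning()
  top <- bin_to_region(bn, c(0L, 5L, 12L))
  track <- simulate_features(bn, enriched_regions = top, n_enriched = 60,
                             n_background = 40, seed = 9)
  z1 <- enrichment_z(top, track, bn, n_draws = 2000, seed = 5)
  z2 <- enrichment_z(top, track, bn, n_draws = 2000, seed = 5)
  expect_identical(z1, z2)  # bit-for-bit reproducible
  expect_true(z1$z_defined)
  expect_gt(z1$z, 1.97)     # heavily enriched by construction

  # constant per-bin counts: every draw equals the observed count, sd = 0,
  # so the result is flagged undefined rather than inventing a z
  flat <- tibble::tibble(chrom = bn$chrom, start = floor((bn$start + bn$end) / 2),
                         end = floor((bn$start + bn$end) / 2) + 10)
  zf <- enrichment_z(bin_to_region(bn, 3L), flat, bn, n_draws = 500, seed = 1)
  expect_false(zf$z_defined)
  expect_equal(zf$observed, zf$bg_mean)

  # observed matching the background expectation -> z near 0: bins
  # alternate 0/2 features, top regions hold one of each (observed = 2,
  # expected draw sum = 2)
  two <- bn[seq(1, nrow(bn), by = 2), ]
  alt <- tibble::tibble(chrom = rep(two$chrom, 2),
                        start = rep(floor((two$start + two$end) / 2), 2),
                        end = rep(floor((two$start + two$end) / 2), 2) + 10)
  za <- enrichment_z(bin_to_region(bn, c(0L, 1L)), alt, bn,
                     n_draws = 4000, seed = 2)
  expect_lt(abs(za$z), 0.1)

  # n_draws = 1 -> sd undefined
  z3 <- enrichment_z(top, track, bn, n_draws = 1, seed = 1)
  expect_false(z3$z_defined)
  expect_true(is.na(z3$z))

  expect_error(enrichment_z(bin_to_region(bn, 0:19), track, bn,
                            n_draws = 10, background = "retained",
                            retained_nodes = 0:3),
               class = "schictrans_parameter_error")
})
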