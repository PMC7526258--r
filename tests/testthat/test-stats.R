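test_that("pooling functions return max, mean, min and stay ordered", {
  x <- c(0.1, 0.2, 0.3)
  expect_equal(pool_probs(x, "max"), 0.3)
  expect_equal(pool_probs(x, "mean"), 0.2)
  expect_equal(pool_probs(x, "min"), 0.1)
  for (func in c("max", "mean", "min")) {
    expect_equal(pool_probs(rep(0.42, 5), func), 0.42)
  }
  for (seed in 1:5) {
    probs <- withr::with_seed(seed, stats::runif(20))
    expect_lte(pool_probs(probs, "min"), pool_probs(probs, "mean"))
    expect_lte(pool_probs(probs, "mean"), pool_probs(probs, "max"))
  }
  expect_error(pool_probs(numeric(), "max"), class = "schictrans_input_error")
  expect_error(pool_probs(c(0.1, 1.2), "max"), class = "schictrans_parameter_error")
})

test_that("binomial tail matches closed forms and high-precision references", {
  # closed forms
  expect_identical(binomial_tail(10, 0, 0.37), 1)
  expect_equal(binomial_tail(5, 5, 0.2), 0.2^5)
  # references computed with 50-digit arithmetic
  expect_equal(binomial_tail(10, 3, 0.1), 0.0701908264, tolerance = 1e-9)
  expect_equal(binomial_tail(25, 7, 0.05), 1.6875315008158508e-4, tolerance = 1e-12)
  expect_equal(binomial_tail(20, 2, 0.001), 1.8773447317733576e-4, tolerance = 1e-12)
  expect_equal(binomial_tail(15, 9, 0.3), 0.015242525769771, tolerance = 1e-12)
  # stable far into the tail where naive summation underflows to noise
  expect_equal(binomial_tail(100, 60, 0.005), 9.78904823793948e-111,
               tolerance = 1e-6)
  expect_gt(binomial_tail(10000, 50, 1e-9), 0)

  expect_error(binomial_tail(5, 6, 0.1), class = "schictrans_parameter_error")
  expect_error(binomial_tail(5, 2, 1.1), class = "schictrans_parameter_error")
})

test_that("binomial tail is monotone in t and in p", {
  for (n in c(5, 50, 500)) {
    p <- 0.03
    tails <- binomial_tail(n, 0:n, p)
    expect_true(all(diff(tails) <= 0))
    ps <- c(1e-6, 1e-4, 0.01, 0.1, 0.5, 0.9)
    at_t <- vapply(ps, function(pp) binomial_tail(n, min(3, n), pp), 0)
    expect_true(all(diff(at_t) >= 0))
  }
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  expect_equal(bonferroni_adjust(0.001, 100), 0.1)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_equal(bonferroni_adjust(0.123, 1), 0.123)
  expect_error(bonferroni_adjust(0.1, 0), class = "schictrans_parameter_error")
  expect_error(bonferroni_adjust(1.5, 2), class = "schictrans_parameter_error")
})

test_that("a strongly recurrent planted edge is called significant", {
  planted <- tibble::tibble(node_a = 2L, node_b = 13L, prevalence = 0.9)
  sim <- toy_sim(23, n_cells = 50, n_background = 5, planted = planted)
  res <- schic_call(sim$contacts, sim$binning, func = "max")
  sig <- dplyr::filter(res$edges, significant)
  expect_true(any(sig$node_a == 2 & sig$node_b == 13))
  # the planted edge has the smallest adjusted p-value
  expect_equal(res$edges$node_a[1], 2L)
  expect_equal(res$edges$node_b[1], 13L)
  # identified regions are exactly the endpoints of significant edges
  expect_setequal(res$regions$node, unique(c(sig$node_a, sig$node_b)))
  expect_true(all(res$edges$p_adj >= res$edges$p_value))
})

test_that("the search-space Bonferroni universe is stricter than observed", {
  planted <- tibble::tibble(node_a = 0L, node_b = 10L, prevalence = 0.8)
  sim <- toy_sim(29, n_cells = 40, n_background = 5, planted = planted)
  r_obs <- schic_call(sim$contacts, sim$binning, bonferroni_universe = "observed")
  r_ss <- schic_call(sim$contacts, sim$binning, bonferroni_universe = "search-space")
  expect_equal(r_obs$meta$m_tests, r_obs$meta$n_tested)
  expect_equal(r_ss$meta$m_tests, r_ss$meta$M)
  expect_true(all(r_ss$edges$p_adj >= r_obs$edges$p_adj - 1e-15))
  sig_ss <- dplyr::filter(r_ss$edges, significant)
  sig_obs <- dplyr::filter(r_obs$edges, significant)
  expect_true(all(paste(sig_ss$node_a, sig_ss$node_b) %in%
                    paste(sig_obs$node_a, sig_obs$node_b)))
})

test_that("node filtering shrinks M and lowers p-values vs the unfiltered space", {
  sim <- toy_sim(31, n_cells = 20, n_background = 3, intra_rate = 3)
  filtered <- schic_call(sim$contacts, sim$binning, search_space = "active")
  unfiltered <- schic_call(sim$contacts, sim$binning, search_space = "all")
  expect_lte(filtered$meta$M, unfiltered$meta$M)
  key <- function(r) paste(r$edges$node_a, r$edges$node_b)
  ord <- match(key(filtered), key(unfiltered))
  # filtering raises p (n_i over a smaller M) and therefore raises p-values
  expect_true(all(filtered$edges$p_value >= unfiltered$edges$p_value[ord] - 1e-15))
})
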