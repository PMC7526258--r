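sizes <- two_chrom_sizes(2e6, 2e6)

test_that("contact files parse, keep intrachromosomal rows, and honour policy", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a comment",
               "chrA 100 chrB 200",
               "chrA\t100\tchrA\t900\textra column",
               "chrUn 5 chrB 200"), f)

  expect_error(read_cell_contacts(f, sizes, policy = "strict"),
               class = "schictrans_input_error")

  cc <- read_cell_contacts(f, sizes, policy = "skip")
  expect_equal(nrow(cc), 2L)
  expect_equal(attr(cc, "n_skipped"), 1L)
  expect_equal(cc$chromB, c("chrB", "chrA"))
  expect_equal(cc$cell_id, rep(sub("\\.txt$", "", basename(f)), 2))

  writeLines("chrA 100 chrB", f)
  expect_error(read_cell_contacts(f, sizes), class = "schictrans_parse_error")
  writeLines("chrA 1.5 chrB 10", f)
  expect_error(read_cell_contacts(f, sizes), class = "schictrans_parse_error")
})

test_that("a directory of cell files reads into one table with file-stem ids", {
  d <- withr::local_tempdir()
  writeLines("chrA 100 chrB 200", file.path(d, "cellX.txt"))
  writeLines(c("chrA 0 chrB 0", "chrA 999 chrB 999"), file.path(d, "cellY.txt"))
  cc <- read_contacts_dir(d, sizes)
  expect_equal(sort(unique(cc$cell_id)), c("cellX", "cellY"))
  expect_equal(nrow(cc), 3L)
  expect_error(read_contacts_dir(withr::local_tempdir(), sizes),
               class = "schictrans_input_error")
})

test_that("feature tracks parse as BED3+ and reject inverted intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chrA\t10\t20\tpeak1\t960",
               "chrB\t0\t5"), f)
  tr <- read_feature_track(f)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$start, c(10, 0))
  expect_equal(attr(tr, "track_name"), sub("\\.bed$", "", basename(f)))

  writeLines("chrA\t20\t10", f)
  expect_error(read_feature_track(f), class = "schictrans_parse_error")
})

result_fixture <- function(seed = 7) {
  sim <- toy_sim(seed, n_cells = 40, n_background = 6,
                 planted = tibble::tibble(node_a = c(1L, 2L),
                                          node_b = c(12L, 15L),
                                          prevalence = c(1, 0.9)))
  schic_call(sim$contacts, sim$binning)
}

test_that("BED, link and TSV outputs round-trip the result", {
  res <- result_fixture()
  expect_gt(res$meta$n_significant, 0)
  d <- withr::local_tempdir()

  write_regions_bed(res, file.path(d, "regions.bed"))
  back <- read_regions_bed(file.path(d, "regions.bed"))
  expect_equal(back$node, res$regions$node)
  expect_equal(back$degree, res$regions$degree)
  expect_equal(back$start, res$regions$start)

  write_links(res, file.path(d, "links.txt"))
  links <- read_links(file.path(d, "links.txt"))
  sig <- dplyr::filter(res$edges, significant)
  expect_equal(nrow(links), nrow(sig))
  expect_equal(links$t, sig$t)
  expect_equal(links$startA, sig$startA)
  # printed precision: 6 significant digits
  expect_equal(links$p_adj, sig$p_adj, tolerance = 1e-5)

  write_edges_tsv(res, file.path(d, "edges.tsv"))
  edges <- read_edges_tsv(file.path(d, "edges.tsv"))
  expect_equal(nrow(edges), nrow(res$edges))
  expect_equal(edges$node_a, res$edges$node_a)
  expect_equal(edges$t, res$edges$t)
  expect_equal(edges$significant, res$edges$significant)
  expect_equal(edges$p_value, res$edges$p_value, tolerance = 1e-5)
})

test_that("empty results write a header-only BED and an empty link file", {
  sim <- toy_sim(3, n_cells = 10, n_background = 2)
  res <- schic_call(sim$contacts, sim$binning, alpha = 1e-12)
  expect_equal(res$meta$n_significant, 0L)
  d <- withr::local_tempdir()
  write_regions_bed(res, file.path(d, "r.bed"))
  lines <- readLines(file.path(d, "r.bed"))
  expect_equal(length(lines), 1L)
  expect_true(startsWith(lines, "#"))
  write_links(res, file.path(d, "l.txt"))
  expect_equal(length(readLines(file.path(d, "l.txt"))), 0L)
})

test_that("link files are ordered by adjusted p-value with stable ties", {
  res <- result_fixture()
  d <- withr::local_tempdir()
  write_links(res, file.path(d, "links.txt"))
  links <- read_links(file.path(d, "links.txt"))
  expect_true(!is.unsorted(links$p_adj))
  # repeated writes are byte-identical
  write_links(res, file.path(d, "links2.txt"))
  expect_identical(readLines(file.path(d, "links.txt")),
                   readLines(file.path(d, "links2.txt")))
})
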