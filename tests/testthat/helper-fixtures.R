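# shared fixtures: tiny genomes, contact tables and an independent
# binomial-tail oracle (naive term-by-term summation of the upper tail)

two_chrom_sizes <- function(lenA = 5e6, lenB = 5e6) {
  tibble::tibble(chrom = c("chrA", "chrB"), length = c(lenA, lenB))
}

three_chrom_sizes <- function() {
  tibble::tibble(chrom = c("chrA", "chrB", "chrC"), length = c(3e6, 2e6, 1.5e6))
}

tiny_binning <- function(bin_size = 5e5, offset = 0, sizes = two_chrom_sizes()) {
  make_binning(sizes, bin_size = bin_size, offset = offset)
}

# one-row-per-contact tibble builder
contacts_tbl <- function(chromA, posA, chromB, posB, cell_id = "c1") {
  tibble::tibble(chromA = chromA, posA = posA, chromB = chromB, posB = posB,
                 cell_id = cell_id)
}

# independent oracle for the binomial upper tail: direct summation of
# choose(N, i) p^i (1-p)^(N-i) over i = t..N (exact binomial coefficients
# for N <= 25, so absolute error is far below 1e-12)
binom_tail_oracle <- function(n, t, p) {
  if (t == 0) return(1)
  i <- t:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# simulation presets used across tests: a ~100-pair toy genome
toy_sim <- function(seed, n_cells = 30, n_background = 5, planted = NULL,
                    intra_rate = 20) {
  simulate_cells(two_chrom_sizes(), bin_size = 5e5, n_cells = n_cells,
                 n_background = n_background, planted = planted,
                 intra_rate = intra_rate, seed = seed)
}
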