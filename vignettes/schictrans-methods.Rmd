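---
title: "Identifying recurrent interchromosomal interactions in single-cell Hi-C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying recurrent interchromosomal interactions in single-cell Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schictrans)
```

## The model

Single-cell Hi-C yields one sparse contact list per cell. `schictrans`
asks, for every pair of genomic bins on *different* chromosomes, whether
the pair is connected in more cells than chance would allow.

Each cell $i$ is reduced to an unweighted network: bins are nodes, and a
trans contact whose two ends fall in bins $u$ and $v$ creates the edge
$\{u, v\}$. Multiplicity is discarded — at single-cell sequencing depth
the presence of a trans contact is informative, its copy number mostly
noise. The cell's edge count is $n_i$, and after removing bins with no
contact of any kind in any cell, the edge search space holds $M$
cross-chromosome bin pairs. The occurrence of a given edge in cell $i$ is
modelled as a Bernoulli trial with success probability $n_i/M$, i.e. the
cell's trans edges are exchangeable across the search space. Pooling the
per-cell probabilities with $p = \mathrm{func}(n_1/M, \dots, n_N/M)$,
$\mathrm{func} \in \{\max, \mathrm{mean}, \min\}$, the recurrence count
$t$ of an edge over $N$ cells is referred to a Binomial$(N, p)$ null:

$$
p\text{-value} = \sum_{i=t}^{N} \binom{N}{i} p^i (1-p)^{N-i}.
$$

P-values are Bonferroni-adjusted and thresholded at $\alpha$. Identified
regions are the bins incident to at least one significant edge, ranked by
their significant-edge degree.

### Assumptions worth stating

* Independence across cells (cells are separate nuclei, so this is mild).
* Uniformity of an edge's null probability over the search space. Real
  trans-contact propensity varies along the genome (e.g. with chromosome
  territories and nucleolar association); the pooled $p$ absorbs depth
  differences between cells, not positional biases. The node filter
  removes fully silent bins (unmappable or unassayed regions), which is
  the coarsest form of positional correction.
* `max` pooling upper-bounds every cell's edge probability, making the
  test conservative; `min` lower-bounds it and is anti-conservative
  whenever depth varies. This is why the significant sets nest,
  $S(\max) \subseteq S(\mathrm{mean}) \subseteq S(\min)$, a property the
  test suite asserts on simulated data.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 500,000 bp | bin width; 500 kb accumulates enough trans signal at typical scHi-C depth, 1 Mb is the coarser alternative |
| `offset` | 0 bp | sliding-window shift, $0 \le s <$ `bin_size`; diversifies region boundaries |
| `func` | `max` | pooling of $n_i/M$; `max` conservative, `min` liberal |
| `alpha` | 0.05 | cutoff on the Bonferroni-adjusted p-value |
| `bonferroni_universe` | `observed` | divisor of the correction: edges tested (observed in ≥ 1 cell) or the full search space $M$ |
| `search_space` | `active` | node filter: union of active bins, or all bins |
| `degree_cutoff` | 1 | minimum significant-edge degree for "top" regions |
| `n_draws` | 50,000 | randomization draws in the enrichment analysis |

The Bonferroni divisor deserves a note: only observed edges ($t \ge 1$)
are actually tested, so the default divides by their count. Dividing by
$M$ instead treats every never-observed pair as an implicit test and is
strictly more conservative; both are exposed because either reading of
"correcting over the edge family" is defensible, and results are labelled
with the universe used.

## Coordinate and indexing conventions

Coordinates are 0-based half-open `[start, end)`, matching BED output.
Bins tile each chromosome exactly: the last bin may be partial, and under
a sliding-window offset $s$ the leading `[0, s)` bin is kept as well, so
every contact stays mappable at any offset and cross-offset comparisons
are well defined. Partial bins are tested like full bins, with no length
correction to their edge probabilities. Global node indices run in
chromosome order (input file order — no sorting is imposed) then bin
order, which makes outputs deterministic for a given chrom.sizes file.

## Sliding-window comparison

Runs at different offsets produce incompatible bin grids, so region
identity is compared by the both-ends rule: a significant edge of run A
is *common* with run B if some significant edge of B overlaps it at both
ends (interval intersection, in either end pairing). The reported number
is the fraction of A's significant edges that are common. The rule is
reflexive (self-comparison gives 1) and invariant to swapping edge ends,
both asserted in tests.

## Enrichment analysis

Top regions are tested for co-location with feature tracks (CTCF,
enhancers, histone marks, ...) by randomization: the observed count of
features — counted by interval midpoint, which avoids double counting a
feature straddling two bins — inside the top regions is standardized
against `n_draws` random sets of the same number of bins, drawn uniformly
without replacement. Enrichment is declared at $z \ge 1.97$ (two-sided
$p = 0.05$). The background universe defaults to all bins of the scheme;
`background = "retained"` restricts draws to active bins, which is
stricter when large genome stretches are silent. Draws come from a single
seeded generator and the seed is recorded in the result; with a constant
background (sd 0, or `n_draws = 1`) the z-score is flagged undefined
rather than fabricated.

## The simulator

`simulate_cells()` generates data *under the exact null of the test*:
each cell draws `n_background` distinct cross-chromosome bin pairs
uniformly from the full pair space, one contact per pair with positions
uniform inside the bin. Planted edges are added independently per cell
with a stated prevalence, and same-bin cis contacts arrive at
Poisson(`intra_rate`) per cell to control node activity — the default
rate of 50/cell makes every bin of a few-hundred-bin genome active with
overwhelming probability (a coupon-collector argument: 200 bins and
5,000 uniform draws leave a bin silent with probability about
$200e^{-25} \approx 3\times10^{-9}$), pinning $M$ at its nominal value.
The ground-truth ledger records each planted edge's carried and realized
recurrence so recovery can be scored exactly.

What the simulator does *not* model: cis distance decay, chromosome
territories, cell-cycle copy-number structure, read-level noise, or
position-dependent trans propensity. Passing tests therefore demonstrate
the statistical machinery — calibration, power, monotonicity, pipeline
determinism — not robustness to the positional biases of real scHi-C,
where the uniformity assumption is only an approximation.

## Numerical choices

* The binomial tail is computed through the survival function
  (`pbinom(t - 1, N, p, lower.tail = FALSE)`), stable for $N$ in the
  thousands and $p$ down to $10^{-9}$; naive summation is used only as an
  independent oracle in tests (exact for $N \le 25$), where the two agree
  to $10^{-12}$ absolutely.
* The pooled $p$ is clamped to $[0,1]$ defensively; $n_i \le M$ is also
  checked outright.
* Output ordering is total and deterministic: edges by adjusted p-value
  then node pair; regions by genomic order. P-values are printed in
  scientific notation with six significant digits, so text outputs are
  byte-stable and round-trip at printed precision.
* Degenerate inputs fail loudly with classed errors: an offset at or
  above the bin size, a search space confined to one chromosome, a
  planted edge within one chromosome, more top regions than bins.

## Validation experiment sizes

The test suite exercises the method at sizes chosen to make the
statistical properties visible yet quick to simulate: null calibration
uses 200 replicates of 50 cells with 25 background edges over a
~5,000-pair space (the family-wise error rate under `max`/0.05 lands
well below 0.05); power uses 100 replicates of 100 cells with a
prevalence-0.6 edge over a 10,000-pair space (recovery ≥ 99%);
enrichment calibration uses 1,000 uniform tracks at 5,000 draws (mean z
within ±0.1 of 0) and a 10×-density track for power. The acceptance
script reruns the same designs from a user seed.

## Known limitations

* No FDR alternative: the core follows the Bonferroni-only design; users
  wanting FDR can adjust the raw p-values in the edge report themselves.
* No intrachromosomal testing — cis contacts only gate node activity.
* No modelling of positional trans-contact biases (see simulator notes);
  regions in pericentromeric or rDNA-adjacent bins deserve scepticism.
* Hub identification is left to inspection of the ranked regions and
  Circos rendering of the link file; no hub-calling heuristic is shipped.
* The comparison and enrichment analyses assume both runs share a genome
  (chrom.sizes); no liftover is provided.
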