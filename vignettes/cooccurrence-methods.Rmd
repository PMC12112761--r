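---
title: "Methods: exact co-occurrence tests and network null models for biocrust communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact co-occurrence tests and network null models for biocrust communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crustnet)
```

## The data model

Everything in crustnet starts from a binary incidence matrix: rows are
field samples, columns are taxa, and a cell is 1 when the taxon was
recorded in that sample. Multiple specimens of one taxon in one sample
collapse to a single 1 — the analysis is strictly presence/absence, and
abundance-valued matrices are out of scope. A taxon's *incidence* is its
column sum. Sample and taxon order are preserved as given, and results are
always reported by label, never by position.

Taxa with zero incidence are retained in the matrix (so I/O is faithful to
the input file) but cannot be tested meaningfully: every pair involving
them has expected overlap 0 and falls below the exclusion filter. A
warning flags them.

## The pairwise co-occurrence model

For taxa with incidences $N_1$ and $N_2$ among $N$ samples, the null model
places each taxon's presence set as an independent uniform random subset of
the samples. Conditioning on one taxon's placement, the number of shared
samples $j$ is hypergeometric:

$$P(j) = \frac{\binom{N_1}{j}\binom{N - N_1}{N_2 - j}}{\binom{N}{N_2}},
\qquad \max(0, N_1 + N_2 - N) \le j \le \min(N_1, N_2),$$

with mean $N_1 N_2 / N$. The test is exact: no asymptotic approximation is
involved, which matters at these sample sizes (38 samples, incidences from
1 to 34).

Three conventions define the test precisely:

* **Inclusive tails.** $p_{lt} = \sum_{j \le j_{obs}} P(j)$ and
  $p_{gt} = \sum_{j \ge j_{obs}} P(j)$ both include the observed count, so
  $p_{lt} + p_{gt} = 1 + P(j_{obs})$ exactly. This is the "observed or
  more extreme" convention; it is why one tail of a significant pair is
  typically printed as ~1.000.
* **Exclusion filter before testing.** A pair is excluded if and only if
  its expected overlap $N_1 N_2 / N$ is *strictly* below `min_expected`
  (default 1). Excluded pairs carry no classification. With rare taxa this
  filter removes most pairs: in study-shaped matrices roughly 165 of the
  253 pairs fall below it.
* **No multiple-testing correction.** The raw tails are reported and
  thresholded at `alpha` (default 0.05): negative if $p_{lt} < \alpha$,
  positive if $p_{gt} < \alpha$, random otherwise. For $\alpha \le 0.5$
  the two conditions are mutually exclusive, because the inclusive tails
  sum to at least 1.

Numerically, the pmf is evaluated as
$\exp(\log\binom{N_1}{j} + \log\binom{N-N_1}{N_2-j} - \log\binom{N}{N_2})$
via `lchoose`, which is overflow-safe for site counts far beyond anything a
field survey produces. Tail sums are clamped at 1: summing ~30 pmf terms
can overshoot 1 by one part in $10^{16}$, and a probability of
$1 + 10^{-16}$ would be a contract violation even though it is numerically
harmless. The tail identity above still holds to $10^{-12}$ and is tested
at that tolerance. The test suite cross-checks the pmf against
`stats::dhyper` and, for all $N \le 10$, against exhaustive enumeration of
every placement of the second taxon.

## The co-occurrence network

Nodes are all taxa (isolated nodes permitted); an undirected, unweighted
edge joins two taxa when they share at least `min_shared_samples` samples
(default 1). The number of shared samples is kept as an edge attribute in
exports but does not enter the metrics.

The edge rule deserves a note, because a co-occurrence network could also
be built from only the significantly positive pairs. The shared-sample
rule at threshold 1 is the one consistent with the descriptive statistics
this package targets: a published 23-taxon degree table whose degrees sum
to 248 implies 124 edges and density $124/\binom{23}{2} = 0.490$, far more
edges than the handful of significant pairs, ruling out a
significance-filtered network. The threshold is still exposed for users
who want sparser graphs.

Metrics are computed with igraph, the same library the field's analyses
cite: degree, unnormalized undirected betweenness with fractional credit
across tied geodesics, edge density $|E|/\binom{n}{2}$, connected
components (with a count of "large modules", components of more than two
taxa), and Newman–Girvan modularity

$$Q = \sum_c \left[\frac{e_c}{m} - \left(\frac{k_c}{2m}\right)^2\right].$$

The suite verifies betweenness against a brute-force geodesic-counting
oracle on all random graphs up to 8 nodes it draws, and modularity against
a direct evaluation of the formula. Two exact anchor cases: the partition
assigning every node to one community has $Q = 0$ on any graph with an
edge, and on two disjoint edges the component partition gives $Q = 0.5$
and the crossed partition $-0.5$.

### The modularity permutation test

Community labels (by default the connected-component partition, which is
what "clusters" denote in this workflow) are shuffled uniformly
`n_permutations` times (default 1000) and $Q$ is recomputed each time. The
p-value is the plain proportion of shuffles with
$Q_{perm} \ge Q_{obs}$ — no $+1$ small-sample correction, matching the
definition the analysis follows. Consequences worth knowing:

* With all labels equal (one community, e.g. a connected network), every
  shuffle reproduces the observed partition and $p = 1$ identically.
* On two disjoint edges with perfect two-community labels, 2 of the 6
  distinct label arrangements reproduce the partition, so $p \to 1/3$;
  the suite checks this at 2000 shuffles within ±0.05.

The comparison uses $Q_{perm} \ge Q_{obs} - 10^{-10}$: when a shuffle
reproduces the observed partition under permuted community ids, floating
point summation order can perturb $Q$ in the last ulp, and the tolerance
keeps such exact ties counted as ties. A single seeded generator drives
all shuffles; the seed is recorded in the result, and the caller's RNG
state is left untouched.

## The synthetic-data generator

The generator emulates the statistical structure the pair test assumes,
nothing more:

* **Fixed column totals.** Each taxon's presence set is a uniform random
  subset of samples of exactly its requested incidence — exact, not in
  expectation — independently across taxa. Row totals (sample richness)
  are left free. This matches the hypergeometric conditioning of the test;
  a row-and-column-fixed swap null is deliberately out of scope.
* **Planted associations.** After the null draw, a planted pair re-draws
  only the second taxon's column, uniformly among placements with exactly
  the target overlap with the first taxon; both column sums are preserved
  and all other columns untouched. A re-drawn taxon may not take part in
  any other planted pair (that would silently distort the earlier
  planting), but one anchor taxon may support several plantings.
* **The study fixture.** `study_fixture()` produces a 38-sample × 23-taxon
  matrix with the published per-taxon incidences of a granite-gneiss
  biocrust survey (6 phyla; *Scytonema* in 34 samples down to five
  singleton taxa), plants the *Riccia weinionis* × *Nostoc* pair at its
  maximal overlap (8) and *Riccia weinionis* × *Bryum atenense* disjoint.
  The published survey counts specimens as 168 while its per-taxon
  frequencies sum to 166; the fixture follows the per-taxon values, and
  the discrepancy is simply noted.

What the generator does **not** emulate: spatial autocorrelation,
microhabitat structure, environmental covariates driving joint occupancy,
or abundance. Passing tests on synthetic matrices therefore certify the
statistical machinery (exactness, calibration, power against planted
signals, determinism), not ecological claims about any real community.
Because the raw study matrix is unpublished, printed per-pair p-values and
per-node betweenness values of the original survey are not reproducible
from marginals alone — fixture runs reproduce the direction and
significance of the planted associations and the analytically forced
graph-level results (single component, $Q = 0$, permutation $p = 1$,
density near 0.5), and that is all they can certify. For the same reason
the published "82 of 253 pairs analyzed" is not recoverable: applying the
expected-overlap filter to the published incidences yields a somewhat
larger analyzed count (typically 85–90 depending on the draw).

## Calibration and power, as tested

The acceptance suite runs 500 null matrices with the study's marginals and
checks that the fraction of analyzed pairs called non-random at
$\alpha = 0.05$ stays below $0.05 + 3\,\mathrm{SE}$. The discrete exact
test is conservative — the achievable size at these incidences is well
below the nominal level — so this bound is comfortable. Power is checked
the opposite way: a planted complete-overlap pair (incidences 8 and 11 in
38 samples, upper tail $3.4 \times 10^{-6}$) must classify positive in
every one of 50 replicates. These replicate counts keep the default test
run around ten seconds; they are ample for bounds this far from their
thresholds.

## Pipeline and reproducibility

`run_pipeline()` composes the stages — matrix (file or generator spec) →
pair table → network → metrics → permutation test — and writes
`pairs.csv`, `edges.csv`, `network.gml`, `metrics.csv` and `summary.json`.
Defaults mirror the analysis conventions above: $\alpha = 0.05$, expected
filter 1, edge threshold 1, 1000 permutations. Identical config and seed
give byte-identical tables, which the suite asserts, and a pipeline run
equals the composition of the individual stages on the same matrix.
Progress messages go to standard error so files and standard output stay
machine-parseable; the thin command-line front end in `inst/cli/`
(subcommands `run`, `cooccur`, `network`, `simulate`) exits 0 on success,
1 on validation errors and 2 on runtime failures.

## Known limitations

* Presence/absence only; no abundance weighting, rarefaction or diversity
  indices.
* The pairwise null ignores site covariates: a shared microhabitat
  preference and a true interaction are indistinguishable.
* Network metrics are unweighted; shared-sample multiplicities are
  exported but unused.
* Community detection beyond connected components (Louvain,
  leading-eigenvector) is intentionally absent — the modularity question
  this workflow answers is about the component partition against a label
  shuffle, not about optimized partitions.
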