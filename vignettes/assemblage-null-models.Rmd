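---
title: "Null-model analysis of assemblage structure: methods and design"
author: "assemblageNull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model analysis of assemblage structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblageNull)
```

## The question

Given a set of species recorded across a set of sites — here, Late
Cretaceous South American titanosaur species recorded across fourteen
stratigraphic formations — did deterministic ecological processes
(competition, habitat filtering, size-mediated niche partitioning)
structure the assemblage, or are the observed co-occurrence and body-size
patterns indistinguishable from chance? The package answers this with
three classical community-ecology tools: a nonparametric richness
estimator, a co-occurrence null model, and body-size overlap null models.
All three are Monte Carlo tests: an observed statistic is compared with
its distribution over pseudo-assemblages randomized under an explicit
null hypothesis.

## Richness: Chao1

With per-species record counts, the Chao1 estimator is

$$\hat S_{\mathrm{Chao1}} = S_{obs} + \frac{F_1^2}{2 F_2},$$

where $S_{obs}$ is the number of observed species, $F_1$ the number of
singletons (species with exactly one record) and $F_2$ the number of
doubletons. The intuition: the ratio of singletons to doubletons measures
how much of the rare tail remains unseen. Implementation choices:

* **$F_2 = 0$ fallback.** The classical formula is undefined when no
  doubletons exist; `chao1Estimate()` then uses the bias-corrected term
  $F_1 (F_1 - 1) / (2 (F_2 + 1))$ and flags the result
  (`biasCorrected`). With $F_1 = 0$ too, the estimate collapses to
  $S_{obs}$ exactly.
* **Confidence interval.** We use the log-normal interval of Chao (1987),
  the convention of the EstimateS program: with $T = \hat S - S_{obs}$
  and estimator variance $\widehat{var}$,
  $K = \exp\!\left(z \sqrt{\ln(1 + \widehat{var}/T^2)}\right)$ and the
  bounds are $S_{obs} + T/K$ and $S_{obs} + T K$. This interval respects
  the hard floor $S_{obs}$; $T = 0$ degenerates to $[S_{obs}, S_{obs}]$.
* **Accumulation curves.** `accumulationCurve()` pools individual fossil
  records (not sites) in random order, recomputing $S_{obs}$ and Chao1 at
  every level and averaging over randomizations (default 1,000). Both
  sampling modes are available; the default is without replacement (a
  random permutation of the records). The two conventions differ only in
  curve smoothness, not in the endpoint, which is always the full-data
  $S_{obs}$.

The titanosaur per-species record counts come from a supplementary
compilation that is not redistributed here, so the packaged fixture
supports the richness machinery only through synthetic abundance vectors
(`makeAbundances()`), which hit prescribed $(F_1, F_2)$ targets exactly.

## Co-occurrence: C-score under the fixed-fixed sequential-swap null

For a species pair with row totals $r_i, r_j$ sharing $S$ sites, the
checkerboard-unit count is

$$CU = (r_i - S)(r_j - S),$$

the number of mutually exclusive site pairs the two species form. The
C-score is the mean CU over all $R(R-1)/2$ unordered pairs — all pairs
enter, including those with $CU = 0$. Segregated (competitively
structured) assemblages have high C-scores.

The null model holds both margins fixed: every pseudo-matrix has the same
number of occupied sites per species and the same richness per formation
as the data. Sampling is by **sequential swap**: pick two rows and two
columns uniformly at random; if the 2×2 submatrix is a checkerboard, flip
it (which preserves both margins); repeat. `nullModelCscore()` discards a
burn-in of 30,000 attempted swaps, then records the C-score once per
successful swap (`thin = 1`), 10,000 times by default. The chain is
implemented in C++ for throughput; margins are re-derived and verified at
every recorded state. Defaults were chosen to make the recorded chain
clearly longer than the mixing time of matrices of this size (a few
hundred cells); both controls are configurable.

Numerical conventions:

* Tail probabilities use the add-one correction
  $p = (1 + \#\{null \ge obs\}) / (1 + \text{iterations})$, ties counted
  toward the tail (the conservative choice); both tails and the
  standardized effect size $(obs - \mu_{null})/\sigma_{null}$ are always
  reported.
* All-zero rows and columns are dropped with a warning by default: they
  can never participate in a swap and only deflate the mean CU.
* A matrix with no swappable submatrix (every pair nested) cannot be
  randomized under fixed margins at all; the result is flagged
  `degenerate` with SES reported as NA rather than silently returning a
  constant distribution.

Because successive recorded states differ by a single swap, consecutive
null values are autocorrelated. This is the standard behavior of
sequential-swap samplers; the type-I calibration test in the suite
(rejection rate on matrices drawn from the null itself) shows the
resulting test operates at close to its nominal level for matrices of the
fixture's shape.

### A documented discrepancy

On the packaged occurrence matrix the C-score, computed by the printed
formula and confirmed by an independent brute-force pair enumeration and
by a dissimilarity-based cross-check, is $377/253 \approx 1.4901$, with
215 of 253 pairs forming at least one checkerboard unit. The source study
reports an observed C-score of 1.96 against a null mean of 1.91. Those
values are not recoverable from the published matrix under the standard
all-pairs C-score definition; either the analyzed matrix differed from
the printed one or a non-standard averaging was used. The package follows
the printed matrix and the printed formula and does not attempt to match
the reported 1.96. The *qualitative* conclusion is unaffected and is
reproduced: the observed score sits well inside the null distribution
(SES ≈ −0.8, both tails > 0.2 at 10,000 iterations).

A second, smaller discrepancy: the source text calls the Allen Formation
the second-richest unit with six species, but its printed column sums
to five. The fixture follows the printed table (Allen = 5).

## Body-size overlap: segment lengths

Body lengths are log10-transformed — size structure is a ratio-scale
phenomenon — sorted, and differenced. Two statistics summarize spacing:

* **variance of segment lengths** — a structured (evenly spaced)
  assemblage has variance significantly *smaller* than null, so the
  structure tail is `pLower`;
* **minimum segment length** — the gap between the closest species pair;
  structure requires it significantly *greater* than null (`pUpper`).

The default null (`mode = "uniform"`) keeps the observed minimum and
maximum as fixed endpoints and draws the $n - 2$ interior values
independently and uniformly between them, the Barton–David-style segment
null. This is the operative reading of a source-pool randomization in
which the pool equals the assemblage itself: resampling the assemblage
from itself without replacement is degenerate (every pseudo-assemblage
would be the observed one), so the uniform-interior null is the default
and pool mode (`mode = "pool"`) requires a pool strictly larger than the
assemblage. Endpoint randomization is available via
`fixedEndpoints = FALSE`.

Choices worth noting: the minimum-segment metric is computed on the
transformed scale by default (`transform = "identity"` reproduces a
meters reading); variance uses the population (divide-by-count)
convention, configurable and recorded in the statistic label; tied sizes
are allowed — the minimum segment is then zero and a warning notes the
tie. For the $n = 3$ uniform null the mean minimum segment has the
closed form $E[\min(U, 1-U)] = 1/4$ (endpoints rescaled to $[0,1]$),
which the test suite uses as an exact oracle for the simulator.

## The packaged fixture and its limits

`titanosaurFixtures()` returns the 23-species × 14-formation occurrence
matrix (33 occurrences; column totals 4, 7, 1, 5, 1, 2, 3, 3, 1, 1, 2,
1, 1, 1) and a body-size table. Only two lengths of the original
assemblage are pinned by the main published record: *Rocasaurus muniozi*
at 8 m and *Puertasaurus reuili* at 30 m. The default size table
therefore carries NA for the other 21 species — missing is marked
missing, not invented. For end-to-end runs a complete stand-in is
packaged (`sizes = "synthetic"`): the two anchors plus 21 log-uniform
draws strictly between them, generated once under a fixed seed and
shipped as `titanosaur_sizes_synthetic.csv`. Its per-species values are
placeholders; conclusions that depend on which species has which length
cannot be drawn from it. Since the stand-in is itself an unstructured
draw, the non-significant size-overlap outcome on it demonstrates the
machinery and the direction of the published conclusion, not an
independent re-measurement of the original size data.

## Synthetic assemblages

The generators give every analysis a ground truth:

* `makeCheckerboard(nPairs, sitesPerSpecies)` — `2*nPairs` species over
  two disjoint site blocks; every within-pair $CU =$
  `sitesPerSpecies`$^2$; maximal segregation for its margins.
* `makeNested(nSpecies, nSites)` — occupied-site sets form a chain; every
  $CU = 0$; the degenerate (unswappable) extreme.
* `makeRandomMargins(template, nSwaps)` — successful-swap chain from a
  template; the fixed-fixed null itself, used for calibration.
* `makeAbundances(sobs, f1, f2)` — exact singleton/doubleton targets;
  the tail (counts ≥ 3) is shifted-geometric with mean 5, a cosmetic
  choice since only $(F_1, F_2)$ enter Chao1.
* `makeSizes(n, pattern)` — `even_log` (zero segment variance),
  `uniform` (the unstructured reference) and `clustered` (two Gaussian
  clumps, sd 2% of the log range, chosen to give the power tests sharp
  contrast at $n = 15$).

What the generators do *not* emulate: taphonomic and preservational
biases, spatially autocorrelated sampling effort, and phylogenetic
non-independence of body sizes. Tests passing on synthetic data therefore
validate the statistical machinery, not the biological fidelity of any
particular null.

## Problem sizes and determinism

Default analyses use 10,000 null iterations (co-occurrence burn-in
30,000 attempted swaps) and 1,000 accumulation randomizations. The test
suite validates calibration with 200 margin-matched replicates at 500
iterations each and power with 100 replicates at 1,000 iterations —
sizes at which the binomial envelopes used in the assertions are
informative. Every stochastic function takes a `seed`; the pipeline fans
a single top-level seed out to per-stage seeds and echoes them in the
report's provenance block, so a report reproduces bit-for-bit.

## Known limitations

* The C-score test conditions on both margins; with 33 occurrences in
  322 cells the null space is modest and the null distribution of the
  C-score is discrete, making the add-one p-values mildly conservative.
* Only the C-score (not CHECKER, V-ratio or COMBO) and only the
  fixed-fixed sequential-swap algorithm are implemented.
* Chao1 is the only richness estimator; it is a lower-bound-style
  estimator and its CI assumes the log-normal approximation.
* The size-overlap tests treat species sizes as independent draws; no
  phylogenetic correction is attempted.
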