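---
title: "Degree-preserving null models with forbidden edges: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-preserving null models with forbidden edges: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redese)
```

## The model

A bipartite degree sequence prescribes a degree for every vertex of two
classes $U$ and $W$; a *realization* is a simple bipartite graph matching the
prescription whose edges avoid a *forbidden set* $\mathcal{F}$ of vertex
pairs. Pairs that may carry an edge are *chords*; forbidden and same-class
pairs are non-chords. `redese` restricts $\mathcal{F}$ to a (partial)
1-factor (a matching) plus one star with center $s \in U$ — "1F1S". This
class is closed under the counting recursion below, and it contains the
bipartite representation of loop-free directed graphs (the forbidden
diagonal is a perfect matching; the star is empty), which is the main
applied use: degree-preserving null ensembles for directed and bipartite
networks.

Three algorithmic layers sit on top of the validated problem object:

1. **Construction.** The generalized Havel greedy (`greedy_realize`)
   repeatedly fixes the neighborhood of one $U$-vertex — the star center
   while the star is non-empty, else the first remaining label — connecting
   it to its first $d(u)$ chord-neighbors in a *good order* and deleting it
   together with its forbidden incidences. The instance is graphical if and
   only if the greedy completes, which gives a polynomial decision
   procedure (`is_graphical`) used throughout as an exact feasibility
   oracle.
2. **Connectivity.** Any two realizations differ in a balanced two-colored
   edge set that decomposes into alternating cycles; each cycle of length
   $2i$ is processed into $\mathcal{F}$-compatible C4/C6 swaps of total
   weight $i-1$ by recursively splitting at a chord between vertices at odd
   cyclic distance (`process_circuit`, `swap_path`). Under 1F1S no
   compatible circular swap longer than C6 exists.
3. **Sampling and counting.** The lazy chain (`run_chain`) holds with
   probability $1/2$, proposes a uniform C4 swap with probability $1/4$ and
   a uniform C6 swap with probability $1/4$; its transition matrix is
   symmetric, so the uniform law is stationary, and the chain is rapidly
   mixing on half-regular instances. The self-reduction counter
   (`approx_count`) conditions on one chord of the star center at a time
   and multiplies reciprocal branch fractions estimated from chain samples.

## Parameters that matter

* `steps`, `burn_in`, `thin` (`chain_config`): burn-in defaults to
  $10\,|U|\,|W|$ steps and thinning to $|U|\,|W|$ — engineering defaults in
  units of proposal rounds, adequate for generic use where consecutive
  samples need not be independent.
* `level_samples` (`approx_count`, default 100): chain samples per
  recursion level. The per-level fraction has binomial standard error
  $\sqrt{p(1-p)/m}$, so the relative error of the product grows roughly
  with the square root of the number of *balanced* levels; double $m$ to
  halve the variance.
* The counter thins at $3\,|U|\,|W|$ by default, more conservatively than
  the generic chain: the fraction estimator assumes near-independent
  draws. On a dense $3\times3$ instance the chain's relaxation time is
  about 12 steps; thinning at one relaxation time leaves autocorrelation
  near $0.4$, which we measured to miscalibrate a chi-square uniformity
  check badly (about 25% false rejections at the 1% level) and to inflate
  the fraction variance. Three relaxation times reduce the residual
  correlation to a few percent. Where the state space is enumerable the
  tests derive the thinning interval from the exact spectral gap.
* `limit` (`exact_enumerate`): a budget on the number of realizations kept
  by the backtracking enumerator, which is exponential in general and
  intended for desk-scale verification only.

## Design choices where the design was open

* **Circuit distance convention.** The distance of two circuit vertices is
  the number of chords between them along the *shorter* arc. This is the
  only reading under which a C4 has no "problematic vertex" pairs (every C4
  swap is compatible) while a C6 has exactly its three opposite pairs —
  both facts the rest of the machinery depends on.
* **Good-order tie-break when the forbidden partner is missing.** Among
  equal-degree neighbors the good order ranks by the degree of the
  forbidden partner $y^{\mathcal F}$; a neighbor *without* a partner ranks
  **last** (key $-\infty$). The opposite convention is subtly wrong: on the
  directed-triangle instance it directs the greedy into a dead end although
  the instance is graphical. The obstruction analysis behind the
  neighborhood-exchange lemma shows the blocking configuration requires
  $z^{\mathcal F}$ to exist and carry an edge at $y$, so ranking
  partner-free vertices last can never create it; the exhaustive
  greedy-vs-backtracking equivalence suite (10⁴ instances) confirms the
  choice.
* **Star inference.** A $U$-vertex with two forbidden incidences is the
  only possible center; when all $U$-incidences are single, a $W$-vertex
  with two incidences still forces a star edge, and the candidate centers
  (the common $U$-partners of all such $W$-vertices) are tried in input
  order. Only $U$ is searched for a center. With an empty star the center
  is left unset and designated on demand as the first $U$ label.
* **Degenerate proposal classes.** If a class has fewer than 2 (resp. 3)
  vertices the C4 (resp. C6) branch of a chain step is a forced hold; this
  keeps the transition matrix stochastic on the smallest instances.
* **Branch policy of the counter.** At each level the branch with estimated
  fraction $\ge 1/2$ is followed, keeping every multiplier at most 2. A
  branch whose reduced instance the greedy proves infeasible contributes
  multiplier exactly 1. An estimated fraction of 0 or 1 with both branches
  feasible triggers a re-run with doubled samples.
* **Determinism.** All tie-breaks use input label order: the greedy pivot,
  the good order, circuit extraction (first unsaturated vertex, first
  unused chord of the required color), and the split chord in circuit
  processing (first odd-distance chord pair by position). Identical seed
  and configuration reproduce identical trajectories within a build.

## What the fixture generator emulates

`generate_fixture` builds a half-regular instance around a known witness:
an $r$-regular round-robin bipartite graph, randomized by valid C4 swaps,
whose $W$-degrees then *define* the prescription; the forbidden star and
matching are drawn among the witness's non-edges, so the witness realizes
the emitted problem by construction. This matches the regime the sampling
guarantee addresses (half-regular in $U$, modest forbidden sets) and gives
every randomized test a feasible instance with a valid starting state.

What it does **not** emulate: skewed or heavy-tailed $U$-degrees
(half-regularity is built in), forbidden sets beyond 1F1S, and the scale of
real interaction networks — the test battery works on instances whose state
spaces can be enumerated (up to a few hundred realizations), because the
properties checked (uniform stationarity, connectivity, count conservation)
need exact references. Passing tests therefore validate the algorithms'
correctness, not the mixing speed on large heterogeneous data.

## Numerical and degenerate-input choices

* Degree-sum mismatches are recorded on the problem object rather than
  raised, so enumeration and counting return 0 cleanly.
* Zero-degree vertices are legal; a zero-degree operative star center is
  eliminated outright during the counting recursion (it has no edges in
  any solution).
* The uniformity acceptance check uses a chi-square at significance 0.01
  on 10⁴ draws thinned at three relaxation times (see above).
* Problem sizes in the test suite: canonical $2\times2$ and $3\times3$
  instances; randomized batteries up to $5\times6$ with degrees $\le 3$ and
  state spaces capped at 200; the exhaustive graphicality family covers
  classes up to size 4 with degrees up to 3 and up to 4 forbidden pairs,
  sampled to 10⁴ instances.

## Known limitations

* The self-reduction estimator with majority branching is slightly biased
  low at levels whose true branch fraction is close to $1/2$: the chosen
  branch's empirical fraction is by construction $\ge 1/2$, so its
  reciprocal cannot exceed 2. With $m$ samples per level the bias is of
  order $\sqrt{2/(\pi m)}$ per balanced level (about 2–5% at $m = 200$),
  which is visible on instances with several balanced levels. Increasing
  `level_samples` shrinks both bias and variance; no explicit
  $(\varepsilon, \delta)$ schedule is implemented.
* Rapid mixing is a guarantee only for half-regular instances; the chain
  runs elsewhere (uniform stationarity holds regardless) after a warning,
  with no mixing-time diagnostics beyond what the user arranges.
* Swap paths are not minimum-weight: the decomposition is deterministic,
  not optimal, and no optimality claim is made.
* The enumerator accepts arbitrary forbidden sets, but the chain, greedy
  and counter require validated 1F1S problems.
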