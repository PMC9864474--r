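---
title: "Similarity downselection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity downselection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdselect)
```

## The problem

Given a population of $N$ items with a pairwise dissimilarity $d_{ij} \ge 0$
between every two items, the *most dissimilar set problem* (MDSP) asks for the
size-$n$ subset $S$ maximizing the total pairwise dissimilarity

$$
f(S) \;=\; \sum_{\{i,j\} \subset S,\; i<j} \ln d_{ij},
$$

with every unordered pair counted exactly once. $f(S)$ is the natural log of
the product of pairwise distances; working on the log scale matters because a
raw product of tens of thousands of factors over- or underflows IEEE doubles,
while the log-sum stays representable. Maximizing $f$ rewards items that are
far from *everything* already chosen and punishes any item with even one very
small pairwise relation — a single near-duplicate pair drives the whole
product toward zero.

The motivating application is molecular conformer sampling for reference-free
metabolomics: property predictions (e.g. collision cross sections) are
averaged over a conformer ensemble, and computing quantum-chemical properties
for tens of thousands of near-identical geometries is wasted effort. Picking
the $n$ conformers most dissimilar *from each other* (by RMSD between
corresponding atoms) spans conformational space with few structures. Note
this is not the same as picking conformers dissimilar from the population
average: two conformers can both be far from the mean yet nearly identical to
each other.

Exhaustive search must score $\binom{N}{n}$ subsets
(`search_space_size()` computes this exactly in arbitrary precision — at
$N = 50{,}000$, $n = 3$ it is already 20,832,083,350,000), so beyond toy sizes
only heuristics are practical.

## The greedy algorithm

`sds_select()` implements the similarity-downselection heuristic:

1. Log-transform the matrix (`log_transform()`): off-diagonal entries become
   $\ln d_{ij}$, zero distances become $-\infty$, the diagonal is masked
   with `NA`.
2. Select the pair with the largest $d_{ij}$ — this size-2 set is provably
   optimal.
3. Maintain a *summation array*: the element-wise sum of the selected items'
   log-rows. Entries at selected indices are masked `NA`.
4. Repeatedly select the index with the largest unmasked summation value
   (the item whose log-sum of distances to everything already selected is
   greatest), add its log-row into the array, and mask it. Stop at $n$ items.

Each step is $O(N)$, so the full pass over all set sizes
(`sds_select_all()`) is $O(N^2)$ time and $O(N)$ auxiliary space beyond the
matrix. By construction the size-$n$ solution is a prefix of the size-$(n+1)$
solution (*nesting*) — exact solutions do not generally nest, which is both
the heuristic's speed and its approximation gap.

`mode = "similar"` is the mirror image (start from the minimum pair, take the
smallest summation value): it finds the most mutually *similar* set. Zero
distances, i.e. exact duplicates, are then the best possible candidates and
the $-\infty$ sentinel deliberately sorts first.

### Baselines

* `mc_select()` — best of `iterations` uniformly random $n$-subsets;
  the "repeated random sampling" baseline. Draws are independent with no
  deduplication (deduplication would cost more than the $O(n^2)$ scoring it
  saves at realistic $N$), and a fixed seed fully determines the result.
* `exact_select()` — plain exhaustive enumeration in lexicographic order
  (C++ inner loop), with a tractability guard that refuses above $10^7$
  subsets unless overridden. No branch-and-bound: the point of the exact
  baseline is to be unarguably correct, not fast.
* `mean_random_objective()` — the expected objective of a uniformly random
  $n$-subset. By linearity of expectation each pair appears with equal
  probability, so the expectation is exactly
  $\binom{n}{2} \cdot \overline{\ln d}$, with the mean taken over all
  off-diagonal pairs. We compute this closed form rather than an empirical
  average so the "mean" reference line is deterministic.

## Numerical and design choices

* **Zero distances.** $\ln 0 = -\infty$ propagates through sums; an objective
  containing a duplicate pair is reported as $-\infty$, not an error. In
  dissimilar mode a duplicate of a selected item can only be chosen when
  every unmasked candidate is at $-\infty$. `mean_random_objective()` alone
  treats a zero distance as an error, because a finite "expected value"
  does not exist there and silently returning $-\infty$ would hide a data
  problem in a reference curve.
* **Tie-breaking.** The source description is silent on ties; every selector
  here breaks ties toward the smallest index (lexicographically smallest
  subset), so all outputs are deterministic given (matrix, parameters, seed).
* **Symmetry tolerance.** `validate_matrix()` accepts asymmetries up to
  `1e-8` relative and averages them; anything larger is an error. The
  diagonal is forced to exactly zero.
* **Indexing.** All programmatic indices are 1-based, the R convention, and
  reports state `index_base=1`. (A 0-based contract would be idiomatic in
  Python, not here.)
* **Arbitrary precision.** `search_space_size()` uses exact base-$10^7$
  big-integer arithmetic (multiply/divide by machine integers only), because
  doubles lose exactness above $2^{53}$ and $\binom{N}{N/2}$ for $N$ in the
  hundreds has dozens of digits.
* **Precision folklore.** Accounts of the multiplicative variant place the
  double-precision breakdown near $10^{323}$; IEEE doubles actually overflow
  at $\approx 1.8 \times 10^{308}$ (and bottom out subnormally at
  $\approx 4.9 \times 10^{-324}$, likely the number intended). Nothing
  depends on it: the log-sum is used regardless.
* **Memory.** The matrix is held dense in memory: $O(N^2)$ doubles
  (≈ 20 GB at $N = 50{,}000$). Shipped tests stay at $N \le 2{,}000$.

## The conformer front-end

`read_xyz()` / `read_sdf()` parse multi-record files into an ensemble and
enforce that every record has the same elements in the same order —
corresponding-atom RMSD is undefined otherwise. `pairwise_rmsd()` is the
standard $\sqrt{\frac{1}{A}\sum_k \lVert a_k - b_k \rVert^2}$ over the $A$
atom pairs (*not* a mean of per-atom RMSDs). By default coordinates are
compared **as given** (`superpose = FALSE`) — the literal reading of
"RMSD between corresponding atoms" for conformers generated in a common
frame; `superpose = TRUE` first applies least-squares rigid superposition
(Kabsch via SVD, with the determinant sign corrected so reflections are never
applied). The flag used is recorded in the matrix metadata. Limitations,
deliberately out of scope: no equivalent-atom (symmetry) permutation
correction, and hydrogen stripping is a coarse all-or-nothing flag
(`strip_hydrogens()`).

## What the synthetic generators do and do not emulate

* `random_point_population(N, dim, seed)` — uniform points in the unit
  hypercube with Euclidean distances. The default test world: a genuine
  metric, like RMSD, with plenty of near-ties. Default `dim = 3` mirrors the
  dimensionality of the physical application.
* `random_matrix(N, seed)` — i.i.d. symmetric entries, uniform on (0.1, 1]
  by default. *Not* a metric; a stress test confirming the selectors never
  assume the triangle inequality.
* `perturbed_ensemble(atom_count, K, sigma, seed)` — one random base
  structure, each conformer an i.i.d. Gaussian displacement of it
  (default-free; tests use $\sigma$ of 0.2–0.5 Å, a realistic thermal spread
  for small molecules). Two copies then satisfy
  $E[\mathrm{RMSD}^2] = 6\sigma^2$ (per-coordinate difference variance
  $2\sigma^2$, three coordinates), which the tests verify by simulation.
  These ensembles have no bonds, torsions or energies, and their
  unimodal geometry cloud is much tamer than a simulated-annealing conformer
  population: a green test establishes algorithmic correctness, not chemical
  realism.

Every generator derives its RNG stream from the user seed plus a fixed
per-generator offset (`seed * 16 + offset` modulo $2^{31}-1$, offsets 1–3),
so fixtures are bit-reproducible and adding a generator call elsewhere never
perturbs existing ones.

## What the benchmarks establish

`bench_mc()` reruns the greedy-vs-sampling contest at desk scale
($N \approx 2{,}000$, $10^4$ iterations, instead of $N = 50{,}000$ and
$10^6$): the greedy selector should win at essentially every set size, with
occasional sampling wins only plausible at very small $n$ on small
populations. `bench_exact()` computes the four reference values — exact
maximum, greedy, analytic random-subset mean, exact minimum — and asserts
the orderings that must hold (exact ≥ greedy, mean ≥ minimum). Wall-clock
columns are informational only and never asserted: they are
hardware-dependent. The acceptance suite encodes the statistical versions of
these claims (greedy ≥ MC on at least 4 of 5 set sizes per seed; greedy
above the mean reference on at least 19 of 20 exact-benchmark instances) and
the structural identities (n = 2 exactness, nesting, greedy-increment,
log-sum/product equivalence).

## Known limitations

* The heuristic carries no optimality certificate; its gap to the exact
  solution is bounded only empirically here.
* Dense $O(N^2)$ memory; no sparse or out-of-core path.
* Only user-supplied matrices, RMSD, or the synthetic metrics — no other
  built-in dissimilarity measures.
* The binary matrix format does not store labels; use the text format when
  labels matter.
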