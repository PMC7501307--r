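---
title: "Optimal binary classification of amino acids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal binary classification of amino acids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaopt)
```

## The problem and the model

Classifying the 20 proteinogenic amino acids by interpretable
physicochemical features underpins much of protein biochemistry: alignment
scoring, substitution reasoning, secondary-structure intuition. Classic
Euler-diagram schemes in the Taylor tradition use eight or more overlapping
features and still leave some amino acids indistinguishable. `aaopt`
implements the opposite extreme: the *minimum* number of binary features
that give every amino acid a unique group.

A numeric feature $j$ with values $v_j(a)$ and a threshold $t$ define a
binary separation: amino acid $a$ goes to the low side iff
$v_j(a) \le t$. A set of $f$ features assigns each amino acid an $f$-bit
code; the set is an **optimal classification** when all codes are distinct.
Since $2^4 = 16 < 20 \le 32 = 2^5$, $f = 5$ is the minimum, and any
solution leaves exactly $32 - 20 = 12$ codes empty.

Two facts drive the algorithm:

1. **Capacity (non-redundancy) criterion.** After applying $n \le f$
   separations, unique classification remains possible iff no partition
   cell holds more than $2^{f-n}$ amino acids. This is a *necessary*
   condition satisfied by every prefix of every solution, so it is a sound
   pruning rule: the depth-first search (`find_solutions()`) revokes a
   separation as soon as a cell overflows. The rule at depth 1 is
   equivalent to the cut-size filter $[4, 16]$ used during pool
   construction for 20 residues.
2. **Unordered solutions.** A solution is a *set* of five separations; the
   $5! = 120$ ordered tree layouts are presentation variants. The search
   enumerates pool subsets in canonical order (accession, then cut size),
   so each set is visited exactly once, and `brute_force_solutions()`
   provides an unpruned oracle the test suite compares against on
   randomized pools.

## Separation pools

**Median mode.** Each feature contributes its median split: low side
$= \{a : v_j(a) \le \mathrm{median}_j\}$. Ties at the median go low — the
natural reading of "less than or equal" — so tied medians can give
unbalanced splits, and a feature whose values place everything on one side
has no realizable median split and is skipped with a warning. With 20
distinct values the split is always 10/10.

**Cuts mode.** Every pair of adjacent sorted values that differ strictly is
a realizable cut (ties can never be split; 19 cuts for 20 distinct values).
Each cut's **gap** is the value difference it crosses, and its **score** is
the number of other cuts of the same feature with strictly smaller gap.
Scoring is computed on the *complete* realizable cut set, before any
filtering — the only convention under which the top score for a 19-cut
feature is 18 and a five-separation solution can reach $5 \times 18 = 90$.
Equal gaps share a score. After scoring, cuts whose group sizes fall
outside `size_bounds` are dropped, and the `k` widest-gap survivors per
feature are kept (ties broken by higher score, then smaller cut size).

Tunable parameters, all dimensionless:

| parameter | default | meaning |
|---|---|---|
| `f` | 5 | separations per solution; must satisfy $2^f \ge n$ |
| `k` | 3 | cuts kept per feature in cuts mode |
| `size_bounds` | capacity bounds | allowed group sizes, $[n - 2^{f-1},\, 2^{f-1}]$ = $[4, 16]$ at $n = 20$ |
| `distinct_features` | `TRUE` | at most one cut per feature per solution |
| `force_median` | `FALSE` | cuts mode: always admit the median split |

`k = 3` is the demonstration default; `k = 2` ("the two widest gaps") is
equally defensible and both are supported — neither is privileged. The
`size_bounds` default is derived from the capacity rule for the *current*
alphabet size, so leave-one-out runs on 19 residues automatically use
$[3, 16]$.

**Deduplication** is pool-wide: if two separations (of the same or
different features) classify identically, only the highest-scoring one is
kept (ties: lexicographically smallest accession, then smallest cut size).
Restricting deduplication to within-feature duplicates would double-count
solutions built from perfectly correlated features; `separation_identity()`
exposes the same equality test for ad-hoc checks of correlated features.

**Thresholds** are reported as the largest low-side value, not a midpoint.
This makes the printed rule "high iff value > t" use a value that actually
occurs in the data, which is how practitioners quote such cut points.

## Leave-one-out redundancy

`redundancy_profile()` asks how many *additional* solutions appear when one
amino acid is ignored. The separation pool is the one learned from the full
table — every median and cut is applied to all 20 amino acids — and leaving
a residue out only restricts the membership vectors and the uniqueness
requirement to the remaining 19 (`restrict_pool()`). Under this definition
every full-alphabet solution survives every deletion, so
`additional_solutions` $\ge 0$ is a theorem, which the tests verify. The
alternative — recomputing medians on 19 values — shifts every split by one
element whenever the deleted residue sat in a low half, destroys that
monotonicity, and answers a different question (how classifiable a
19-letter alphabet is, rather than how redundant a residue is within the
20-letter analysis); we deliberately use the restriction reading.

## Niche assessment

`niche_assessment()` (also `predict()` on a fitted classification) codes a
candidate amino acid with the thresholds learned from the canonical 20 —
the candidate never shifts a threshold — and counts how often the code is
unoccupied. Solutions needing a feature value the candidate lacks (`NA` or
absent) are skipped and reported, because context-dependent features such
as helix propensities are often undetermined for non-canonical amino
acids. For any one solution a candidate code is either empty or collides
with exactly one residue, a dichotomy the tests assert.

## The synthetic generator

`generate_planted_table()` emulates a residue-by-feature table with a known
optimal classification: distinct $f$-bit codes per residue, and one feature
per code bit whose values occupy a low band $[0, 0.9]$ (bit 0) or a high
band $[2, 2.9]$ (bit 1). The between-band gap (at least 1.1) strictly
dominates every within-band gap (at most 0.9), so the planted cut is each
feature's widest-gap cut deterministically, not just with high probability.
With `balanced = TRUE` codes are drawn as complement pairs
$\{c,\, 2^f - 1 - c\}$, making every bit-plane split exactly 10/10, so the
planted cut coincides with the median split and median-mode search recovers
the planted solution too. Noise features are 18 exactly tied values plus
two high outliers: their only realizable cuts isolate one or two residues,
which the size filter removes (guaranteed whenever $n - 2 > 2^{f-1}$, as at
$n = 20$); making noise ineligible via the size filter rather than via
duplicate vectors matters because duplicates would be removed by
deduplication and never stress the search. With a `k = 1` pool the planted
solution is provably the only one; with `k \ge 2` pools, alternative
solutions assembled from secondary cuts of planted features can genuinely
exist, so recovery is then asserted as "present and top-scoring" rather
than "unique".

What the generator does *not* emulate: the value distributions of real
physicochemical indices, correlations between features (real volume scales
correlate strongly), and missing-value patterns. Passing tests therefore
demonstrate algorithmic correctness — pruning soundness, canonical
enumeration, scoring arithmetic, format fidelity — not that any particular
real feature set admits solutions; for real data the user supplies an
AAindex1 file and a curated accession list, which the same pipeline
consumes (the tests exercise that pathway end-to-end on a synthetic flat
file).

`generate_random_table()` adds uniform tables with a controllable fraction
of within-feature ties, used to exercise tie handling in sorting, cut
enumeration and median splits.

## Numerical choices and degenerate inputs

* Values are parsed by exact decimal-to-double conversion and written with
  17 significant digits, so both interchange formats (AAindex1 flat file,
  TSV) round-trip bit for bit; `NA` tokens are imputed to zero at parse
  time, flagged per feature, and re-emitted as `NA` on writing.
* Sorting is ascending by value with ties broken by alphabet position, so
  cut enumeration is deterministic; all tie handling follows from "tied
  values are never split".
* Constant features yield zero cuts (cuts mode) or a "no realizable median
  split" error (median mode, downgraded to a warning during pool
  construction).
* The search is an explicit-stack depth-first enumeration; depth is bounded
  by $f$ and memory by the open-branch list, so pools of hundreds of
  separations are safe. No randomness is involved anywhere in the search:
  identical pools give identical output without seeds.

## Problem sizes

The test suite and the acceptance script run entirely on generated tables:
oracle-equivalence uses 100 random pools of up to 12 separations (brute
force $\binom{12}{5} = 792$ subsets each), planted recovery uses 100
seeded designs with noise, and redundancy profiling runs on 20-residue
tables with `k = 2` pools. These sizes keep the brute-force oracle exact
while covering the combinatorics; the real-data analysis (83 curated
AAindex features) is the same computation on a pool of at most 83 median
separations or $83 k$ cuts and runs in seconds.

## Known limitations

* The package ships no AAindex data (the database's license and size argue
  against vendoring); real-data results require the user-supplied flat
  file, and the curated accession list is an input, not a package constant.
* Tree-layer ordering for presentation is the canonical one; optimizing the
  layer order so that similar amino acids separate late is out of scope.
* Euler-diagram and tree exports are text (DOT, TSV, JSON); rendering is
  left to graphviz or similar tools.
* Redundancy profiling reports count differences only; it does not identify
  *which* residue pairs share a cell, though the partition API
  (`refine()`/`admissible()`) makes that straightforward to inspect.
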