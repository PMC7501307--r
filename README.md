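# aaopt — minimal binary-feature classification of the proteinogenic amino acids

`aaopt` finds *optimal classifications* of the 20 proteinogenic amino
acids: sets of exactly five numeric physicochemical features (hydrophobicity,
volume, helix propensities, ...) such that repeated binary separation on
those features places every amino acid in its own group. It is aimed at
protein biochemists and synthetic biologists who want interpretable
amino-acid groupings — for alignment analysis, substitution reasoning, or for
choosing non-canonical amino acids that occupy an unfilled "biochemical
niche" when expanding the genetic code.

## The method

Each feature *j* with values *v_j(a)* over amino acids *a* induces a binary
separation at a threshold *t*: the low set is {*a* : *v_j(a)* ≤ *t*}. A set
of *f* features assigns every amino acid an *f*-bit code; the set is an
**optimal classification** when all 20 codes are distinct. Five features are
the minimum, since 2⁵ = 32 ≥ 20 while 2⁴ = 16 < 20, and any solution leaves
exactly 32 − 20 = 12 codes empty.

Candidate separations come from two regimes:

* **median mode** — each feature is split at its median (ties at the median
  go low), so splits are near-balanced by construction;
* **cuts mode** — every realizable cut between adjacent sorted values is a
  candidate. Cuts splitting into groups of < 4 or > 16 are excluded (they
  can never take part in a five-feature solution), each surviving cut gets a
  **gap-rank score** — the number of other cuts of the same feature with a
  strictly smaller value gap, at most 18 for a feature with 19 realizable
  cuts — and the *k* widest-gap cuts per feature are kept. Identically
  classifying separations are collapsed to the best-scoring one.

The search enumerates feature sets depth-first, pruning with the
**non-redundancy capacity criterion**: after *n* of *f* separations, no
partition cell may hold more than 2^(f−n) amino acids. Solutions are ranked
by the **cumulative score** (sum of the five gap-rank scores, maximum
5 × 18 = 90). A brute-force enumerator cross-checks the pruned search in the
test suite. Downstream tools profile per-residue redundancy (how many extra
solutions appear when one amino acid is left out) and assess candidate
amino acids by how often they land on empty codes.

## Worked example

The synthetic generator plants a known five-feature classification plus
noise features, so the full pipeline can be demonstrated (and tested)
without an AAindex download:

```r
library(aaopt)
gen <- generate_planted_table(20, n_noise_features = 3, seed = 11)
fit <- aa_classify(gen$table, mode = "median")
fit
#> Optimal amino-acid classification (median mode, f = 5)
#>   pool: 8 candidate separation(s) over 8 feature(s)
#>   solutions: 1 (top cumulative score 90)
fit$solutions[[1]]
#> Optimal classification: 5 separations, cumulative score 90
#>   PLNT0001  cut 10/10 at 0.777499 (gap 1.369, score 18, median)
#>   PLNT0002  cut 10/10 at 0.677127 (gap 1.507, score 18, median)
#>   PLNT0003  cut 10/10 at 0.732361 (gap 1.281, score 18, median)
#>   PLNT0004  cut 10/10 at 0.706678 (gap 1.374, score 18, median)
#>   PLNT0005  cut 10/10 at 0.891315 (gap 1.236, score 18, median)
#>   empty codes: 12 of 32
```

The one solution is the planted one: each separation is a 10/10 median
split, each cut sits at its feature's widest gap (score 18 of a possible
18), and 12 of the 32 codes stay empty. A candidate amino acid is assessed
by the codes those thresholds give it — here a candidate built to land on
the empty code `00010`:

```r
s <- fit$solutions[[1]]
bits <- strsplit(s$empty_codes[1], "")[[1]]
cand <- setNames(ifelse(bits == "0", s$separations$threshold,
                        s$separations$threshold + 1),
                 s$separations$accession)
predict(fit, cand)
#> Niche assessment for 'candidate': occupies an empty niche in 1 of 1 assessed solution(s)
```

To run the same pipeline on real data, download the AAindex1 flat file,
list your curated accessions one per line, and:

```r
tab <- filter_features(read_aaindex("aaindex1"),
                       read_accession_list("curated.txt"))
fit <- aa_classify(tab, mode = "median")   # or mode = "cuts", k = 3
```

A command-line interface wraps the same operations
(`inst/exec/aaopt parse|search|score|redundancy|niche|simulate|export`).

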