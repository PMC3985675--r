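---
title: "Designing and using transition-constrained subset seeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and using transition-constrained subset seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subseed)
```

## The problem

Homology search between distantly related DNA sequences — say, between two
mammal genomes at roughly 70% identity — is done by *seed-and-extend*:
find short, cheap matches (seeds), then run expensive extension alignment
only around them. Almost all of the sensitivity/speed trade-off is decided
by the seeding stage. `subseed` implements the seeding toolbox this
package is about:

* **subset (transition-constrained) seed patterns** over the alphabet
  `{0, T, 1}`: a `1` position must match exactly, a `T` position tolerates
  transitions (`A↔G`, `C↔T`) but not transversions, a `0` position is a
  don't-care. Transitions are far more frequent than transversions in real
  genomes (about 3:2 between human and mouse rather than the unbiased
  1:2), so tolerating them where mismatches are likely buys sensitivity at
  little cost in specificity.
* **exact sensitivity computation** for a *set* of patterns on an i.i.d.
  alignment model, by automaton dynamic programming;
* **hill-climbing co-design** of several complementary patterns;
* **adaptive seeds**: instead of a fixed seed length, the minimum-length
  match (along the cyclically extended pattern) occurring at most `m`
  times in the reference, found with a per-pattern *subset suffix array*;
* **gapless and gapped X-drop extension** with the usual thresholds
  (`y`, `d`, `ydrop`, minimum score);
* a **synthetic genome-pair generator** and a **chunk benchmark** that
  measures, for a grid of configurations, how often each one misses the
  best alignment score any of them found.

## The alignment model and exact sensitivity

Gapless alignments are modeled as i.i.d. columns over three letters, in
the fixed order (transversion, transition, match). The two foreground
models used throughout are `(0.12, 0.18, 0.70)` — 70% identity with a 3:2
transition:transversion ratio, the inter-mammal regime — and
`(0.15, 0.15, 0.70)` for a 1:1 ratio, appropriate for *Drosophila*-like
comparisons.

The *sensitivity* of a seed set is the probability that some pattern
matches somewhere in a random length-`l` alignment (optionally with hit
offsets restricted to multiples of a sparsity `c`). We compute it exactly:
the set of patterns is compiled into a deterministic automaton whose
states are sets of alive pattern-prefix lengths (plus the offset phase
modulo `c`), with the accepting state absorbing; a forward pass pushes
probability mass through the automaton for `l` steps.

```{r}
sensitivity_dp("11T0TT010T", bernoulli_model(0.12, 0.18, 0.70), l = 64)
```

Because subtle indexing errors in this kind of DP are easy to make and
hard to see, the package also ships `sensitivity_bruteforce()`, a
deliberately naive enumeration of all `3^l` alignment strings (guarded to
`l <= 14`). The test suite drives both routes over hundreds of randomized
seed sets, models, lengths and sparsities and requires agreement to
`1e-12`. The DP itself is exact up to double-precision rounding.

## Seed design

`design_seeds()` maximizes model sensitivity over patterns of fixed
weight (number of `1`s plus half the number of `T`s — stored as an exact
half-integer to keep equal-weight comparisons exact) and bounded span.
The search is simple and honest about being heuristic: random restarts,
each followed by coordinate-wise greedy hill climbing. The neighborhood
is weight-preserving by construction: swap two unequal symbols, trade one
`1` plus one `0` for two `T`s, or two `T`s for one `1` plus one `0`.
Guaranteed-optimal co-design is intractable for transition seeds, which
is precisely why the design is heuristic; for tiny spaces the tests
compare against exhaustive enumeration.

Random initial patterns force their first and last symbols to be non-`0`
when possible (a leading or trailing `0` only shifts the pattern), but
climbing moves may produce them and they are accepted with a warning at
parse time, not rejected.

Ties during climbing are broken toward the lexicographically smaller
pattern text, and all randomness flows from `rng_seed`, so a design is
reproducible. Defaults: `l = 64`, `restarts = 200`. Different `rng_seed`s
may legitimately return different, equally good sets.

The bundled files under `inst/extdata/` (e.g.
`seeds-70-18-12-n2.txt`) were produced by this designer at desk scale
(weight 8, spans 8–12, 30 restarts, recorded seed) — they are examples,
not reference artifacts from elsewhere. The designed patterns are
transition-rich, which is the expected outcome under a 3:2 model.

## Adaptive seeds over subset suffix arrays

For alignment, a pattern is *cyclically extended* (`110T → 110T110T…`),
and each reference suffix is compared under the position-dependent letter
classes this induces: 4 classes at a `1` position, purine/pyrimidine at a
`T` position, one class at a `0` position. One suffix array is built per
pattern (memory is linear in the number of patterns); `N` — which is what
every lowercase (repeat-masked) or ambiguous letter becomes after
`mask_lowercase()` — sorts as a terminator and can never be part of a
match. Realizing `T` positions as a two-letter remap is what keeps every
narrowing step a single contiguous suffix-array interval; for the same
reason interior `0` positions are one class rather than a 4-way union.

From each query position (every `k`-th, if query seeding is sparse), the
prefix is lengthened until it occurs at most `m` times among indexed
positions — the *rareness threshold* — and all occurrences at that
minimal length become seeds. If the count never drops to `m` before the
query ends (or an `N` intervenes), that start yields nothing; emitting an
over-frequent seed instead would flood repetitive regions, which is what
adaptive seeds exist to avoid. Comparison depth is capped (default 512);
adaptive seeds terminate far earlier at any realistic `m`. A quadratic
scan-everything matcher backs the suffix-array path in the tests.

A note on sparse reference indexing (`step = w > 1`): it makes seeds
*rarer*, so the threshold is reached at equal or shorter prefix lengths
and seed matches at indexed positions form a superset of the dense
matches there — sparse indexing saves memory but does not simply
subsample the seeds.

## Extension

* **Gapless**: from a seed's first column, extend left then right along
  the diagonal; each direction stops when the running score drops more
  than `y` below its maximum and is trimmed back to that maximum.
  Anchoring the extension at the seed's *first column* (rather than the
  full seed span) makes the result a pure function of the column — any
  two seeds starting at the same place yield the same segment — which
  gives the pipeline a clean superset property: enlarging the seed set
  (larger `m`, more patterns) can only add records, never perturb
  existing ones. The benchmark's monotonicity rests on this.
* **Threshold `d`**: only segments scoring at least `d` proceed to gapped
  extension. The default rule is `d = round(t·ln(m·r/(10·n)))` with `r`
  the unmasked reference size and `t` the score-matrix scale factor; it
  crudely keeps the number of gapped-phase candidates proportional to the
  gapless-phase work. On a mammal-scale example (`r = 1 363 595 724`,
  `t = 96.1735`) the rule spans `d` from 1823 (`m = 10`, `n = 8`) to 2466
  (`m = 1000`, `n = 1`). `d` is always overridable, and
  `t` is user-supplied configuration (no Gumbel fitting here).
* **Gapped**: affine-gap X-drop DP (`gap_exist + gap_extend·g`; adjacent
  insertions and deletions are allowed, each maximal same-direction run
  paying its own opening) in both directions from the *anchor* — the
  column achieving the gapless maximum, leftmost on ties. Cells more than
  `ydrop` below the best score are pruned; the default
  `ydrop = min_score − 1` gives 3999 for the HoxD70 scheme. Records below
  the scheme's `min_score` are dropped, exact coordinate duplicates are
  merged keeping the best-scoring path, and both query strands are
  searched (minus-strand coordinates follow the MAF convention).

Two scoring schemes are built in: `last_scheme()` (+1/−1, gaps 7+1g,
minimum score 35, N −1, default `y` 10) and `hoxd70_scheme()` (HoxD70
matrix, gaps 400+30g, minimum 4000, N −100, default `y` 962, scale
96.1735). The `y` default for the +1/−1 scheme is this package's choice.
In a *degenerate* configuration — pattern `1`, `m` at least the reference
length, `d = min_score`, very large `ydrop` — seeds cover every matching
column and the pipeline's best score equals a full Smith–Waterman with
the same affine costs; the tests exploit this with an independent plain-R
oracle on related pairs whose ends are kept identical for at least 60 bp
(so a clean gapless run of score ≥ `d` lies on the optimal path under
both schemes, including HoxD70's `d = 4000`).

## The synthetic genome pair and what it does (not) show

`synth_genome_pair()` generates an i.i.d. uniform ancestor, optionally
implants self-similar lowercase repeat tracts (segments copied within the
genome; mean tract length ~300 bp), and derives a relative column by
column: identity with probability `identity`, otherwise a transition with
odds `ts_tv_ratio : 1`; indel events at `indel_rate` per position with
geometric lengths (mean `indel_length_mean`, default 3). The true
alignment is recorded during simulation, so generator validation
(`count_substitutions()` recovering the configured 70/18/12 within one
percentage point at megabase scale) is independent of any aligner.

Defaults emulate the human–mouse regime: identity 0.70, ts:tv 3:2. The
indel rate (0.02/bp) and mean length (3) are round figures typical of
diverged mammalian alignments; repeat implantation defaults off and the
benchmark uses 10%.

What the simulator deliberately does *not* reproduce: compositional
heterogeneity (isochores, CpG effects), rate variation along the genome,
nested/diverged repeat families, and large-scale rearrangements. Passing
benchmarks on this synthetic pair therefore demonstrates correctness of
the machinery and the qualitative parameter response, not performance on
real genomes.

## The chunk benchmark

`run_benchmark()` implements the package's evaluation protocol: sample
random 1 kb chunks (rejecting any with uppercase non-ACGT letters;
lowercase is allowed and masked to `N` just before alignment, in both
chunk and target), align every chunk under every configuration, record
each configuration's best score per chunk, and count, per configuration,
the chunks where it missed the best score any configuration achieved.
Chunk starts are drawn without replacement so duplicate queries cannot
distort counts; error counts are order-invariant; wall time is recorded
but never asserted.

The shipped acceptance checks run 500 chunks × 1 Mb at the 70:18:12
regime over `m ∈ {10, 100, 1000}` × nested one- and two-pattern sets
(query step `k = 4`, fixed `y = 10`, `d = 35`, `ydrop = 34` under the
+1/−1 scheme) and require error counts non-increasing in `m` and in the
number of seeds — the qualitative response one sees on real genome pairs.
Problem sizes here (1 Mb, 500 chunks, weight-8 seeds) are the package's
desk-scale choices; the protocol itself is size-agnostic.

## Numerical and degenerate-input choices

* Letter order is (transversion, transition, match) *everywhere* —
  models, automata, brute force — to preclude silent permutation bugs.
* Weights are exact half-integers (`twice_weight` integer).
* Sensitivity DP in plain double precision; no log-space is needed for
  `l` up to a few hundred.
* The automaton caps at 2^19 states and pattern spans at 63 symbols.
* Empty alignments (`l = 0`) have sensitivity 0; an all-`N` (fully
  masked) query aligns to nothing; an empty reference is an error.
* Coordinates are 0-based half-open everywhere, including MAF output.
* `trim_to_cyclic_prefix()` follows the shortest-prefix-that-recovers
  rule exactly; note it is not idempotent for patterns like `1T011T01`
  (→ `1T01` → `1T0`), because a shorter prefix can regenerate the finite
  pattern without sharing its infinite extension.

## Limitations

No E-values (scores only; the scale factor `t` is supplied, not
estimated), no chaining/netting or paralog filtering, no compressed
indexes, no interpolation between found alignments, and sensitivity is
computed under gapless i.i.d. models only. These are the standard outer
layers around the seeding machinery this package focuses on.
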