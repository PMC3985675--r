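# subseed

Seeding machinery for distant DNA homology search: design
transition-constrained (subset) spaced seeds against an explicit
substitution model, and use them in a seed-and-extend local aligner with
adaptive seeds over subset suffix arrays.

## Why

Between genomes at ~70% identity (human vs mouse, say), almost all of the
sensitivity/speed trade-off of seed-and-extend alignment is decided by the
seeding stage. Two facts drive this package's design:

* Real substitutions are transition-biased (about 3:2
  transitions:transversions between mammals, against the unbiased 1:2), so
  seed patterns over `{0, T, 1}` — where `1` demands a match, `T` tolerates
  transitions (`A↔G`, `C↔T`) and `0` is a don't-care — detect diverged
  homologies that exact-match seeds miss. The *weight* of a pattern is
  `#1 + #T/2` (so `11101011` has weight 6) and governs its rarity.
* Fixed-length seeds behave badly on repetitive, compositionally uneven
  genomes. *Adaptive seeds* instead take, from each query position, the
  shortest match along the cyclically extended pattern that occurs at most
  `m` times in the reference (the rareness threshold), found by interval
  narrowing on a per-pattern *subset suffix array* sorted under the
  pattern's position-dependent letter classes.

What the package computes:

* **Exact sensitivity** of a seed *set*: the probability that some pattern
  hits a random gapless alignment of length `l` drawn i.i.d. over
  (transversion, transition, match) probabilities, via an automaton whose
  states are alive pattern-prefix sets (accepting state absorbing), plus a
  brute-force `3^l` enumeration oracle.
* **Seed co-design**: hill climbing with random restarts over
  weight-preserving moves, maximizing joint model sensitivity of `n`
  patterns.
* **Alignment**: adaptive seeds → gapless X-drop extension (drop limit
  `y`, score threshold `d`, with the default rule
  `d = round(t·ln(m·r/(10·n)))`) → affine-gap X-drop gapped extension
  (`ydrop`), both query strands, MAF output. Built-in scoring schemes:
  `+1/−1` with gaps `7+1g` (min score 35) and HoxD70 with gaps `400+30g`
  (min score 4000).
* **Benchmarking**: a synthetic related-genome-pair generator with
  recorded truth alignment (configurable identity, ts:tv ratio, indels,
  lowercase repeat tracts), and the chunk protocol: align random 1 kb
  chunks under many configurations and count, per configuration, the
  chunks where it missed the best score any configuration found.

## Worked example

Score the bundled pair of codesigned transition seeds, simulate a 50 kb
genome pair at the human–mouse-like regime, and align a 1 kb chunk of the
ancestor back to the derived genome:

```r
library(subseed)

seeds <- read_seed_file(system.file("extdata", "seeds-70-18-12-n2.txt",
                                    package = "subseed"))
sensitivity_dp(seeds, bernoulli_model(0.12, 0.18, 0.70), l = 64)
#> [1] 0.952036

gp <- synth_genome_pair(50000, identity = 0.70, ts_tv_ratio = 1.5,
                        repeat_fraction = 0.1, rng_seed = 42)
ref   <- mask_lowercase(gp$derived)
chunk <- mask_lowercase(sample_chunks(gp$ancestor, 1, 1000, rng_seed = 43))
idx   <- lapply(seeds$patterns, function(p) build_index(ref, p))
recs  <- align(chunk[[1]], idx, scheme = "last", m = 100,
               query_name = names(chunk))
recs[, c("strand", "score", "query_start", "query_end",
         "ref_start", "ref_end")]
#>   strand score query_start query_end ref_start ref_end
#> 1      +   142          21       453     46283   46716
#> 2      +    65         779       946     47030   47200
```

The chunk (drawn from ancestor position 46228) is recovered at the right
place in the derived genome, split into two local alignments where the
accumulated indels interrupt it; scores are +1/−1 column sums minus
`7 + g` per gap. The recorded truth alignment validates the generator
itself:

```r
count_substitutions(gp$alignment$ancestor_row, gp$alignment$derived_row)
#>     identity   transition transversion
#>        69.96        18.15        11.90
```

A command-line front end with `design`, `sens`, `trim`, `index`, `align`,
`simulate` and `benchmark` subcommands lives at
`system.file("scripts", "subseed-cli.R", package = "subseed")`.

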