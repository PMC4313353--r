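# regevo — comparative evolution of promoters and enhancers

Active regulatory elements in a mammalian tissue — promoters carrying
H3K4me3 (with or without H3K27ac) and enhancers carrying H3K27ac alone —
are gained and lost as species diverge. Given per-species replicate
ChIP-seq peak calls, a dated phylogeny and pairwise orthology maps,
`regevo` quantifies that turnover end to end:

1. **Consensus elements** — peaks reproducible in ≥ 2 biological replicates
   (≥ 50% overlap of the shorter peak), merged transitively and classified
   into dual promoters / H3K4me3-only promoters / enhancers.
2. **Cross-species conservation** — interval projection through block-wise
   orthology maps, with `conserved` / `absent` / `unalignable` calls at a
   50% reciprocal-overlap rule, always averaging the two reciprocal
   directions of a species pair.
3. **Turnover rates** — the pairwise conservation ratio decays with
   divergence time *t* as *A·e^(−t/τ)*; log-scale OLS gives the class
   half-life *τ·ln 2* with a 95% CI, and mean lifetime *τ = half-life/ln 2*.
   Neighbor-joining trees are built from `1 − ratio` distances.
4. **Conserved / lineage-specific / recently evolved sets** — strict
   all-panel conservation with majority-rule classification and an exact
   permutation null for the conserved count; clade-restricted conservation;
   elements conserved nowhere.
5. **Sequence age and repeats** — exaptation analysis (age of the most
   distant alignable species, binned 0–40 / 40–100 / ≥ 100 Ma) and
   binomial repeat-family enrichment with BH correction.
6. **Gene layer** — GREAT-style basal-plus-extension regulatory domains,
   tissue-specificity scores, expression ratios, and hypergeometric /
   Wilcoxon tests for association between recently evolved enhancers and
   positively selected genes (PSGs).
7. **Feature regression** — incremental variance decomposition of
   conservation over experimental and sequence features.

Because the statistics, not the raw sequencing data, are what needs
validating, the package ships a seeded synthetic genome-evolution
generator (`sim_config()` / `simulate_world()`) producing a complete
20-species study — dated tree, orthologous DNA blocks with their own
turnover, true element histories with class-specific exponential loss,
replicate peaks with intensity-dependent detection noise, repeats, genes,
expression and PSGs — together with the ground truth for every estimator.

It is aimed at computational biologists studying regulatory evolution who
want the full analysis chain as tested, reusable functions, plus the
simulation machinery to calibrate it.

## Worked example

```r
library(regevo)

world <- simulate_world(sim_config(seed = 2026))
cons  <- consensus_all(world)                       # per species: k4, k27, elements
mats  <- conservation_ratio_matrices(world, cons)   # pairwise ratio matrices
fit   <- fit_exponential_decay(decay_points(mats$enhancer, world$tree))
fit
#> exponential decay fit (n = 190): half-life 178 Ma [175-182], mean lifetime 257 Ma, R2 = 0.981
```

The fitted half-life is the time for pairwise enhancer conservation to
halve along the phylogeny. With ongoing element births the apparent decay
is faster than the planted per-lineage loss half-life (300 Ma here), since
recently born elements sit in the alignable denominator;
`experiment_halflife_recovery()` isolates pure loss and recovers the
planted values (promoter 900 Ma, enhancer 300 Ma) without bias.

The numbered scripts under `analysis/` run the whole study and write their
tables under `results/`. On the default seed they print, among other
things:

```
promoter : half-life 505 Ma [488-524], mean lifetime 729 Ma, R2 = 0.943
enhancer : half-life 178 Ma [175-182], mean lifetime 257 Ma, R2 = 0.981
NJ tree vs generating topology: Robinson-Foulds distance 0
954 highly conserved elements (26% of 3679 anchor elements); 65% classed promoter
permutation test: observed 954 vs null 261.2 +- 14.1, p < 1e-04
144 recently evolved elements in human (86% enhancers)
=> 60% of recent elements re-use DNA older than 100 Ma (exaptation)
```

— promoters turn over several-fold slower than enhancers, enhancer
conservation distances alone recapitulate the species tree, and most
recently evolved elements arise by exaptation of ancestral DNA, with the
planted PSG association detected by all three tests.

`run_pipeline()` wraps the same chain behind one seeded YAML/list
configuration with a checksummed, byte-reproducible run manifest.

## Layout

```
R/                  implementation (intervals, tree, simulator, peaks,
                    orthology/conservation, turnover, conserved sets,
                    age/repeats, gene association, regression, pipeline,
                    validation experiments)
analysis/           numbered narrative drivers of the full study
inst/extdata/       20-taxon dated mammal fixture tree (newick)
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/          methods vignette (model, assumptions, design choices)
```
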