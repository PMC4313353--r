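---
title: "Measuring promoter and enhancer turnover across a mammalian phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring promoter and enhancer turnover across a mammalian phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regevo)
```

## The problem

Tissue-active regulatory elements — promoters marked by H3K4me3 (with or
without H3K27ac) and enhancers marked by H3K27ac alone — gain and lose
activity as species diverge. Given replicate ChIP-seq peak calls from the
same tissue in many species, a dated phylogeny, and pairwise whole-genome
alignments, one can ask: how fast does regulatory activity turn over, which
elements are deeply conserved, which are lineage-restricted or entirely
recent, does new activity arise in young DNA or by exaptation of ancestral
DNA, and what predicts an element's conservation?

`regevo` implements that entire analysis chain and, because the real
multi-species ChIP-seq compendium is not required for validating the
statistics, ships a synthetic genome-evolution generator with complete
ground truth, so that every estimator in the chain can be checked for
parameter recovery and calibration.

## The measurement chain

**Consensus elements.** A peak is reproducible when it overlaps a peak from
at least one other biological replicate by ≥ 50% of the shorter peak's
length; reproducible peaks connected by such overlaps are merged
transitively into one consensus region ("50% of their length" is read as
50% of the shorter peak — the symmetric, maximally merging choice, and the
one under which results are insensitive to the threshold). H3K4me3 and
H3K27ac consensus regions overlapping by ≥ 50% merge into dual-marked
promoters; the rest become H3K4me3-only promoters and enhancers. A species
with a single biological replicate can retain all its peaks (the
single-individual path), at the price of more noise in that species'
element set.

**Conservation calls.** Elements are projected through block-wise orthology
maps (an abstraction of EPO/LastZ whole-genome alignments; each map is a
set of paired equal-length, non-overlapping blocks). A projection is
`unique` unless its pieces land on several chromosomes, mix strands, or
leave an internal gap larger than twice the query length — multi-block but
co-linear projections are accepted, since alignment blocks fragment
routinely and discarding every multi-block region would discard nearly
everything. An element is conserved in a target species when its projected
interval is covered ≥ 50% (of the projected interval's length — the
directional reading of the reciprocal-overlap rule) by a consensus region
of one of its own marks. Pairwise values always average the two reciprocal
directions.

**Turnover rates.** Per class, the pairwise conservation ratio (conserved /
uniquely alignable) is regressed on divergence time — the age of the pair's
most recent common ancestor — as `ratio = A·exp(−t/τ)`, fitted by ordinary
least squares on the log scale, the model under which the points sit on a
straight line on a log axis. The amplitude `A` is left free: it absorbs
divergence-independent technical non-conservation (finite detection
sensitivity), so the half-life `τ·ln 2` is estimated from the slope alone.
The 95% CI transforms the t-interval of the slope (n−2 df). Mean lifetime
is `half-life / ln 2`. Neighbor joining on `1 − ratio` distances (via ape,
negative branches clamped to 0) recovers the species topology whenever the
decay is a monotone transform of divergence time, because any monotone
transform of an ultrametric matrix remains ultrametric.

**Conserved, lineage-specific and recent sets.** An anchor element is
*highly conserved* when every species of the high-quality panel shows
enrichment for at least one mark at the orthologous location; classes are
assigned by majority over the observed per-species states, ties breaking to
promoter because dual marking subsumes H3K27ac. The count is compared to a
permutation null that shuffles, per species and per mark independently,
which anchor elements carry that stratum's conserved labels. Under this
null the per-species conserved sets are independent uniform random subsets,
so the null count equals the intersection size of independent random
subsets; the default sampler draws that intersection exactly via iterated
hypergeometric thinning (the literal shuffling is also implemented and
distributionally identical — the sampler makes 10,000-iteration tests and
200-seed calibration studies cheap). P-values use the add-one estimator
`(1+#{null ≥ obs})/(1+N)` and are reported as a `< 1/N` bound when no null
draw reaches the observation. *Lineage-specific* elements are conserved in
all designated high-quality species of a clade and in no species outside
the clade (non-designated clade members neither count nor disqualify;
unalignable species are uninformative). *Recently evolved* elements have no
conserved call anywhere — including elements alignable nowhere, which are
genuinely species-specific DNA.

**Sequence age and repeats.** A recent element's sequence age is the
divergence of the most distant species with a unique projection (0 when
nothing aligns), binned as young (0–40 Ma), mid (40–100 Ma) and ancestral
(≥ 100 Ma). Repeat inclusion requires ≥ 50% of the *repeat's* length
(repeats are short relative to 2-kb elements; the element-length reading
would almost never trigger); enrichment per family and per class is an
upper-tail binomial against the all-elements background with BH correction
within each analysis, and an empty background cell is floored at
`0.5/bg_total` and flagged.

**Gene layer.** Regulatory domains follow the GREAT basal-plus-extension
rule: basal = TSS −5 kb/+1 kb by strand; each side extends to the nearest
gene's basal edge, capped at 1 Mb beyond the basal edge and clipped to the
chromosome. When a neighbour's basal overlaps a gene's own basal the
extension on that side is zero — no midpoint splitting is needed under
this rule. Elements link to every domain they touch by ≥ 1 bp. The
tissue-specificity score is target-tissue expression over the mean of the
other tissues (a dimensionally sensible form under which the 1.5 and RPKM > 10
thresholds make sense; swappable);
liver-specific genes require tsps > 1.5, liver argmax and RPKM > 10, with
missing measurements imputed as 0. PSG association uses three uncorrected
tests: link-level and gene-level hypergeometric tests and a one-sided
Wilcoxon on per-gene recent-enhancer proportions (genes with ≥ 1 enhancer).

**Feature regression.** Conservation ratios are regressed on reproducibility,
intensity, length, TSS distance, GC, constraint fraction and TFBS count by
plain OLS (no logit transform — the response is a bounded ratio, but the linear fit keeps the
variance decomposition interpretable); marginal R² comes from univariate fits
("each feature in isolation"), cumulative R² from left-to-right prefixes,
and feature inter-dependence from pairwise Pearson R².

## The generator

`sim_config()` / `simulate_world()` emulate the study:

* **Tree** — a 20-taxon dated ultrametric mammal tree (depth 180 Ma;
  human–macaque 25 Ma, human–mouse 90 Ma, boreoeutherian split 105 Ma,
  opossum 180 Ma), bundled as `inst/extdata/mammal_tree.nwk`. The fixture tree is a plausible dated topology for these taxa and is
  fully configurable.
* **DNA turnover** — genomes are strings of 3-kb orthologous blocks
  separated by unaligned spacers; blocks are born on branches and lose
  alignability per lineage with a long half-life (1,500 Ma), populating the
  alignable-but-inactive cells of the alignability × conservation plane.
  Young blocks are alignable only within their clade of birth.
* **Activity turnover** — elements are born at the root (1,200 dual
  promoters, 400 H3K4me3-only promoters, 2,400 enhancers by default) and on
  branches (birth rates chosen near steady state), and are lost per lineage
  as a memoryless exponential — the model implicitly assumed by a
  single-exponential fit to pairwise decay. Promoter half-life defaults to
  900 Ma and enhancer half-life to 300 Ma, matching the magnitudes the
  method is meant to recover, with loss inherited by the whole subtree
  below a loss event. Activity requires the underlying DNA to survive;
  alignability and activity are otherwise independent. A configurable
  fraction of births (25% promoters / 35% enhancers) lands in new young
  DNA, the rest exapts ancestral blocks.
* **Measurement noise** — element intensities are log-normal with
  replicate-level multiplicative noise; per-replicate detection is a
  logistic function of log intensity with mean sensitivity 0.92 (a typical
  replicate concordance for strong liver marks), so reproducibility emerges
  from detection rather than being hard-coded; peak boundaries jitter by 8%
  of element length; false-positive peaks arrive at 5% of the true count
  per replicate; a dual promoter displays only one of its marks in a given
  species with probability 0.05. Three replicates per species, except one
  designated single-replicate species (`sei_whale`) exercising the
  single-individual path.
* **Annotations** — repeat families with configurable young-DNA bias,
  constrained elements covering a planted per-element fraction, GC and TFBS
  counts, genes preferentially hosted in root-promoter blocks (promoters at
  TSSs), a 6-tissue log-normal expression matrix with liver-specific,
  other-tissue-specific, ubiquitous and silent genes, and a PSG list whose
  regulatory domains receive recent enhancer births at a configurable
  fold-rate (3× by default).

What the generator does *not* emulate: nucleotide sequence (everything is
interval-based), read-level noise, assembly gaps and fragmented scaffolds,
inter-chromosomal rearrangement (one chromosome per species; split
projections are exercised by constructed maps in the tests), repeat-driven
element birth mechanisms, and correlated loss across neighbouring elements.
Passing tests therefore demonstrate that the estimators recover the
parameters of this generative model under realistic noise — not that the
biological conclusions of any particular data set are correct.

## Validation experiments and numerical choices

The package ships its validation as functions (used by the test suite and
by `scripts/acceptance.R`):

* `experiment_halflife_recovery()` — the ten-species high-quality panel,
  5,000 elements per class, planted half-lives 900/300 Ma. Ongoing births
  and mark switching are disabled in this experiment: it isolates the decay
  process the fit estimates (births contaminate the pairwise denominator
  with young elements; a dual promoter whose H3K4me3 consensus is missed in
  one species would be misclassified there as an enhancer, so the promoter
  cohort is planted as H3K4me3-only, keeping the two cohorts cleanly
  separated). Point estimates are unbiased. A caveat worth knowing: the 45
  pairwise points are clustered — every pair sharing a species shares that
  species' element-loss and detection realizations — so the iid OLS
  t-interval undercovers for the slow-decaying promoter class (its slope
  signal is small relative to the shared-branch variance), while enhancer
  coverage is near nominal. The fitted interval should be read as
  conditional on the realized tree path noise, not as a full sampling
  interval.
* `experiment_phylogeny_recovery()` — NJ on enhancer non-conservation
  distances from the default 20-taxon study recovers the generating
  topology (Robinson–Foulds 0); the no-loss promoter limit (half-life 10⁹
  Ma, no births) yields near-star distance matrices, with the residual
  off-diagonal distance dominated by the single-replicate species.
* `experiment_permutation_calibration()` — 200 null studies, p-values
  uniform (KS) and valid (`P(p ≤ α) ≤ α + 1/(N+1)`).
* `experiment_fdr_calibration()` — 500 null enrichment simulations with 50
  families; realized FDR within 2 standard errors of the BH level; binomial
  p-values agree with an exact log-space summation oracle to 10⁻¹².
* `experiment_truth_recovery()` — the full default study once: recently
  evolved and lineage-specific calls reach precision and recall ≥ 0.9
  against the truth registry, and the young-DNA fraction among recent
  enhancers matches the configured birth placement within sampling error.
* `simulate_psg_fixture()` — a compact gene-level fixture for the PSG
  tests; the planted 3× association is detected by all three tests in well
  over 80% of seeds, and the null is calibrated.

Problem sizes throughout (element counts, seed counts, iteration counts)
are those listed above; they were chosen once as the smallest scales at
which the sampling-error bounds in the tests are meaningful.

Other numerical choices: coordinates are 0-based half-open everywhere;
overlap and merge logic follows base-set semantics (book-ended intervals
coalesce when merging, but have zero overlap); strand is ignored for all
histone-domain overlap logic and used only for TSS/basal orientation;
degenerate inputs error early (zero-length intervals, trees without branch
lengths, single-taxon trees, empty PSG lists, all-zero divergence decay
input), and a constant control vector in the coverage false-negative check
degrades the threshold to the control mean. The control-tail check uses the
sample (n−1) standard deviation.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 2026)
world <- simulate_world(cfg)
cons <- consensus_all(world)
mats <- conservation_ratio_matrices(world, cons)
fit <- fit_exponential_decay(decay_points(mats$enhancer, world$tree))
fit
mean_lifetime(fit$half_life)
```

The numbered scripts under `analysis/` run the complete study — simulation,
consensus, conservation, turnover rates, conserved/recent sets, ages and
repeats, gene association, and the feature regression — writing their
tables under `results/`; `run_pipeline()` wraps the same chain behind one
seeded configuration with a checksummed run manifest.

## Known limitations

* Genome structure is deliberately simple (one chromosome, equal-length
  blocks, one element per block); projection edge cases (multi-chromosome
  splits, strand flips) are exercised by constructed maps rather than by
  the generator.
* The decay-fit CI machinery assumes independent points; see the coverage
  caveat above.
* The tissue-specificity score is one reasonable formalisation of a score
  whose exact published form varies between studies; it is pluggable.
* Element-level conservation uses mark-level consensus sets; alternative
  readings of the 50% rule (against the target peak rather than the
  projection) are monotone-equivalent in the threshold range where results
  are stable, but are not implemented as options.
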