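---
title: "Methods: detecting and modelling degenerative expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and modelling degenerative expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Young supergenes with fully suppressed recombination -- the fire ant
social chromosome's Sb variant being the motivating case -- are expected
to degenerate like Y and W chromosomes.  Before shrinking, however, a
nonrecombining region can *grow*: deleterious insertions fix more easily
than deletions, so repetitive DNA accumulates ("degenerative
expansion").  Demonstrating this requires a chain of analyses that this
package implements end to end:

1. **Optical-style evidence.** Ordered-label maps of a haploid *B*
   (recombining SB) and a haploid *b* (nonrecombining Sb) individual are
   aligned pairwise; large (>= 3 kb) insertions/deletions and unaligned
   "overhangs" quantify where the b genome carries excess sequence.
2. **Enrichment statistics.** Indel counts per chromosome are tested for
   homogeneity against chromosome size, with per-chromosome Pearson
   residual Z-scores and Bonferroni correction; cumulative indel lengths
   and net overhang excess localise the growth to the supergene.
3. **Reference-free corroboration.** Genome sizes of paired B/b samples
   are estimated from 21-mer spectra of unassembled reads; the paired
   percent difference, propagated through the supergene's genome
   fraction, gives an independent expansion estimate.
4. **Cross-species evidence.** Presence/absence of shared indels across
   six individuals (three species, one B and one b each) yields
   neighbour-joining trees: background chromosomes group by species, the
   supergene region groups by variant.
5. **Mechanism.** A forward Wright-Fisher simulation of a nonrecombining
   chromosome under asymmetric insertion/deletion fitness costs
   reproduces the qualitative regimes: expansion, drift plateau, and
   shrinkage.

Every stage can be exercised without external data: the synthetic-data
generators produce genomes, label maps, read sets and indel matrices
with the statistical structure the analyses assume, plus exhaustive
truth tables.

## Coordinates and conventions

All coordinates are 0-based, half-open, in bp; BED-like writers record
this in a header comment.  All generators and simulators accept a
`seed` and are exactly reproducible under it (seeds are applied with
`withr::local_seed`, so user RNG state is never clobbered).

## Synthetic genome pairs

`genome_spec()` / `generate_genome_pair()` produce a reference (B)
genome of uniform random DNA across 16 chromosomes and derive the b
genome by planting indels:

* Insertions land inside the supergene interval with probability
  `insertion_bias` and uniformly by length elsewhere; deletions are
  uniform by length everywhere.  The default bias of 0.32 places about
  a third of insertions on the social chromosome, the level at which
  the published counts sit (55 of 163 on 8.4% of the genome).
* Sizes are log-uniform with a hard floor at the 3 kb optical detection
  threshold (scaled proportionally for miniature genomes).
* Optional tandem-repeat families are planted identically in both
  genomes and inserted DNA is drawn from their units, so the b genome's
  excess is repetitive -- matching the empirical finding that the
  size difference is carried by repeats.
* The truth table is exhaustive: splicing its edits into B reconstructs
  b byte for byte (a tested invariant), and both B- and b-coordinates
  are recorded for every event.

The default full-scale chromosome table (`fire_ant_chromosomes()`)
reproduces the published superscaffolded genome: 350.94 Mb total, a
29.61 Mb social chromosome, and a 20.9 Mb supergene at 7.7--28.6 Mb.
Per-chromosome lengths of chromosomes 1--15 are not individually
published at optical resolution; they are apportioned on a fixed
decreasing profile summing to the published non-social total, which
is all the length-proportional statistics require.  Sequence-level
experiments use `scale < 1` miniatures (typically a few hundred kb per
chromosome) so that everything runs on a laptop; all statistics are
scale-free.

## Label maps, noise model, and alignment

`digest_to_label_map()` labels motif matches (e.g. the 7 bp
`GCTCTTC` nicking site, one label per ~16 kb) or draws a uniform point
process at a given density.  The noise model is the minimal standard
one: Gaussian perturbation of inter-label intervals (default sd 150
bp), independent per-label loss, and Poisson false labels.  Chimeric
molecules and stretch variation are deliberately out of scope.

`align_label_maps()` maximises, by dynamic programming over monotone
non-crossing matchings, the score

```
sum over matched steps [ match_bonus
                         - min(dL^2 / (2 m sigma^2), max_step_cost)
                         - miss_penalty * skipped_labels ]
```

where `dL` is the difference between the two matched inter-label
intervals and `m` the mean number of elementary intervals spanned
(interval noise is additive, so variance scales with `m`).  End gaps
are free, which is what lets unaligned flanks surface as overhangs.

Numerical choices worth recording:

* **Step-cost cap.** A step spanning a large indel would otherwise cost
  thousands of units and truncate the alignment.  Capping the sizing
  term at `max_step_cost = 6` -- just above one `match_bonus = 5` --
  makes an indel crossing cost at most one match plus a unit, so
  matching always resumes beyond an indel, while ordinary sizing noise
  (cost about 1 at two map-sds) is still discriminated.  With the cap
  at several bonuses, maps carrying one planted indel per 4--5 labels
  fragment into per-segment alignments and most calls are lost; the
  reciprocal-consistency experiment is the regression guard.
* **Tie-breaks.** Among equal-scoring predecessors the DP prefers fewer
  skipped labels, then the nearer index; among equal-scoring end cells
  it prefers the longer alignment.  Both are purely for
  reproducibility.
* **Optimality.** The DP score is tested against an independent
  longest-path oracle (igraph Bellman-Ford on the explicit step DAG)
  and, on tiny maps, against exhaustive enumeration of all monotone
  matchings.

`call_indels()` emits one call per matched interval pair with
`|dL| >= 3000` bp; the size is `|dL|` and the position is the flanking
interval on the reference map, because optical resolution cannot place
breakpoints within an interval.  Calls carry coordinates on both maps,
which is what makes reciprocal (swapped-role) recovery testable without
any global coordinate lifting.  `call_overhangs()` records each
unaligned flank; the net per-chromosome excess in b is
`sum(b overhangs) - sum(B overhangs)`.

## Enrichment statistics

Expected counts are proportional to chromosome length in bp (the
homogeneity hypothesis is "distributed according to chromosome size");
a count-proportional expectation sits behind the `expectation`
argument.  The per-chromosome Z-score is the standardised Pearson
residual `(O - E) / sqrt(E)` -- this reproduces the published 11.1 for
55/163 insertions on 29.61/350.94 Mb -- with a one-sided upper-tail
normal p (only enrichment is of interest) Bonferroni-corrected by the
number of chromosomes.  The chi-square statistic is identically
`sum(z^2)`, an invariant tested to 1e-9.

Net overhang excess per chromosome can be negative, so no plain
chi-square on it is defined; the package instead scores each
chromosome's net-per-Mb as a leave-one-out outlier z against the
remaining chromosomes, with one-sided Bonferroni p-values.  This is a
declared design choice: the package makes no claim to reproduce the
published overhang chi-square of 83.25, whose construction is not
specified; the planted-excess experiment shows the substitute flags
exactly the right chromosome.

Expansion percentages are plain arithmetic, kept as exact values and
printed at one decimal: `100 (L_Sb / L_SB - 1)` from lengths;
`mean_pct / supergene_fraction` (default fraction 0.045, the same
transform applied to the CI bounds) from whole-genome size differences,
under the documented assumption that the entire difference lies in the
supergene; `100 excess_bp / supergene_len` from repeat excess.

## K-mer genome sizing

Reads are counted as canonical 21-mers (lexicographic minimum of the
2-bit encoded k-mer and its reverse complement) in compiled code;
k-mers touching non-ACGT bases are skipped and accounted, so histogram
mass conservation is exact.  Because the samples are haploid males the
spectrum has a single coverage peak and the estimator needs no
heterozygosity mixture:

* error cutoff = first local minimum of the spectrum;
* coverage peak = mode above the cutoff, refined by a local mass
  centroid (window of about a quarter of the mode) so the estimate is
  not quantised to integer multiplicities -- without the refinement the
  estimator carries a 2--4% bias at 25x k-mer coverage;
* genome size = above-cutoff k-mer mass / peak;
* repeat fraction = mass above `1.5 * peak` relative to above-cutoff
  mass.  The 1.5 multiplier is a documented, configurable rule for
  separating single-copy from multi-copy mass in a haploid spectrum.

A spectrum with no interior minimum (too little coverage, or error
k-mers merging into the peak) is an explicit error instructing deeper
coverage.  Multiplicities are capped (default 10,000) with overflow
pooled in the top bin.

`paired_comparison()` works on per-pair percent differences
`100 (b - B) / B`: two-sided 95% t interval, one-sided paired t-test
(b > B).  Degenerate all-equal differences collapse the CI to the mean
with p = 0.5 at exactly zero.  Recovery experiments use 20 seeds of a
200 kb genome at 30x, 125 bp reads, 0.1% substitution error -- sizes at
which the estimator's median absolute bias stays under 3% and a full
run takes well under a minute per seed.

Read simulation is uniform-start, substitution-only; that is exactly
what a k-mer spectrum needs, and read-level indels or quality profiles
would add nothing the estimator consumes.

## Indel phylogenetics

Calls are merged into loci by greedy reciprocal 50% interval overlap
(the merging rule is not specified in the source material; reciprocal
overlap is the standard structural-variant convention and the fraction
is configurable).  The published filters are applied verbatim: a locus
is kept only when present in at least two individuals *and* covered in
every individual.  Under these filters absence is informative, so the
default distance is Hamming over presence/absence (Jaccard optional),
and no missing-data handling is needed downstream.

Trees are neighbour joining (the source's tree method is unstated; NJ
is the declared default and is isolated behind `infer_indel_tree`),
with the unique closed-form topology for three samples.  Because no
outgroup exists in-system, grouping is tested as *clans* on the
unrooted tree -- a group separable by removing one edge -- implemented
by rooting at a non-member tip and testing monophyly.  All-zero
distance matrices return a star tree and an indeterminate grouping
rather than an arbitrary one.

The planted-matrix generator gives background loci species-shared
patterns and supergene loci variant-shared patterns (75% carried by the
b class, reflecting insertion accumulation on Sb), with independent
cell flips (default 2%) and missing coverage (default 3%).  Default
locus counts (60 background, 40 supergene) keep within-group distances
well below between-group distances at those noise levels.

## The Wright-Fisher simulator

Each of N haploid individuals carries one nonrecombining chromosome: a
length plus non-overlapping functional-element intervals, each intact
or disrupted.  Per generation, offspring draw parents with probability
proportional to fitness, then mutate: Poisson event counts per
chromosome for insertion, deletion, and optional ectopic large-deletion
channels (a per-bp mode rescaling rates by current length is available
behind a flag, since length-proportional rates change the long-run
dynamics).

* Insertions add neutral DNA only -- the model is repetitive-element
  gain.  An insertion landing strictly inside an intact element
  disrupts it at cost `s_ins` and stretches the element.
* A deletion removes its span; any intact element it touches (fully
  removed or truncated) costs `s_del` once and is marked disrupted.
  Loss of function is not dose-graded: later hits to a disrupted
  element are free, which is what makes the fitness cost of mutations
  disappear as the chromosome degenerates.
* Fitness is multiplicative over incurred costs and maintained
  incrementally; `(1 - s)^k` is verified against log-space
  accumulation.
* Deletion sizes are floored at `length - min_length` (default floor
  1 kb, event logged) and deletion start positions are drawn uniformly
  over positions where the span fits.  Drawing positions this way,
  rather than clipping spans at the chromosome end, removes a subtle
  upward length bias (clipped deletions apply less than their drawn
  size) that would otherwise break the neutral-drift symmetry.
* Bookkeeping is exact: `length == L0 + ins_bp - del_bp` holds for
  every individual at every generation and is checked after every run.

The original simulation's parameter values are not available; the
scenario presets are therefore this package's own calibration of the
three qualitative regimes, and only directions are treated as claims:

* **expansion** (N = 200, T = 2000, L0 = 1 Mb, 200 x 2 kb elements,
  mu = 0.1/0.1 per chromosome per generation, ~5 kb exponential sizes,
  s_del = 0.05 >> s_ins = 0.005): deletions almost always hit an
  element (Ns = 10, effectively barred) while most insertions are
  neutral, so length grows -- roughly mu_ins x P(neutral) x E[size]
  ~ 300 bp per generation at the start.
* **drift** (no elements, all s = 0, symmetric channels): length is a
  martingale; across 50 replicates the mean change sits within 2 SE of
  zero.
* **shrinkage** (drift plus an ectopic channel, rate 0.05 with ~10 kb
  exponential sizes): net loss ~ 500 bp per generation.

The selection machinery is validated against the classical fixation
probability: a single beneficial variant at advantage s fixes with
probability `(1 - exp(-2s)) / (1 - exp(-2Ns))` (about 2s), tested at
s = 0.01 and 0.05 with N = 500.  The degeneration feedback -- growth
rate declining as intact elements are lost, the brake that ends the
expansion phase -- is tested in an accelerated configuration (N = 50,
dense elements, high rates) where element decay completes within 4000
generations and per-epoch growth correlates positively with intact
count.

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* the analyses
assume: length-proportional null placement, supergene-directed
insertion bias, paired genome-size differences concentrated in repeats,
species/variant-structured indel sharing, optical sizing noise.  They
do not emulate real Bionano molecule artifacts (chimeras, stretch
variation, fragile-site breaks), real repeat landscapes (nested,
diverged families), heterozygosity (all samples are haploid), or
inversion breakpoints (inversions are out of scope here).  Passing the
property-based checks therefore demonstrates that the *methods* recover
planted truth under their stated noise models at the published effect
sizes -- not that the original raw-data results are re-derived; those
require the deposited Bionano and Illumina data.

## Problem sizes

Defaults were chosen once so that the full test suite and the
reproduction script each run in minutes on one core: 100 seeds for the
enrichment and grouping rates, 20 seeds x 200 kb x 30x for estimator
recovery, 100 replicate studies for CI coverage, four 600 kb
chromosomes for the optical-map experiments, and 20/50/20 replicates
for the expansion/drift/shrinkage regimes.  All are arguments, and all
statistics are scale-free, so users can rerun any experiment larger.

## Known limitations

* The optical aligner is a minimal semi-global DP, not a consensus
  assembler: no chimeric map splitting, no multi-map scaffolding, no
  inversion detection.
* The overhang outlier test is a pragmatic substitute for an
  unspecified published statistic and should be read as a flagging
  rule, not a calibrated test.
* The k-mer estimator assumes a haploid single-peak spectrum; diploid
  heterozygous samples would need a mixture model it does not have.
* The simulator tracks coordinates, not sequence, and models neither
  recombination restoration nor transposon family dynamics.
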