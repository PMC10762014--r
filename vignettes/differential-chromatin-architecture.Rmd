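---
title: "Differential chromatin architecture analysis with archdelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential chromatin architecture analysis with archdelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archdelta)
```

# Overview

`archdelta` compares chromatin architecture and chromatin-associated signal
between two conditions — canonically a wild type (WT) and a knockout (KO) of
a heterochromatin writer, where loss of H3K9me3 unmasks CTCF binding sites
and perturbs loops. The package implements the full downstream statistical
pipeline over standard text formats (bedGraph, BED, BEDPE, text contact
triples, TSV count tables): binned quantification, differential binding and
expression tests, A/B compartment assignment and switch classification,
directionality-index domains, differential loops and interactions, and
repeat-class enrichment. Upstream read alignment and peak/loop calling are
treated as inputs, not reimplemented.

Because the real datasets this kind of study uses are large and external,
the package ships a fully seeded synthetic-data generator with
machine-readable planted truth. Every stage is validated end to end against
that truth; the `analysis/` scripts in the repository narrate a complete run.

# One-dimensional signal

ChIP signal is quantified as reads per kilobase per million mapped reads
(RPKM) in 100 bp bins, with a matched input track subtracted
(`counts_to_rpkm()`, `input_subtract()`). Input-subtracted values may be
negative and are deliberately never clipped: clipping would bias window
means upward in depleted regions. Window aggregation (`aggregate_to_windows()`)
uses the mean of member bins by default; the sum is available where a count
interpretation is needed.

Mutual exclusivity of two marks (H3K9me3 versus CTCF) is assessed over
fixed windows that contain peaks of both marks in at least one sample
(`cooccupancy_windows()`, 5 kb windows by default). The relationship in the
resulting scatter is summarized by two numbers (`exclusivity_summary()`):
the Pearson correlation of the window means, and the fraction of windows
jointly above each signal's 0.9 quantile (the "double-high fraction").
A strongly negative correlation with a near-zero double-high fraction is
the mutual-exclusivity signature. The scatter itself carries more
information than any scalar; these two were chosen as minimal, reproducible
summaries of its claim.

Methylation calls are pooled per 100 bp window as
`sum(methylated) / sum(coverage)` — the count-weighted ratio, which is
standard practice and robust to uneven per-site coverage — and windows with
fewer than 5 aligned reads are masked (`methylation_windows()`). Row
clustering (`cluster_rows()`) uses k-means with a seeded k-means++
initialization and Lloyd iterations (at most 100), so a seed fully
determines the labels.

# Differential binding and expression

The pairwise comparison of two counts with library-size normalization
(`poisson_pairwise_test()`) is offered in two mathematically distinct
forms:

* **conditional** (default): the exact conditional comparison of two
  Poisson rates. Under the null, conditional on the sum of the two counts,
  the observed count is binomial with success probability
  `total_obs / (total_ref + total_obs)`. This test accounts for sampling
  noise in *both* counts, is conservative only through discreteness, and is
  exactly symmetric under swapping the samples — the property that makes
  increased/decreased calls mirror exactly when the comparison is reversed.
* **rate**: the plug-in form that treats the normalized reference as a
  known Poisson rate `lambda = (count_ref + pseudocount) * total_obs /
  total_ref` and sums Poisson tails. It admits closed forms (for example
  `P(X = 0) = exp(-lambda)`) but ignores reference noise, which inflates
  two-sided type-I error at moderate counts (about 0.14 at a nominal 0.05
  in our null simulations, versus 0.034 for the conditional form). It is
  retained for transparency and comparison; no calling stage uses it.

One-tailed enrichment of a count in one sample is Fisher's exact test on
the 2x2 table (`fisher_increase_test()`), computed as the hypergeometric
upper tail. With library-sized margins this is numerically the conditional
Poisson test's one-sided counterpart; both are exposed in
`call_increased_peaks(method=)` because the source analyses describe the
increased-peak statistic both ways. The default is Fisher.

Multiple testing uses Benjamini-Hochberg (`bh_adjust()`), applied within
each family (peaks, genes, repeats, loops, interactions) and never pooled
across families, matching the per-analysis q thresholds. Increased peaks
are tiered at q < 5e-4 (low), 1e-5 (medium) and 1e-7 (high); tiers are
nested by construction. Dysregulated genes require q < 0.001 and fold
change > 2; individual repeats q < 0.01 and fold change > 2; downregulation
uses the symmetric rule (FC < 1/2). Fold changes are library-normalized
with a pseudocount of 1 on both counts.

Number-matched random controls (`sample_matched_random()`) draw uniformly
without replacement from a feature universe minus an exclusion set,
deterministically under a seed; exclusion matches exact coordinates.

# Compartments

A/B compartments are called at 25 kb. The observed/expected transform
(`observed_expected()`) uses per-chromosome distance means with no
smoothing and the diagonal included — the simplest faithful expected model.
Cells whose whole diagonal is empty are masked. The Pearson correlation
matrix of the O/E rows (masked cells dropped pairwise; computed with masked
cross-products for speed) is eigendecomposed and the three eigenvectors of
largest absolute eigenvalue retained (`correlation_eigenvectors()`), each
of unit norm.

Per chromosome, `assign_compartments()` selects the eigenvector best
correlated (largest |r|, ties to the lowest index) with an accessibility
(ATAC) track on the same grid, flips its sign if the correlation is
negative, and labels bins A (score > epsilon) or B (score < -epsilon).
The sign convention is therefore a gauge fixed by accessibility: a global
sign flip of the eigenvectors cannot change the output. Epsilon defaults
to 0 — no dead zone — because scores near zero are rare on well-structured
maps and a dead zone would silently shrink the classified genome; a
positive epsilon is available for robustness analyses. Each condition is
oriented by its own ATAC track by default (a config can pin one track for
both), since orientation only requires the correlation sign and the
condition's own accessibility is always the self-consistent choice.

Switch classification (`classify_switching()`) maps label pairs to
`A->B`, `B->A` or `unchanged`, with any unclassified member propagating.
Enrichment of a feature bin set in switching bins uses the exact two-tailed
hypergeometric test with the minimum-likelihood two-sided convention (the
sum of the probabilities of all outcomes no more likely than the observed
one) — the standard exact two-sided choice.

# Domains

Contact matrices are balanced with the Knight-Ruiz algorithm
(`kr_balance()`): the inner-outer Newton iteration with conjugate-gradient
solves and the published safeguarding bounds, run to a relative row-sum
tolerance of 1e-6 (at most 3000 outer iterations; zero-marginal bins are
masked first and left zero). The balanced matrix has unmasked row sums
equal to 1; the scaling vector is returned.

The directionality index (`directionality_index()`) contrasts each bin's
upstream (A) and downstream (B) contact sums within a window (default
±2 Mb, i.e. ±80 bins at 25 kb — the window is not fixed by the upstream
literature, so it is a configurable parameter):

DI = sign(B - A) * ((A - E)^2 + (B - E)^2) / E,  with E = (A + B) / 2,

and DI = 0 where A + B = 0. DI scales linearly with a global count scaling
and is mirror-antisymmetric; both properties are tested exactly.

Boundary calling (`call_boundaries()`) is a deliberately simple
deterministic scanner, not the hidden-Markov caller used by the original
domain-calling tools: a boundary is placed at the first bin of every
`DI >= +threshold` run that follows a `DI <= -threshold` run, allowing one
near-zero gap bin between the runs. The default threshold is 0.4 times the
standard deviation of nonzero |DI| per chromosome. On block-TAD maps this
recovers every planted boundary within one bin with no extra calls; on full
maps with compartment structure it also reports compartment-block edges,
which are genuine directionality transitions — consumers who want "TADs
only" should call on compartment-free maps or post-filter. Boundary sets
from several samples are merged within a bin tolerance
(`merge_boundaries()`; merged position is the cluster midpoint rounded
down) with a pairwise conservation table.

# Loops and interactions

Loops called per sample are merged on exactly identical anchor coordinates
(`merge_loops()`), keeping provenance. Counts are rectangle sums of
contact-map cells over the anchor pair (`loop_counts()`). Differential
testing scales each sample's counts to the smallest library
(`scale_to_smallest()`, preserving within-sample proportions exactly) and
applies the two-sided conditional pairwise test; both scaled counts are
rounded to the nearest integer for the test (the least surprising
discretization of real-valued scaled counts, and symmetric). Increased
loops require q < 0.1 and FC > 2; decreased q < 0.1 and FC < 0.5.

Significant interactions at 25/10/5 kb are filtered to q < 0.1 in at least
one sample, then a lower-resolution record is dropped exactly when a
retained higher-resolution record has both anchors fully contained within
it (`merge_interactions_multires()`); partial overlaps keep both. The
differential core is shared with loops, with BH applied within the
interaction family separately.

Anchor classification (`classify_anchor_binding()`) gives precedence to
increased peaks: a loop is `increased` at the anchor level if any increased
peak touches either anchor, else `unchanged` if any peak does, else
`none`. "Falling into" a loop (`features_in_loops()`) means overlapping
the closed span from the start of anchor 1 to the end of anchor 2 by at
least 1 bp; a feature can fall into several loops but each class is
counted once per feature.

# Enrichment

Peak sets are decomposed by repeat class (`repeat_composition()`): each
peak takes the class of its largest-overlap repeat annotation (ties broken
by overlap length, then annotation start), or `unannotated`. The
hypergeometric universe is peak-based: class-positive peaks among all
peaks, tested against class-positive increased peaks. Bootstrap enrichment
(`bootstrap_enrichment()`) compares an observed statistic with draws from a
seeded null sampler; the empirical p uses the add-one formula
`(1 + #extreme) / (1 + n_sim)` with 10,000 draws by default. A
density-smoothed tail was considered and rejected for p-value use because
kernel density p-values are bandwidth-dependent; the retained simulated
vector still supports density plots of the null.

# The synthetic-data generator

`simulate_genome()` plants the full truth; `simulate_tracks()`,
`simulate_contacts()` and `simulate_expression()` emit per-condition data;
`truth_report()` dumps the truth as TSV. Everything is deterministic given
`(config, seed)`.

Defaults (see `sim_config()`) encode the study design at desk scale: two
50 Mb chromosomes; 5,000 CTCF sites of which 200 gain binding 4-fold in the
knockout while their H3K9me3 is divided by the same ratio (coupling
strength 1 scales this exponent); 400 + 400 co-occupied sites where one
mark dominates; 1,000 H3K9me3-only sites; peak heights of 20 (CTCF) and 16
(H3K9me3) counts per 100 bp bin over a background of 0.2, giving
input-RPKM enrichment of realistic magnitude; H3K9me3 intervals are 2 kb
(domain-like) versus 500 bp CTCF sites. Sites occupy distinct 5 kb slots so
no two sites share an aggregation window. 42% of gained peaks sit on
SINE B2 repeat copies (the retrotransposon-borne binding-site scenario) and
10% of other peaks overlap a repeat of any class, so the composition and
enrichment stages see realistic structure. Expression uses log-normal base
rates (median 100 for genes, 30 for repeats) with 60/40 genes and 120/60
repeats planted up/down at 4-fold; 40% of upregulated genes are placed
inside B-to-A switch blocks, emulating direct targets.

Contact maps at 25 kb follow `depth * (d + 1)^-alpha` with `alpha = 1` and
`depth = 60` (about 3.7 million contacts per genome — scaled down from
real experiments but deep enough for stable eigenvectors), modulated by a
compartment checkerboard (20-bin blocks, same-label 1.6x / cross-label
0.6x), 11 TADs per chromosome (within-domain 2.0x, 20 interior boundaries
genome-wide), and 500 loop spikes (20x the local expected rate) at 100 kb
to 1 Mb separations — the range where most CTCF loops live. Counts are
Poisson; an overdispersion knob (gamma-mixed Poisson) exists for robustness
experiments only, matching the Poisson assumption of the differential
tests. The knockout applies 20 planted 10-bin compartment switch blocks
and 3-fold intensity changes at 50 planted loops.

Two consequences of this coupling deserve emphasis. First, a compartment
switch at a loop anchor changes that loop's expected rate by 1.6/0.6 =
2.67x even when the loop itself was not planted as changed;
`loop_expected_ratio()` exposes the exact expected knockout/wild-type rate
ratio per anchor pair so recovery is scored against the rate-model truth,
not just the planted list. Second, planted expression effects shift
library totals, so fold-change estimates under total-count normalization
carry a composition bias exactly as in real count data; the all-null
configuration (`sim_config_null()`) is the right substrate for calibration
checks.

What the generator does **not** emulate: mappability and GC biases,
replicate-level variability beyond Poisson noise, overdispersed biological
variation (unless the knob is turned), sequence content, inter-chromosomal
contacts, and the scale of a mammalian genome. Passing recovery tests on
this data therefore demonstrates the correctness and calibration of the
statistics under their own assumptions — not robustness to every artifact
of real libraries.

# Problem sizes and numerical choices

The validation suite and the acceptance script run the generator at its
default scale (two chromosomes of 2,000 bins at 25 kb; 5,000 peaks; 500
loops) and smaller scales for per-module tests — sizes chosen so a complete
run takes minutes on one core while leaving all recovery margins wide.
Other numerical choices: eigenvector selection ties resolve to the lowest
index; the unclassified band epsilon defaults to 0; KR tolerance 1e-6 with
masked zero-marginal rows; the two-sided exact tests use the
minimum-likelihood convention with a 1e-7 relative tolerance guarding
floating-point ties; empirical p-values use the add-one formula; all seeds
derive from a single user seed via a fixed hash, and every seeded operation
restores the caller's RNG state.

# Known limitations

The boundary caller is not the original hidden-Markov tool and reports all
strong directionality transitions, including compartment edges. The
rate-form pairwise test is anti-conservative by construction and is
provided for comparison only. Interaction "calls" in the simulator are
derived from the planted truth with the pipeline's own Poisson
significance, since upstream interaction callers are out of scope; their q
values exercise the filtering logic but do not model a spline-based
background. Fold-change normalization uses total counts, inheriting
composition bias under asymmetric dysregulation.
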