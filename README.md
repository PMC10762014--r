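# archdelta

Integrative differential chromatin-architecture analysis for
paired-condition epigenomics experiments — the downstream statistics a
study runs after aligning reads and calling peaks and loops, when the
question becomes *what changed between wild type and knockout, and is the
change significant?*

The motivating biology: loss of a heterochromatin writer (e.g. the H3K9
methyltransferase SETDB1) erases H3K9me3 from facultative heterochromatin
and unmasks CTCF binding sites, many carried by SINE B2 retrotransposons.
The architectural consequences — gained CTCF/cohesin peaks, altered
chromatin loops, occasional A/B compartment switches — are read out from
ChIP-seq, RNA-seq, ATAC-seq and Hi-C. `archdelta` implements that entire
read-out as a tested R package over plain-text formats (bedGraph, BED,
BEDPE, text contact triples, TSV), plus a fully seeded synthetic-data
generator with machine-readable planted truth so every stage can be
validated end to end without any external download.

## The statistics at the core

* **Differential binding/expression.** For counts $a$ (reference) and $b$
  (observed) with library totals $T_a, T_b$, the pairwise Poisson
  comparison conditions on $n = a + b$: under the null
  $b \sim \mathrm{Binomial}(n,\ T_b/(T_a+T_b))$, and exact tail sums give
  one- and two-sided p-values (the plug-in rate form
  $\lambda = a\,T_b/T_a$ is also available). One-tailed Fisher's exact
  test on the 2x2 table is the alternative increased-peak statistic.
  Benjamini–Hochberg adjustment within each family; increased CTCF peaks
  tiered at $q <$ 5e-4 / 1e-5 / 1e-7; dysregulated genes at $q < 0.001$,
  repeats at $q < 0.01$, both with fold change $> 2$.
* **Compartments.** Per chromosome at 25 kb: observed/expected by distance
  means, Pearson correlation of O/E rows, first three eigenvectors; the
  one best correlated with ATAC is the compartmentalization score, signed
  so positive = A. Switches are label changes between conditions; switch
  enrichment is an exact two-tailed (minimum-likelihood) hypergeometric
  test.
* **Domains.** Knight–Ruiz balancing (Newton/conjugate-gradient), then the
  directionality index
  $\mathrm{DI} = \mathrm{sign}(B-A)\,[(A-E)^2 + (B-E)^2]/E$ with
  $E = (A+B)/2$ over ±2 Mb, and a deterministic sign-transition boundary
  scanner with per-chromosome adaptive threshold.
* **Loops and interactions.** Exact-anchor merging, rectangle-sum counts,
  scaling to the smallest library, two-sided conditional Poisson test
  ($q < 0.1$, fold change $> 2$ or $< 0.5$); multi-resolution significant
  interactions keep $q < 0.1$ in any sample and drop a coarser record only
  when a finer retained record is completely contained in it.
* **Enrichment.** Largest-overlap repeat-class composition, exact
  hypergeometric tests on the peak universe, and a 10,000-draw bootstrap
  with add-one empirical p-values.

## Worked example

The `analysis/` directory is a numbered, narrated pipeline over one
simulated experiment (seed 1). Stage 02 calls increased CTCF peaks from
the paired tracks:

```sh
$ Rscript analysis/02_differential_binding.R
tier low    (q < 0.0005): 199 peaks
tier medium (q < 1e-05): 191 peaks
tier high   (q < 1e-07): 163 peaks
         set    mark median_log2fc
1: increased    CTCF      1.936435
2: increased H3K9me3     -1.956931
3:    random    CTCF      0.000000
4:    random H3K9me3      0.000000
```

199 of the 5,000 peaks pass the loosest tier (the generator planted 200
four-fold gains), and at those peaks CTCF roughly quadruples
(median log2 fold change 1.94) while H3K9me3 drops four-fold (-1.96);
a number-matched random control changes neither — the reciprocal
gain/loss signature. Stage 03 quantifies mutual exclusivity over 1,000
co-occupied 5 kb windows (Pearson r = -0.92 in both conditions); stage 05
classifies compartment switches (5.05% of bins, all 200 planted switch
bins recovered in the correct direction) and finds up-regulated genes
20-fold enriched in B-to-A bins (p = 7.2e-27); stage 07 calls differential
loops and stage 08 recovers the SINE B2 enrichment at gained peaks
(42% versus 5% genome-wide, bootstrap p = 1e-4).

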