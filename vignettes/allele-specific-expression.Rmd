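---
title: "Estimating single-cell allele-specific expression with scvaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating single-cell allele-specific expression with scvaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scvaf)
```

## The measurement and its assumptions

At a heterozygous single-nucleotide variant (SNV), the expressed variant
allele fraction in one cell is

$$\mathrm{VAF}_{RNA} \;=\; \frac{n_{var}}{n_{var} + n_{ref}}$$

where $n_{var}$ and $n_{ref}$ are counts of *unique mRNA molecules* carrying
the variant and reference base. In droplet 3′ scRNA-seq each read carries a
cell barcode (CB) and a UMI; reads sharing (CB, UMI) at a position are PCR
copies of one captured molecule, so deduplication is what turns read counts
into molecule counts. Three systematic biases dominate this measurement and
the pipeline addresses each explicitly:

1. **PCR amplification bias** — removed by exact-UMI deduplication within
   (cell, locus), keeping the copy with the highest mapping quality.
2. **Allele-mapping bias** — reads whose alignment depends on which allele
   they carry are excluded upstream by a WASP-style remapping filter; the
   aligner records the verdict in the `vW` tag and `count_alleles()` honours
   it (`vW` absent or 1 passes; anything else is dropped).
3. **Sampling stochasticity** — with $n$ informative molecules and true
   allele fraction $p$, the probability of observing a *strictly*
   monoallelic VAF (exactly 0 or 1) is $p^n + (1-p)^n$: 25% at $n=3,p=0.5$,
   6.25% at $n=5$, ≈0.2% at $n=10$. This is why all analyses are carried out
   over a grid of minimum-read thresholds **minR**: only (cell, SNV) pairs
   with $n_{ref}+n_{var} \ge \mathrm{minR}$ yield an estimate, and every
   downstream statistic is reported per minR.

The approach assumes bi-allelic SNVs, one predominant genotype per dataset
(cells from one individual), and RNA evidence only: heterozygosity is
declared from pooled RNA counts, which *by construction* removes loci with
strong non-random monoallelic expression across all cells (they look
homozygous in the pool). Results must be read in the light of this
selection; a genotype-backed mode (`skip_count_rule`) bypasses it when DNA
genotypes exist.

## Pipeline stages and their parameters

**Cell QC** (`qc_cells`). A cell passes with ≥ 3000 detected genes and ≤ 6%
mitochondrial counts. Both are computed on *raw* counts: detection and a
within-cell fraction need no normalisation, which is why the
normalisation/scaling step common in expression workflows is deliberately
omitted here. Whether the 6% rule should use normalised totals is genuinely
ambiguous in the field; raw totals are the choice documented and tested.
Mitochondrial genes are matched by the name prefix `MT-` by default, or an
explicit list.

**Allele counting** (`count_alleles`). Pileup at each SNV position over a
coordinate-sorted CB/UB-tagged SAM/BAM. Defaults `min_base_qual = 20` and
`min_map_qual = 30` are common practice, exposed in the config rather than
asserted as inherited values — the upstream tooling this stage mirrors does
not publish its internal cutoffs. "High-quality reads" in the
heterozygosity rule below means exactly the reads surviving these filters.
A base call of N counts toward `n_other` (it is coverage without allelic
information); deletions, reference skips and clipped-over positions
contribute nothing. `n_other` never enters the VAF denominator.

**UMI dedup** (`dedup_umis`). Grouping is by *exact* UMI string; no
edit-distance collapsing. Error-correcting UMI networks belong upstream;
within a locus, exact grouping is the conservative, reproducible choice.
Within a group the read with the highest MAPQ wins; ties break by
(alignment position, query name) in C-locale lexicographic order, which
makes counting invariant to input record order.

**Heterozygosity selection** (`select_het_snvs`). An SNV is retained iff
pooled counts give ≥ 50 unique molecules for *each* allele, QUAL > 100,
MQ > 60, QD > 2, FS = 0.000, and its annotation category is not repetitive
or intergenic. The operators mirror the stated selection verbatim: "at
least 50" is inclusive, the quality gates are strict inequalities, and the
FS equality is tested within 1e-9 (FS is a Phred-scaled value printed to
three decimals; exact floating equality would be brittle). Gates evaluate
in the fixed order counts → qual → mq → qd → fs → annotation and the audit
table records the first failure; a missing required field rejects with
`missing_field` at its gate rather than passing silently.

**VAF analysis** (`estimate_vaf`, `summarize_snv`, `classify_pattern`).
Per-cell calls partition into strictly monoallelic (VAF exactly 0 or 1,
decided on the integer counts — never a float comparison), predominantly
monoallelic (VAF ≤ 0.2 or ≥ 0.8, inclusive of strict) and bi-allelic
(0.2 < VAF < 0.8). The bi-allelic interval is *open*: where a summary
phrase like "0.2–0.8" conflicts with the inequality form, the inequality
wins, so boundary values count as predominantly monoallelic. Predominant +
bi-allelic fractions partition each SNV's cells and must sum to 1 (a tested
invariant, tolerance 1e-12).

Per-SNV statistics need ≥ 10 cells (`min_cells_stats`); a pattern call
needs ≥ 50 (`min_cells_pattern`). The 10-cell rule applies per minR
independently — the qualifying locus set differs by threshold, so each
threshold's summary stands on its own. Classification:

* **RME** iff the bi-allelic cell fraction is < 0.05. The rule fires for
  any locus whose cells each express one allele — including constitutively
  monoallelic loci; with RNA-only evidence the two are distinguishable only
  through the cell-level mixture, so strictly monoallelic simulation truth
  is *expected* to be RME-labelled.
* else **skewed** iff the rarer exclusively-expressed allele appears in
  < 10% of cells *and* the bi-allelic fraction is < 0.80. The prose origin
  of this rule is ambiguous about conjunction; both conditions are ANDed
  here, with RME given precedence, and the operationalisation is fixed in
  code and tests.
* else **bi-allelic**.

**Gene level** (`aggregate_gene`, `compare_intronic`). Genes aggregate
member SNVs per minR: intronic vs non-intronic group means of the
bi-allelic fraction, a concordance score (max pairwise absolute difference
of bi-allelic fractions, 0 for singletons), and a majority-vote pattern
(ties → `discordant`; non-classifiable members do not vote). The intronic
comparison pools *cell-level measurements* into a 2×2 table (bi-allelic vs
not) × (intronic vs not) and applies Pearson's chi-square without
continuity correction. The exact contingency construction behind the
original genome-wide comparison is under-specified; measurement-level
pooling was chosen because it weighs each VAF estimate equally and is the
construction the analytic depth argument (below) predicts for. An empty
group returns `applicable = FALSE` rather than a statistic.

**Histograms** (`vaf_histogram`). Twelve bins at width 0.1: point masses
{0} and {1} flanking (0,0.1], …, (0.9,1), so strict monoallelic mass is
never diluted into the interior bins.

## What the simulator emulates — and what it does not

`simulate_dataset()` writes the four pipeline inputs (tagged SAM, VCF,
annotation TSV, MatrixMarket gene matrix) plus truth tables, from one seed;
identical seeds give byte-identical files. It emulates the *statistical*
structure the pipeline is sensitive to:

* 14 nt cell barcodes, 10 nt UMIs, 150 nt single-end reads — the barcode
  geometry and read length of the emulated platform generation;
* per-(cell, SNV) molecule depths from a fixed / Poisson / negative-binomial
  model (the real per-cell-per-SNV depth law is unpublished; the model is a
  stand-in, not a claim — hence it is a config knob, with Poisson a
  reasonable null for 3′ capture at moderate expression);
* allelic classes per locus: symmetric (beta-)binomial at $p=0.5$, skewed
  at $p = 0.9$ by default (side coined per locus), RME as a fair coin per
  cell (all-ref or all-alt — the "random" in RME), strict monoallelic at
  $p \in \{0,1\}$;
* PCR duplicates as extra records sharing (CB, UB, position),
  `1 + Poisson(rate)` copies per molecule;
* WASP-failing reads as extra `vW:i:2` records with fresh UMIs, so the
  truth table remains exact whether or not the tag is honoured (honouring
  reproduces truth; ignoring strictly inflates counts);
* engineered QC failures: cells at ~1/5–5/6 of the detected-gene threshold,
  and cells at ~12% mitochondrial counts, disjoint sets recorded in truth;
* engineered VCF-gate failures (QUAL 50, MQ 55, QD 1, FS 6.5 versus passing
  200 / 60.5 / 3 / 0).

Deliberately **not** emulated: transcript structure and splicing-aware
alignment (reads are un-clipped, exact-match CIGAR, spaced so no read spans
two SNVs — isolating counting logic from alignment artifacts), paired-end
records (only the genome-aligned mate reaches these stages in the real
protocol), sequencing error beyond an optional uniform base flip at the SNV
(default 0), UMI sequencing errors, ambient RNA, doublets. A green test
against this generator therefore establishes the correctness of counting,
filtering and classification logic — not robustness to alignment artifacts
or chemistry noise, which the WASP/quality knobs only partially proxy.

Intronic SNVs get a depth multiplier (`intron_depth_scale` < 1) with the
*same* true $p = 0.5$; at minR = 3 the truncated low-depth sampling alone
then depresses the bi-allelic proportion of intronic measurements, which is
exactly the confound the intron/exon comparison must be read against.

## Numerical and engineering choices

* Deterministic everything: one seed drives the generator; SAM records sort
  by (contig, position, read name); TSV/JSON writers are byte-stable; the
  run manifest omits timestamps by default (`manifest_timestamps = TRUE`
  restores them) because re-run byte-identity is a tested invariant and a
  timestamp would break it.
* The pipeline's "second counting pass" (restricted to selected SNVs and
  QC-passing cells) is a pure subset of the whitelist-restricted counts
  table: counting is independent per locus and per cell, so re-pileup over
  the restricted inputs would reproduce the identical rows.
* Config files are JSON (one section per stage, defaults filled in); R has
  no YAML parser in the supported dependency set, and jsonlite round-trips
  the nested structure losslessly.
* Degenerate inputs: zero-cell/zero-SNV simulation configs are rejected;
  empty count tables flow through `pool_counts`/`estimate_vaf`/
  `summarize_snv` as empty tables with stable schemas; a zero-count cell
  has mitochondrial percentage 0 and fails on detected genes; contigs
  missing from the alignment header are an error, not a silent zero.
* Multi-allelic or non-SNV VCF records are dropped with a warning at parse
  time; the analysis is defined for bi-allelic substitutions.
* CLI exit codes: 0 ok, 2 configuration error, 3 data error — classed
  conditions (`scvaf_config_error`, `scvaf_data_error`) internally.

## Known limitations

* RNA-only heterozygosity cannot see loci that are silent or strongly
  monoallelic in the pool; imprinted genes are systematically excluded.
* Exact-UMI grouping over-counts molecules when UMIs contain sequencing
  errors (no network collapse) and under-counts on UMI collisions; both
  effects are negligible at the simulated depths but real at high depth.
* The chi-square measurement-level pooling treats cells as independent
  across SNVs of the same gene, which overstates the effective sample size
  when many SNVs share cells; the test is used directionally.
* Pattern recovery degrades near the decision boundaries (e.g. a skewed
  locus at depth 10 has ≈7% bi-allelic mass, close to the 5% RME cut), so
  the ≥95% recovery criterion is a property of the stated simulation
  scales, not of arbitrary configurations.
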