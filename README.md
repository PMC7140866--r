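# scvaf

Single-cell allele-specific expression from barcoded, UMI-tagged RNA-seq
alignments.

## What it does, and for whom

Droplet-based 3′ scRNA-seq (10x-style) tags every read with a cell barcode
(CB) and a unique molecular identifier (UMI). At a heterozygous SNV this makes
it possible to count, per cell, the unique mRNA molecules carrying the
reference and the variant base, and from them the **expressed variant allele
fraction**

    VAF_RNA = n_var / (n_var + n_ref)

where `n_var` and `n_ref` are deduplicated molecule counts. `scvaf` is for
analysts who have such alignments (plus a candidate-SNV VCF, an SNV annotation
table and a gene-by-cell count matrix) and want per-cell VAF_RNA estimates and
per-SNV / per-gene allelic-pattern calls — bi-allelic, skewed, random
monoallelic (RME), strictly monoallelic — without re-implementing the
counting, filtering and classification plumbing each time.

The central tuning knob is **minR**: the minimum number of unique informative
reads (n_ref + n_var) a (cell, SNV) pair needs before a VAF_RNA estimate is
made. Low minR admits many loci but inflates monoallelic calls through
sampling stochasticity (at depth n and true allele fraction p the expected
strictly monoallelic fraction is `p^n + (1-p)^n`, i.e. 25% at n = 3 and p =
0.5); high minR is confident but sparse. `scvaf` computes everything across a
minR grid (default 3, 5, 10) so the trade-off is visible, and classifies each
SNV observed in enough cells:

* **RME** — fewer than 5% of cells with 0.2 < VAF_RNA < 0.8;
* **skewed** — under 10% of cells exclusively expressing the rarer allele and
  under 80% of cells bi-allelic;
* **bi-allelic** — otherwise.

Per-cell calls use the open interval (0.2, 0.8) for bi-allelic expression;
VAF_RNA of exactly 0 or 1 (decided on the integer counts) is strictly
monoallelic, and ≤ 0.2 / ≥ 0.8 predominantly monoallelic.

Because the pipeline stages are format-level reimplementations, a seeded
synthetic-data generator with complete ground truth (`simulate_dataset()`)
ships as a first-class module: every stage is tested against truth tables,
and analytic binomial oracles back the classification thresholds.

## Worked example

```r
library(scvaf)

cfg <- sim_config(seed = 1, n_cells = 150, n_genes = 10, snvs_per_gene = 2,
                  depth_model = list(kind = "poisson", lambda = 8),
                  class_fractions = c(symmetric = 0.7, RME = 0.2, skewed = 0.1),
                  pcr_duplication_rate = 2, fraction_intronic_snvs = 0.4,
                  intron_depth_scale = 0.5,
                  n_bad_cells_low_genes = 4, n_bad_cells_high_mito = 2)
tr <- simulate_dataset(cfg, "demo")
#> scvaf synthetic truth: 150 cells, 20 SNVs, 2990 (cell,SNV) pairs, 62858 reads

qc <- qc_cells(read_counts_mtx(tr$paths$matrix_dir))
sum(qc$pass_qc)                                   # 144 of 150 cells pass

snvs   <- read_snv_vcf(tr$paths$vcf, annotation = tr$paths$annotation)
counts <- count_alleles(tr$paths$alignment, snvs,
                        barcode_whitelist = qc$barcode[qc$pass_qc])
sel    <- select_het_snvs(snvs, pool_counts(counts))   # 20/20 retained here
counts <- counts[snv_id %in% sel$retained$snv_id]

for (mr in c(3, 5, 10)) print(allelic_fractions(estimate_vaf(counts, mr)))
```

The allelic composition of all per-cell measurements shifts with minR exactly
as expected from sampling at low depth — monoallelic calls melt away as the
required depth grows:

| minR | estimates | % strict mono | % predom mono | % bi-allelic |
|-----:|----------:|--------------:|--------------:|-------------:|
|    3 |      2676 |          31.2 |          39.8 |         60.2 |
|    5 |      2213 |          25.6 |          36.0 |         64.0 |
|   10 |       619 |          15.8 |          25.2 |         74.8 |

(The % predominantly monoallelic column includes the strict calls, and each
row's predominant + bi-allelic percentages sum to 100.)

Per-SNV summaries and pattern calls at minR = 3 recover the simulated
classes:

```r
s3 <- summarize_snv(estimate_vaf(counts, 3),
                    classification_config(min_cells_pattern = 50))
s3[1:4, .(snv_id, n_cells, mean_vaf, frac_biallelic, pattern)]
#>             snv_id n_cells  mean_vaf frac_biallelic   pattern
#> 1: GENE001_300_A_C      99 0.5454545      0.0000000       RME
#> 2: GENE001_600_C_A     142 0.5001658      0.8591549 biallelic
#> 3: GENE002_300_G_A     141 0.4680851      0.0000000       RME
#> 4: GENE002_600_T_C     142 0.4890662      0.8521127 biallelic
table(s3$pattern)
#> biallelic       RME    skewed
#>        13         6         1
```

Intronic SNVs — simulated here at half the read depth but the same true
allele fraction 0.5 — show a lower bi-allelic proportion at minR = 3 (0.171
vs 0.713; chi-square 535.0, p < 1e-100), reproducing the depth-driven deficit
of bi-allelic calls in intronic sequence:

```r
compare_intronic(estimate_vaf(counts, 3), snvs[, .(snv_id, category)])
```

The whole workflow is also available as one call / one command:

```r
run_pipeline(list(seed = 1, simulate = list(n_cells = 150)), out = "run1")
```

```sh
Rscript inst/cli/scvaf.R run --config cfg.json --out run1 --seed 1
# subcommands: simulate | qc | count | select-snvs | vaf | report | run
```

Re-running with the same config and seed reproduces the output tree
byte-for-byte.

## Layout

* `R/` — simulator, allele counter (pileup + UMI dedup), SNV selector, cell
  QC, VAF analysis/classification, pipeline driver, CLI.
* `vignettes/allele-specific-expression.Rmd` — model, assumptions, parameter
  rationale, limitations.
* `tests/testthat/` — unit, property and acceptance suites (fixtures built in
  code).
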