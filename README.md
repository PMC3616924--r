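# forumdomains

Analysis toolkit for genome-wide maps of **blunt-ended DNA double-strand
breaks (DSBs)** obtained by terminus-capture sequencing, written for
genomicists studying non-random chromosome fragmentation, fragile sites and
domain-level gene regulation.

In this assay, DNA flanking a spontaneous blunt DSB is ligated to a
biotinylated adaptor, cut at the nearest Sau3A (GATC) restriction site,
amplified and sequenced. Each mapped read therefore spans a **forum-domain
terminus (FT)** — an interval bounded by the DSB on one side and a Sau3A
site on the other, typically 50–300 bp. Recurrently broken positions show
up as FT built from several overlapping reads (DSB *hot spots*), and the
long protected stretches between consecutive hot spots are **forum
domains** (mostly tens to hundreds of kb). The package implements the full
downstream analysis of such data:

- **Read clean-up** — positional adaptor/primer trimming (a primer counts
  only within 5 bp of a read end) and the ≥18 bp length filter.
- **FT calling** — maximal union of overlapping mapped reads per
  chromosome, with per-FT read counts, distinct cut positions and
  hot-spot flags (`read_count ≥ min_support`).
- **Domain segmentation** — forum domains as the gaps between consecutive
  boundary FT, with size statistics and midpoint-rule gene content.
- **Profiles** — FT density in sliding windows (default 500 kb window,
  100 kb step; WIG export) and read-subsampling saturation curves.
- **Region enrichment** — Monte-Carlo test of FT excess in a query region
  (null: observed FT lengths and count re-placed uniformly on the
  chromosome, 10,000 replicates by default), backed by the analytic
  binomial tail P(X ≥ k), X ~ Bin(n, region/chrom), for depths beyond
  Monte-Carlo resolution.
- **Domain expression** — per-domain median expression, activity
  classification against the chromosome mean, silent-fraction tables, and
  the **circular-shift test** of within-domain co-expression: the observed
  statistic D = mean within-domain variance of gene expression is compared
  with the distribution of D under random circular rotations of the gene
  expression vector along each chromosome, giving the one-sided p-value
  `p = (1 + #{D_null ≤ D_obs}) / (1 + reps)`.
- **Synthetic data** — a generator that emulates the entire experiment
  (log-normal hot-spot spacing, Sau3A point process, cut-to-site read
  construction with adaptor decoration, ~30% active domains with
  coordinated expression), so every stage is testable without downloads.

## Worked example

```r
library(forumdomains)

cfg <- sim_config(chrom_lengths = c(chr1 = 5e6),
                  hotspot_spacing_median = 5e4, seed = 7)
sim  <- simulate_genome(cfg)
raft <- simulate_raft_reads(sim$genome, sim$truth, cfg)

reads <- data.frame(chrom = raft$alignments$chrom,
                    start = raft$alignments$start,
                    end   = raft$alignments$end,
                    cut_side = ifelse(raft$alignments$strand == "+",
                                      "left", "right"))
ft <- classify_hotspots(call_ft(reads), min_support = 2)
#> classify_hotspots: 73/93 FT flagged (min_support=2)

domains <- segment_domains(ft, cfg$chrom_lengths)
domain_size_stats(domains)$median
#> [1] 51795.5

expr <- simulate_expression(sim$truth, cfg)
circular_shift_test(expr, domains, reps = 10000, seed = 11)
#> Circular-shift test of within-domain expression coordination
#>   genes: 211 in 55 multi-gene domains; statistic: variance
#>   observed D = 0.2772; null mean = 0.5994 (10000 shifts)
#>   one-sided p-value = 0.0001

mc_enrichment(ft[ft$chrom == "chr1", ], region = c(1e6, 1.5e6),
              chrom_length = 5e6, reps = 10000, seed = 11)
#> FT enrichment: region [1,000,000, 1,500,000) on a 5,000,000 bp chromosome
#>   observed FT in region: 9 of 93
#>   Monte-Carlo p (reps=10000, seed=11): 0.595
#>   analytic binomial tail: 0.592
```

Reading the output: 696 simulated reads collapse into 93 FT, 73 of them
supported by ≥2 overlapping reads (hot spots). The protected domains
between hot spots have a median size close to the planted 50 kb spacing.
Genes inside the same domain vary far less than rotated null arrangements
(D = 0.28 vs null mean 0.60), so the coordination p-value sits at the
Monte-Carlo floor 1/(reps + 1) ≈ 1e-4. The queried 500 kb region holds no
FT excess (p ≈ 0.6 by both routes).

`run_pipeline(pipeline_config(...))` chains all stages (simulate → trim →
callft → domains → density → saturate → enrich → express → coexpress) and
writes FASTA/BED/GFF/WIG/TSV/JSON artifacts with seed- and
parameter-stamped headers.

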