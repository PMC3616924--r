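---
title: "Methods: mapping DSB hot spots and forum-domain expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping DSB hot spots and forum-domain expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forumdomains)
```

## The experiment this package models

Spontaneous blunt double-strand breaks (DSBs) in genomic DNA can be
captured by ligating a biotinylated adaptor to the blunt end, cutting at
the nearest Sau3A (GATC) restriction site, and sequencing the captured
fragment. Each mapped read is therefore an interval with a sharply defined
biological meaning at each end: one end *is* the break, the other is a
restriction site. We call the merged footprint of overlapping reads a
forum-domain terminus (FT). Since GATC occurs roughly every 4^4 = 256 bp
in random sequence, FT are typically 50–300 bp. Positions broken
recurrently across the cell population accumulate several overlapping
reads; we flag FT with `read_count >= min_support` (default 2) as DSB hot
spots. The DNA between consecutive hot spots — a forum domain — is
protected from breakage and, in the data this package was built around,
tends to behave as a unit of transcription: a minority of domains
(about 30%) contain actively, coordinately expressed genes while the rest
are silent or low.

The pipeline stages are deliberately small and composable: trimming and
length filtering; interval merging into FT; segmentation into domains;
windowed density and saturation profiles; a Monte-Carlo region-enrichment
test; and per-domain expression summaries with a circular-shift
coordination test. `run_pipeline()` chains them with per-stage seeds
derived from one master seed by a stable string hash, so adding a stage
never perturbs another stage's random stream.

## Read clean-up

Adaptor/primer trimming implements a positional rule: a primer (or its
reverse complement) is recognised at a read end only if it starts within
`max_offset = 5` bp of that end; on recognition the primer and everything
outside it are removed, at both ends independently. Matching is exact by
default (`max_mismatches = 0`): the rule is positional, and on 454-style
data the dominant failure mode is a displaced adaptor rather than a
substituted one; a mismatch budget is exposed for other chemistries. After
trimming, reads shorter than 18 bp are dropped — below that length a match
to a masked human genome is not meaningful.

## FT calling and the cut-side convention

Mapped reads are merged per chromosome into maximal unions of overlapping
intervals (IRanges reduce); `min_gap = 0` means strict overlap — abutting
reads that share no base stay separate, since nothing ties their breaks
together. Reads from both strands merge into the same FT: fragments flank
a break from either side. Each FT records the number of merged reads, the
distinct cut coordinates among them, and their span; the cut coordinate of
a read is taken from its `cut_side`, inferred from strand under the
documented default convention (`+` alignments carry the DSB at the left,
5'-most coordinate). The convention is configurable in
`load_alignments()` because deposited interval files may encode the
construct orientation the other way round.

Hot-spot status is a plain threshold on read support, with unflagged
single-read FT retained: they are real observations, just not evidence of
recurrence, and the threshold is a parameter precisely because deposited
datasets may have used none.

## Segmentation and gene content

Domains are the gaps between consecutive boundary FT — by default
hot-spot-flagged FT, since single-read FT boundaries would shatter the
domain structure sequencing depth happens to touch. The FT intervals
themselves are excluded (domains are the protected DNA *between* breaks),
terminal chromosome segments are emitted unbounded, and size statistics
use bounded domains only, because terminal segments are censored by the
chromosome end rather than delimited by breaks. Genes are assigned to the
domain containing their interval midpoint: every gene counts exactly once
and boundary-straddling genes go to the side holding more of them.

## Density, saturation

FT density uses sliding windows (defaults 500 kb window, 100 kb step) and
counts an FT in a window when its midpoint falls inside — with
overlapping windows an overlap criterion would multiply-count FT
straddling window edges. WIG export anchors each value at
`window_start + 1` with `span = step`, keeping spans disjoint as the
format requires.

The saturation analysis subsamples reads without replacement on a
schedule (1% steps from 100% to 70%, then 5% steps to 10%), re-calls FT,
and reports the percentage of full-data FT overlapped by any subsample
FT. Recovery is computed over all FT rather than hot spots only; that is
the conservative choice, since single-read FT are the first to vanish
under subsampling. A deep library shows a plateau near 100% over the
90–100% read range; a library still discovering FT at full depth rises
steeply instead.

## Region enrichment

The Monte-Carlo null for "are there more FT in this region than chance"
keeps what the data determine — the number of FT on the chromosome and
their lengths — and randomises what the null hypothesis says is free:
their positions, uniform on `[0, chrom_length − length]`, overlaps
permitted. Nothing in the null constrains inter-FT spacing, because the
question is about occurrence in a region, not about spacing. A synthetic
FT scores on ≥1 bp intersection with the region (a flank extension is
available for "close to the gene" queries). The p-value carries the +1
pseudocount, so 10,000 replicates can never report 0; alongside it we
report the analytic binomial tail P(X ≥ k), X ~ Bin(n, region/chrom),
computed by `pbinom(..., lower.tail = FALSE)` which is accurate in deep
tails far beyond Monte-Carlo resolution (claims like p < 1e-7 are
meaningful only through this route). The analytic form treats FT as
points; with FT of ~100 bp on multi-Mb chromosomes the approximation
error is negligible, and the test suite checks the two routes against
each other within Monte-Carlo standard error.

## Expression and the circular-shift test

Per-gene expression is the median of the gene's exon signals (mean of
middles for even counts), log2(x+1)-transformed by default. A domain's
expression is the median over its genes; a domain is *active* when that
median exceeds the chromosome average, defined as the arithmetic mean of
per-domain medians over gene-bearing domains. Gene-less domains are
classed low-or-silent and excluded from the average — they carry no
expression information and would otherwise drag the reference down. Note
that this mean-threshold classification undercounts weakly active
domains by construction (an active domain whose effect sits below the
chromosome mean is classed silent), so with 30% of domains planted
active the recovered active fraction sits slightly below 30%; the test
suite asserts a band rather than a tight interval for exactly this
reason.

The coordination test asks whether genes sharing a domain are more alike
than their chromosomal arrangement predicts. The statistic D is the mean,
over domains with at least two genes, of the within-domain variance of
gene values (a mean-absolute-deviation-from-median variant is available
for heavy-tailed data). The null rotates each chromosome's ordered vector
of gene values by a random offset in gene-rank space while the gene→domain
membership pattern stays fixed: rotation preserves the value
multiset and the serial autocorrelation of expression along the
chromosome — the two nuisance structures that would otherwise masquerade
as coordination — while destroying the alignment between values and
domain boundaries. Offsets are drawn uniformly from the n−1 *nonzero*
rotations; the identity rotation is not a draw from the null, and the +1
pseudocount already accounts for the observed arrangement. (Had the
identity been included, the attainable p-value would floor at about
1/n_genes no matter how many replicates are run.) The test is one-sided —
coordination means *small* D — with
`p = (1 + #{D_null ≤ D_obs})/(1 + reps)`. For small single-chromosome
problems `exact = TRUE` enumerates all n rotations, identity included,
and reports `#{D_rot ≤ D_obs}/n`; this mode is the reference the
Monte-Carlo mode is tested against.

## The synthetic-data generator

The generator exists so that every stage has ground truth. Its defaults
describe the system the package models:

| parameter | default | meaning |
|---|---|---|
| `hotspot_spacing_median` | 110,000 bp | median inter-hot-spot gap; gaps are log-normal |
| `hotspot_spacing_logsd` | 1.1 | log-scale gap SD; reproduces a ~1 kb–3 Mb size range around a ~110 kb median |
| `sau3a_spacing_mean` | 256 bp | GATC spacing expected in random sequence (4^4) |
| `read_min_len`/`read_max_len` | 50 / 300 bp | typical captured-fragment bounds; longer fragments truncate at 300 bp from the cut |
| `reads_per_hotspot_mean` | 10 | breaks sampled per hot spot (Poisson) |
| `cut_jitter_sd` | 15 bp | spread of cut positions within a hot spot, matching cut clusters confined to a few tens of bp |
| `background_break_rate` | 5e-7 /bp | sporadic non-recurrent breaks |
| `frac_active_domains` | 0.30 | fraction of domains with an active expression baseline |
| `domain_effect_sd` | 2 (log2) | half-normal SD of the active-domain effect |
| `gene_noise_sd` | 0.5 (log2) | per-gene noise around the domain baseline |

Sau3A sites are a geometric point process by default — what matters
downstream is spacing, not sequence — with a sequence-backed mode
(`simulate_genome(cfg, sequence = TRUE)`) that derives sites from GATC
occurrences in generated sequence when read sequences must be
genome-consistent (the trimming tests use it). Each break emits up to two
fragments, one per side, each captured with probability 0.5: per-side
recovery is not identifiable from published data, and 0.5 encodes
indifference. Fragments longer than `read_max_len` truncate from the cut
end, because sequencing starts at the ligated biotinylated end; truncated
reads carry no Sau3A adaptor. Sub-18 bp fragments are still emitted — the
length filter belongs to the pipeline under test, not to the simulator.
Silent domains sit at baseline 0 on the log2(signal+1) scale, i.e. at the
floor of the transform; active baselines are half-normal draws, so
activity is always an elevation.

What the generator does *not* emulate: sequencing errors and homopolymer
artifacts, PCR duplicates, multi-mapping in repetitive sequence, copy
number variation, and any correlation between breakage and transcription
beyond the planted domain structure. Tests passing on synthetic data
therefore validate the *computational* contracts — merging, segmentation,
null distributions, recovery — not robustness to platform noise.

## Numerical and reproducibility choices

Coordinates are 0-based half-open internally, converted at the BED
(0-based) / GFF and WIG (1-based) boundaries. Medians use R's
mean-of-middles rule. All Monte-Carlo machinery runs on R's default
Mersenne-Twister generator; every randomised function takes an explicit
seed, records it in its result, and restores the caller's RNG state.
Per-stage seeds derive from the master seed via a 31-bit string hash of
the stage name. Degenerate inputs have defined behaviour: chromosomes
shorter than twice the spacing median get no hot spots (with a warning),
empty read sets give empty FT tables, chromosomes without FT segment into
one unbounded domain, a region covering its whole chromosome gives p = 1,
and the coordination test refuses data without any multi-gene domain
rather than returning a vacuous p-value.

The statistical checks in the test suite run at desk scale by design:
simulated chromosomes of 1.5–12 Mb with 25–50 kb hot-spot spacing
(hundreds to thousands of inter-hot-spot gaps aggregated across 20 seeds
for recovery checks), 10,000 shifts for the coordination power check, 200
simulated null datasets at 199 shifts each for calibration, and 1e5
replicates for the Monte-Carlo/analytic cross-check. These sizes give the
binomial and Monte-Carlo intervals quoted in the tests their intended
coverage while keeping a full run in the low minutes.

## Known limitations

Single-read FT are indistinguishable from artifacts without replication;
the hot-spot threshold is a blunt instrument compared to a local
background model, which is out of scope. Domain segmentation admits no
nesting or hierarchy. The enrichment null ignores chromosome-scale
heterogeneity in breakability (mappability, chromatin): its p-values are
exact for the stated null, which is itself a simplification. The
circular-shift test conditions on gene order and domain membership;
chromosomes with very few genes contribute little and a chromosome with
one gene is rotation-invariant. None of the expression machinery corrects
for gene length, GC, or batch structure — inputs are assumed normalised.
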