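---
title: "Windowed methylome comparison: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed methylome comparison: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why:
the statistical model behind each stage, the tunable parameters and their
defaults, the choices we made where more than one defensible design
exists, and what the synthetic-data tests do and do not establish about
real data.

## The data model

The unit of observation is a cytosine call: a chromosome position, the
reference nucleotide (`C` on the forward strand, `G` on the reverse), the
sequence context (CG, CHG or CHH, with H ∈ {A, C, T}), and read counts
from which the methylation level is defined as

$$\ell = \frac{\text{methylated reads}}{\text{total reads}} \in [0, 1].$$

CGmap is the canonical on-disk form: eight tab-separated columns (chrom,
C/G, 1-based position, context, dinucleotide, level, methylated count,
total count). Printed levels in real files are rounded, so the parser
*reconciles* the level with the exact count ratio and rejects records
whose printed level deviates by more than printing can explain (0.005 for
two-decimal output). After parsing, `level == meth/total` holds exactly.
All call-level coordinates are 1-based inclusive; the shift to 0-based
half-open happens once, at BED emission.

Converters accept Bismark CX reports, BSMAP `methratio.py` output and
METHimpute tables, always recomputing levels from counts and dropping
zero-coverage records (their level is undefined). Two lossy corners are
documented rather than papered over: `methratio`'s effective CT count is
a float and is rounded to the nearest integer for the total (the
methylated count is capped at the total if rounding inverts the order),
and METHimpute does not record the local dinucleotide, so non-CG sites
receive the placeholder `CN`.

## Window matrices

Chromosomes are tiled into fixed, non-overlapping windows anchored at
position 1; the terminal partial window is kept and filtered like any
other. The eligibility filter has three parameters:

| parameter       | default | meaning                                        |
|-----------------|---------|------------------------------------------------|
| `window_bp`     | 500 bp  | window width                                   |
| `min_cytosines` | 4       | context cytosines required per window          |
| `min_depth`     | 4 reads | coverage required of each contributing cytosine|

The filter must hold **in every sample**. This makes the retained window
set identical across samples, which is what lets one matrix feed PCA,
clustering and DMR testing without per-sample missingness. The defaults
follow common practice for plant WGBS at moderate depth; sparse designs
(RRBS, low coverage) usually need wider windows or a lower site count.

Two deliberate choices at this stage:

* **Cell value = unweighted mean of per-cytosine levels**, not pooled
  counts. Pooling counts would weight deep sites more; the unweighted
  mean treats each cytosine as one observation of the region's state.
* **Cytosines on both strands count as separate sites.** CGmap records
  are per-strand, and symmetric-CpG merging is a modelling step we do not
  take; a CpG covered on both strands therefore contributes two sites.

## Differential methylation

For each eligible window, Δ is the experimental-group mean minus the
control-group mean of the cell values (the control group is whichever is
listed first in the sample sheet). The significance test compares two
observation vectors with one of Welch/Student *t*, Kolmogorov–Smirnov, or
Mann–Whitney U, two-sided. A window is a DMR when

$$|\Delta| \ge \texttt{min\_delta} \quad\text{and}\quad p < \alpha,$$

with defaults `min_delta = 0.10` and `alpha = 0.05` on raw p-values.

**Observation unit.** By default the observations are the per-cytosine
levels *pooled across a group's replicates* (replicate × site
observations). This was a genuinely open choice; we pooled because
(a) 1-vs-1 designs are legitimate in this field and replicate-level tests
are impossible there, and (b) the ≥ 4-site window minimum then guarantees
enough observations for the rank and distribution tests to be meaningful.
The cost is that sites within a window are treated as independent, which
understates within-window correlation; users with many replicates can
switch to `mode = "replicate_means"` to test per-replicate window means
instead.

**Test variant.** "t test" is Welch (unequal variance) by default —
methylation variance differs strongly between near-0/near-1 and
intermediate windows — with `var_equal = TRUE` available for the pooled
form.

**Multiplicity.** The DMR definition thresholds raw p-values; no
correction is applied by default. `adjust = TRUE` reports
Benjamini–Hochberg q-values alongside, without changing the emitted set,
so users can filter on them downstream.

**Conventions for degenerate windows.** Two groups with zero variance and
equal means get p = 1 (never a DMR); zero variance with different means is
treated as perfect separation (p = 0); windows where a test cannot be
computed (too few observations) are skipped and counted, never treated as
significant. Adjacent significant windows are **not** merged: a DMR here
is one fixed window, which keeps counts comparable across parameter
settings.

**Small-sample behaviour of the tests.** The exact Mann–Whitney and KS
tests have discrete statistics, so at small per-window observation counts
their achievable significance levels sit below the nominal α — the KS
test especially is conservative below roughly 50 observations per group,
and read-count ties push all rank-based tests further in the conservative
direction. The type-I calibration test therefore uses windows with 20
sites × 3 replicates per group (60 observations) and continuous per-site
levels, a regime where all three tests hold their nominal level; with the
default 4-site windows, users should expect fewer false positives than α
suggests, not more.

## Genes, features and enrichment

The GTF is collapsed to one model per `gene_id` (union of exons/CDS over
transcripts; gene body = min-start to max-end span, introns included).
When explicit UTR rows are absent, UTRs are derived as exon-minus-CDS
split by which side of the CDS span they fall on, strand-aware. Eight
interval sets make up the catalog: promoter (the `promoter_bp` = 2000 bp
immediately upstream of the TSS, clipped to the chromosome), gene body,
exon, intron, 5′UTR, CDS, 3′UTR, and IGR. The features are independent
merged sets, not a partition — with overlapping genes a base can be one
gene's intron and another's exon — but gene body and IGR partition the
genome exactly, which the tests verify base by base.

**IGR includes promoters.** The intergenic set is the complement of
merged gene bodies only. Carving promoters out of IGR is a defensible
alternative; we kept promoters inside IGR because the two features are
reported side by side and an IGR excluding promoters would change meaning
as `promoter_bp` changes.

A gene is a DMG when at least one DMR overlaps (≥ 1 bp) its gene body or
its promoter; the record notes which, and a gene may be in both classes.

Enrichment per feature is
$\log_2(\mathrm{RG}/\mathrm{LR}) - \log_2(\mathrm{LF}/\mathrm{LG})$, all
four symbols lengths in bp: RG the overlap of the merged DMR footprint
with the feature, LR the DMR footprint, LF the feature length, LG the
genome length. The score is 0 when DMR composition matches genome
composition and is invariant under uniform genome rescaling. Features
with no DMR overlap get −∞, rendered as a capped bar and kept as −∞ in
the table. An optional coverage mask recomputes all four lengths inside a
supplied interval set before scoring, for assays (e.g. RRBS) where only
part of the genome is assayable.

## Summaries and profiles

* **PCA**: samples are observations, windows variables; columns are
  mean-centered but **not** variance-scaled, because levels share the
  [0, 1] scale and scaling would inflate near-constant windows. PCA is
  skipped below 3 samples (two points always separate trivially).
* **Variable regions / heatmap**: windows with across-sample spread
  (max − min) ≥ 0.20 by default; hierarchical clustering uses Euclidean
  distance with average linkage for both rows and columns (neither is
  canonical in this field; both are configurable in code). Row and column
  orders are emitted as text so the clustering is testable without
  parsing a figure.
* **Genome tracks**: large windows (default 1 Mb) retained when they hold
  ≥ 4 context cytosines per sample, with no depth filter — at this scale
  the cytosine-count condition is the binding one.
* **Metagene**: gene bodies rescaled to 20 proportional bins, each 2-kb
  flank cut into 20 × 100-bp bins. Per bin: mean over a gene's eligible
  cytosines (depth ≥ `min_depth`), then mean over genes (genes without
  data in a bin skip that bin), then mean over a group's samples.
  Minus-strand genes are mirrored exactly, so upstream is always left;
  the mirroring is tested to machine precision against a flipped
  plus-strand computation. Genes shorter than the body bin count are
  skipped and counted.

Every figure has a TSV twin; figure generation never alters a computed
number.

## The synthetic-data generator

`simulate_dataset()` emulates a two-group study at read-count resolution:
sites are scattered per context at plant-like densities (CG 0.04, CHG
0.03, CHH 0.08 per bp), true levels start from context baselines (CG
0.19, CHG 0.10, CHH 0.05 — wild-type-plant-like values), optionally
shifted genome-wide per group, inside implanted DMR windows, or by a
gene-body/flank spatial profile; read depth is overdispersed negative
binomial (mean 10, size 5, floored at 1) so the depth filter actually
removes sites; methylated counts are binomial in the true level. Effects
are clipped to [0, 1] and the ground-truth table records both the nominal
and the realized (post-clipping) per-window effect. The reference
configuration is a 2 × 100-kb genome with 10 genes and 3 vs 3 samples;
all randomness derives from a mandatory seed, and identical seeds give
byte-identical files.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: sequence-driven site spacing and CpG
islands, bisulfite conversion error, strand-symmetric CpG correlation,
spatial autocorrelation of methylation beyond the implanted patterns,
batch effects, and mapping artefacts. The tests establish that the
machinery is correct (filters, arithmetic, test statistics, interval
algebra, determinism), not that the defaults are optimal for any
particular organism.

## Test problem sizes

The suite verifies windowing against a brute-force reimplementation on
twenty 10-kb single-chromosome genomes with 2–6 samples; test p-values
against closed-form Welch/Student formulas and exhaustive enumeration
oracles for KS and Mann–Whitney; type-I error on 2,000 null windows;
recovery of 50 implanted hypo-DMRs (effect −0.4, depth ≈ 10, 3 vs 3) with
recall ≥ 0.9 and no hyper calls; the feature partition per base on a
100-kb genome; and end-to-end determinism of two full pipeline runs on a
seeded 2 × 50-kb study. `scripts/acceptance.R` re-runs the headline
computations on fresh seeded simulations and writes the resulting numbers
as JSON.

## Known limitations

* Exactly two groups; no covariates, no paired designs.
* Fixed windows only — no HMM/beta-binomial segmentation and no merging
  of adjacent significant windows (a deliberate non-goal; dedicated
  segmentation callers exist for that).
* Pooled-site testing ignores within-window site correlation (see above).
* GFF3 is not parsed; convert to GTF first.
* Chromosome lengths are approximated by the maximum observed coordinate
  when no sizes file is given; supply `chrom.sizes` for exact terminal
  windows and IGR lengths.
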