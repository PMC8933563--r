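---
title: "Methods: prioritizing developmentally licensed stimulus-responsive CREs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing developmentally licensed stimulus-responsive CREs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creLicense)
```

# The model

T-cell effector genes are frequently controlled by enhancers that only open
after antigen-receptor stimulation, yet the DNA demethylation that permits
their activity happens much earlier, during thymic development. creLicense
operationalizes that "licensing" hypothesis as a four-criterion conjunction
over a shared gene universe (genes passing a low-count filter):

| criterion | evidence | gate |
|---|---|---|
| `upregulated` | normalized RNA-seq counts, base → target stage | log2FC > 1 (strict) |
| `hmc_any` | CMS-IP vs input coverage over the gene body | log2 ratio > 2 (strict), in DP **or** CD4SP |
| `dev_cre` | ATAC peak ∩ H3K27Ac peak, DP or CD4SP | ≥ 1 bp overlap; assigned to gene |
| `novel_th0` | Th0 ATAC peak with no developmental ATAC overlap | assigned to gene |

`licensed = upregulated ∧ hmc_any ∧ dev_cre ∧ novel_th0`. A gene set is
also computed for `changed` (|log2FC| > 1, both directions) to define the
head of the cascade summary.

Assumptions worth stating explicitly: counts are raw non-negative integers
from a bulk RNA-seq quantification; stages are encoded in sample names
(`<stage>_<replicate>`); peak and coverage files share one genome build
with the gene table; and all coordinates are BED-convention 0-based
half-open, because every consumed format (BED, bedGraph) already is.
1-based dialects are out of scope.

# Expression gating

Counts are filtered (a gene is dropped only when *every* sample is strictly
below `min_count = 10`), normalized by median-of-ratios size factors, and
gated on a pseudocounted stage-mean fold change:

$$\mathrm{log2FC}_g = \log_2 \frac{\bar{x}_{g,\mathrm{target}} + c}{\bar{x}_{g,\mathrm{base}} + c}, \qquad c = 1.$$

The gate is deliberately a fold-change criterion, not a count-model Wald
test: the cascade definition is stated purely as "fold change > 2", and
re-deriving negative-binomial dispersion shrinkage would add machinery
without changing the gate. For users who want a p-value column,
`stage_welch_test()` provides a two-sided Welch t-test on log-normalized
values; it is labelled as such and is **not** equivalent to a
dispersion-shrunk count-model test, and the pipeline does not gate on it.
Whether the original 6719-gene "changed" list also used a significance
cutoff is not documented; this package gates on fold change only.

Size factors follow the standard median-of-ratios estimator with the median
taken in log space (for an even number of usable genes this takes the
geometric mean of the two middle ratios, matching the reference
implementation). One property deserves a precise statement: scaling a
single column by $c$ multiplies that column's factor *relative to every
other column's* by exactly $c$. The absolute factors all shift together by
$c^{-1/m}$ ($m$ samples), because each gene's geometric mean absorbs
$c^{1/m}$; the tests assert the exact ratio form rather than the loose
absolute form, and do not assert that factors have unit geometric mean
(median-of-ratios does not guarantee it).

# 5hmC scoring

Each gene body is scored as the log2 ratio of coverage-weighted sums,

$$S = \sum_{\text{segments}} v \times \mathrm{bp\ overlap\ with\ body},
\qquad \mathrm{score} = \log_2 \frac{S_\mathrm{IP} + 1}{S_\mathrm{input} + 1}.$$

"Intragenic" means the gene body only — no promoter flank is added, since
5hmC is depleted at TSSs and the criterion of interest is gene-body
enrichment. The ratio of sums is invariant to segmentation granularity and
to track length, and with pseudocount 0 it is invariant to jointly
rescaling both tracks; the pseudocount of 1 on both sums keeps every score
finite (an all-zero gene scores exactly 0). A per-bp mean mode
(`mode = "mean"`) is available; with matched IP and input segmentation it
gives the same ranking. The exact statistic used by upstream CMS-IP
processing pipelines varies; this ratio-of-sums with pseudocount is the
package's explicit, documented choice.

# Peak-to-gene assignment and novelty

`assign_peak()` algorithmizes a curation rule: a peak belongs to a gene if
it overlaps the gene body (category `gene_body`), otherwise to the gene
with the smallest TSS distance provided that distance is strictly below
`max_tss_dist = 10000` bp. Distances are measured from the nearest peak
edge to the TSS — the rule "< 10 kb from the TSS" names no anchor, and edge
distance is the conservative, convention-free reading; a midpoint anchor is
available (`anchor = "midpoint"`). Determinism choices: ties in TSS
distance break by lexicographically smallest `gene_id`; a peak spanning
several gene bodies links to the overlapped gene with the nearest TSS
(single assignment keeps Venn counts well defined); `upstream` /
`downstream` is strand-aware (upstream = 5′ of the TSS on the gene's
strand), and a peak straddling the TSS without touching the body is
classed `upstream` (promoter-proximal).

A developmental CRE candidate is an ATAC peak with ≥ `min_overlap_bp = 1`
bp of H3K27Ac overlap; the ATAC peak is the positional anchor and its
coordinates are retained, H3K27Ac serving only as activity evidence. A
Th0 peak is *novel* when it has no qualifying overlap with any DP or CD4SP
ATAC peak. The original analysis established novelty by manual curation;
the binary overlap rule is this package's algorithmization, with `min_bp`
and an optional reciprocal-overlap-fraction mode (`min_frac`) as knobs.
Requiring H3K27Ac at the novel Th0 peaks as well is not part of the rule
here (the evidence consumed is accessibility); users can intersect
`novel_th0_peaks()` with a Th0 H3K27Ac set themselves if they want that
stricter variant.

All gates are strict at their boundaries: log2FC of exactly 1, a 5hmC score
of exactly 2 and a TSS distance of exactly 10000 bp are all excluded. The
tests pin each boundary.

# Cascade summary and enrichment

`venn_summary()` reports the nested counts — changed; 5hmC-positive among
changed; upregulated-and-5hmC (the cascade universe); developmental-CRE and
novel-peak counts within it; licensed — with each percentage
`round(100 * child / parent, 1)` (`NA` when the parent is empty). Two
published-figure quirks are worth knowing when comparing against the
original report: the 409-of-6719 ratio is 6.1% although 10.8% was printed
alongside it (the package reports the raw ratio), and the upregulated ∧
5hmC universe is quoted there both as 333 and as 350 in adjacent analyses;
this package has a single definition (`upregulated ∧ hmc_any`), so
`n_positive_correlation` and `n_upregulated_hmc` are the same number, and
both fields are kept for the summary contract.

"Positive correlation with increased expression and presence of 5hmC" is
operationalized as set membership (upregulated ∧ hmc_any); no per-gene
correlation coefficient is computed because none is defined by the cascade.

Enrichment is an in-package upper-tail hypergeometric test per term with
Benjamini–Hochberg correction, replacing an external web service so runs
are self-contained and deterministic. Term annotations are a user-supplied
two-column TSV (`term_id`, `gene_id`); term gene lists are intersected with
the universe before testing, terms with zero query overlap are dropped
before BH (so the correction's m counts reported terms — standard
enrichment-report behaviour), and results sort by p-value with term-id
tie-breaks. No term-redundancy clustering is attempted.

# The synthetic generator

`generate_synthetic_bundle()` writes a toy genome in exactly the formats
the pipeline reads. Defaults (chosen once, as the study conditions the
validation runs under): 100 genes on 2 chromosomes, bodies 5–15 kb,
intergenic gaps 25–35 kb, stages DN3/DP/CD4SP with 3 replicates, base mean
50 counts (null genes 30), planted log2FC = 3 from base to target for
upregulated classes (ample margin over the >1 gate), planted 5hmC
enrichment of 3 log2 units (weaker state 2.5, and 25% of positive genes
carry the stronger mark in DP to emulate early demethylation), 100-bp
bedGraph bins, 400-bp developmental peaks mid-body with offset H3K27Ac,
350-bp Th0-novel peaks planted 3 kb from the TSS. Class fractions: 10%
licensed, 5% per partial class (`no_novel_peak`, `no_dev_cre`, `no_hmc`,
`not_upregulated`), remainder null. `no_dev_cre` genes deliberately get an
ATAC peak *without* H3K27Ac, so the intersection requirement itself is
exercised; Th0 inherits a copy of every developmental ATAC peak (activated
cells keep developmental accessibility) plus the planted novel peaks.

Noise knobs: `count_noise` draws counts from a negative binomial
(dispersion 0.05) instead of the exact class means; `peak_jitter` shifts
each planted locus uniformly by up to ±j bp. Jitter is applied per locus —
the ATAC peak, its H3K27Ac partner and the Th0 copy share one offset — so
that jitter bounded by the construction slack (validated in
`synthetic_config()`: half the minimum body minus the peak width, and
10 kb minus the novel-peak offset and width) can never flip a planted
truth label. The 3-kb novel-peak placement against the 10-kb rule is that
slack by design.

What the generator does *not* emulate: realistic genomic sequence (GC,
mappability), overlapping or nested genes, replicate-specific library
artifacts, peak-caller noise, or read-level data. Passing the recovery
tests therefore shows the integration logic is correct — every planted
criterion is detected by exactly the stage that targets it, and the
licensed set equals truth with noise off — not that thresholds are optimal
for any particular real dataset.

# Numerical and degenerate-input choices

- All writers use fixed (non-scientific) number formatting, and reruns on
  identical config and inputs are byte-identical; the run log stores an
  MD5 of the effective config and the cascade counts, never timestamps.
- Parsers raise on violated invariants (negative coordinates, end ≤ start,
  overlapping bedGraph segments, negative counts or values, duplicate gene
  ids, unknown strands) naming the offending line or gene; nothing is
  silently clamped.
- bedGraph gaps are signal 0; explicit zero segments are not required.
- `percentage(child, 0)` is `NA`; an empty gene index or universe is an
  error; a zero-length gene body is an error.
- Size-factor estimation fails loudly when no gene is expressed in all
  samples.

# Test problem sizes

The suite validates the interval engine against a brute-force all-pairs
oracle on 1000 random intervals × 50 probes, the hypergeometric tail
against exhaustive enumeration for every (K, n, k) with N ≤ 12, and the
end-to-end cascade on 100-gene bundles (noise-free, jittered, and
NB-noised), sizes at which the whole suite runs in under a minute while
exercising every code path.

# Limitations

The pipeline consumes peaks and coverage as given — no peak calling,
alignment or read processing. Gating is marginal per criterion; no joint
model, no significance testing on the fold change, and no
dosage/directionality of the novel peak's effect. Single-assignment
peak-to-gene links ignore long-range regulation: a licensed enhancer acting
over > 10 kb, or on a non-nearest gene, is invisible by construction.
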