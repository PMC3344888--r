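---
title: "fiveDGE: models and methods for 5'-end tag quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fiveDGE: models and methods for 5'-end tag quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiveDGE)
```

## The measurement model

5'-end digital gene expression (5'-DGE) sequences a single 25 bp tag from
the 5' end of each captured mRNA molecule. Template switching during
reverse transcription appends an adaptor carrying an engineered EcoP15I
recognition site (CAGCAG) at the position corresponding to the mRNA 5' end;
EcoP15I, a type III enzyme cutting 25/27 nt downstream of its site, then
releases exactly 25 bp of cDNA with a 2-nt 5' overhang. Because sequencing
starts from the adaptor distal to the mRNA 5' end, the read runs
*antisense* to the transcript. Each sequenced tag therefore represents one
transcript molecule, and a gene's molar abundance is estimated without any
transcript-length normalization as tags per million:

$$\mathrm{TPM}_g = \frac{c_g}{N_{\mathrm{mapped}}} \times 10^6,$$

where $c_g$ is the (possibly fractional) tag count of gene $g$ and
$N_{\mathrm{mapped}}$ the number of genome-mapped tags in the library.

The package implements the complete computational side of this assay:
an in-silico library simulator with recorded ground truth, SOLiD
color-space read handling and mapping, fractional tag counting over
extended gene regions, QC metrics, and the downstream time-course
statistics. All randomness is seeded; seeded runs are byte-reproducible.

## Color space and mapping

SOLiD reads are strings of di-base *colors*: coding A/C/G/T as 0–3, the
color of a transition is the XOR of the two base codes, which reproduces
the canonical matrix (identical pair → 0; A↔C, G↔T → 1; A↔G, C↔T → 2;
A↔T, C↔G → 3). Colors are complement-invariant, so the color string of a
reverse complement is the reversed color string — minus-strand alignment
reduces to matching the reversed read colors against the forward reference
colors.

Scaffolds are concatenated into a single reference with 60 `N`s after each
segment (`concatenateReference()`); `N` has no color, so windows touching
a spacer can never match and cross-scaffold alignments are impossible by
construction.

`mapColorReads()` reports **all** locations on either strand with at most
2 color mismatches among the 24 informative colors of a 25 bp tag. The
first color crosses the synthetic primer base; it is excluded from
mismatch counting by default (`skipFirstColor`), as in corona-era
pipelines, and the flag is exposed. The search is seed-and-verify: the
informative colors are cut into three blocks of eight; with at most two
mismatches at least one block is exact (pigeonhole), so an exact 8-mer
index over the reference color string enumerates every candidate, each of
which is verified color by color. The unit tests assert exact equivalence
with a brute-force full scan on small genomes. Reads with three or fewer
non-0 colors (any homopolymer gives a run of 0s) are removed beforehand by
`filterLowInformation()`; filtering precedes mapping because its purpose
is to prevent spurious mappings.

No correction of adjacent color pairs (two-color error decoding) is
attempted: mismatches are counted in color space as-is.

## Tag accumulation and counting

`accumulateTags()` adds each read into a strand-resolved, genome-length
array of floating-point weights. A unique best hit contributes 1.0; a read
with $n$ equally-best hits contributes $1/n$ to each (the two strands
count as distinct positions, so cross-strand ties share the split). Total
array weight therefore equals the number of reads retained — an invariant
checked to $10^{-6}$ in the tests. A `unique` mode discards multi-hit
reads entirely, for quantifying how repeat-fed genes collapse without
fractional assignment.

A tag occupies 25 positions but is recorded in **one** cell: by default
the genomic position of the transcript's 5'-most base of the tag
(`positionMode = "tss"`), i.e. the right end of a plus-strand-mapped tag
and the left end of a minus-strand-mapped tag, since tag reads run
antisense to their transcript. This puts the 5'-peak exactly on the
transcription start site. The alternative (`"start"`, the leftmost mapped
base) is a flag because either convention is defensible; only the peak's
apparent position differs.

`countRegions()` sums cells over a gene's region. The default
`"antisense"` convention counts a gene on strand $s$ from tags mapped to
strand $-s$; `"sense"` and `"both"` are available. Internally all ranges
are Bioconductor `GRanges` (1-based, closed); external formats keep their
native conventions (GFF3 1-based, BED/bedGraph and hit TSVs 0-based
half-open, declared in each file's header comment).

## Extended gene regions

Gene models frequently lack UTR annotation, so tags are counted over an
extended region per gene: 2 kb beyond the 5' end and 1 kb beyond the 3'
end when the distance $d$ to the nearest same-strand neighbor exceeds
3 kb. For $d \le 3000$ the gap is split 1:2 — $\lfloor d/3 \rfloor$ to the
upstream gene's 3' side, the remainder to the downstream gene's 5' side —
so the regions abut without overlapping. The orientation of the split is
forced by continuity: at $d = 3000$ it coincides with the full 1 kb/2 kb
caps. Flooring the 3' share makes the shares sum exactly to $d$. 5'/3'
are transcription-oriented (on the minus strand the 5' extension grows
the genomic end); extensions clip at scaffold boundaries; opposite-strand
neighbors are ignored, which can make opposite-strand regions overlap —
harmless, because counting is strand-resolved. Nested or overlapping
same-strand input models are rejected rather than guessed at. The
distance is measured between gene-model boundaries, not extended
boundaries, and $d = 3000$ takes the split branch (the outcome is
identical either way; fixing it makes the rule deterministic).

## The library simulator

`makeToyGenome()` builds random A/C/G/T scaffolds (at least 10 kb) with
non-overlapping, stranded, optionally multi-exon gene models and known
gaps; `assignExpressionProfiles()` lays a time-course truth over them; and
`simulateTags()` emits color-space reads:

* per-gene tag counts are Poisson with mean `depth * TPM / 1e6`;
* a fraction `tssPeakWeight` (default 0.6) of a gene's tags sit exactly on
  its annotated 5' end; the rest spread over exonic positions with an
  exponential decay in transcript coordinates (`decayScale`, default
  500 bp) — emulating a sharp TSS peak over a background of truncated
  mRNAs and premature template-switch products. The observed fraction of
  real tags outside annotated transcripts conflates annotation gaps with
  truncation, so both the mixture weight and the decay shape are modeling
  choices, not measured values;
* reads are emitted antisense to the transcript strand and encoded in
  color space with a uniform per-color error rate;
* optionally, candidate positions within a window 3' of reverse EcoP15I
  sites (CTGCTG) are down-weighted by a constant factor before sampling,
  emulating digestion-induced depletion (default off);
* `digestEcoP15I()` models the cut geometry itself: 25 bp tags, 2-nt
  overhangs, sites with under 27 bp of downstream sequence dropped.

Library chemistry (template switching, adaptors, PCR) is abstracted: only
its observable consequences reach the mapper. Not simulated: tags
spanning splice junctions, realistic quality values, and poly-A-induced
homopolymer reads (available only as an explicit fixture via
`homopolymerReads`, to exercise the low-information filter).

Expression truth is defined in TPM (relative) space. Every time-point
column sums to $10^6$ and null genes are *exactly* flat: the mass that
planted patterns add at their peak is balanced by a column factor applied
to the regulated gene set only. TPM being compositional, this is the one
way to satisfy both properties at once; its cost is that the realized
peak-to-trough fold of pattern genes is somewhat below the nominal
`effectSize` (for the default 4, realized folds span roughly 2–4). The
planted baseline is log-normal (median ≈ 20 TPM, sdlog 1.2), mimicking
the skewed abundance distribution of real tag libraries.

`simulateCountMatrix()` draws replicate Poisson counts directly from a
truth — the count distribution the pipeline would produce for uniquely
mapped tags — and is used for the statistical calibration studies where
read-level detail is irrelevant.

## Time-course statistics

The analysis order is fixed: per-gene median normalization → logarithmic
conversion → Welch one-way ANOVA across time points → Benjamini–Hochberg
FDR at 5%. `normalizePerGene()` divides by the per-gene median over all
samples (mean of the central order statistics for even counts) and
excludes zero-median genes with a report; it is scale-invariant. The log
uses a pseudo-value of 0.01 on the median-normalized scale — two decades
below the median, so zeros stay finite while values near 1 are
essentially untouched; the assay's detection limit discussion centers on
1 TPM, and on that scale 0.01 is far below any quantifiable signal.

"Parametric ANOVA not assuming equal variance" is realized as Welch's
heteroscedastic F test with Welch–Satterthwaite degrees of freedom
(`stats::oneway.test`). A caveat the package's own calibration tests
quantify: with only 3 replicates per time point the Welch approximation
is anticonservative (empirical type-I error near 7% at nominal 5% in a
6×3 Gaussian null), and BH inherits that inflation, so the realized FDR
sits slightly above the nominal level under these conditions. With more
replicates the calibration tightens; users needing strict control at
triplicate depth should treat the 5% FDR as approximate. Degenerate rows
(all values equal) return $F = 0$, $p = 1$ with a flag; rows where a
zero-variance group makes the statistic undefined return `NA` with the
flag.

Significant genes' profiles — median-normalized, logged, averaged over
replicates per time point — are clustered on a 3×3 self-organizing map.
The SOM hyperparameters of the original desktop software are unpublished,
so the package fixes its own: 2000 online iterations, learning rate 0.5
decaying linearly to 0.01, Gaussian neighborhood with radius
`max(shape)/2` decaying to 0.5, codebooks initialized deterministically
on a grid spanned by the first two principal components (seeded random
initialization as a fallback), best-matching unit by Euclidean distance
with ties to the lowest node index. Planted-pattern recovery is scored
with the adjusted Rand index. Gene and condition trees use 1 − Spearman
rank correlation with average linkage (`stats::hclust`); constant items
(undefined rank correlation) are dropped with a warning, and trees export
to Newick.

## QC metrics

* `ecop15iBiasProfile()` accumulates tag weight (both strands) at offsets
  within ±100 bp of every exact CAGCAG and CTGCTG occurrence; offset 0 is
  the site's first base as written on the forward strand, so "3' of the
  reverse site" is the negative-offset flank.
  `estimateSiteSuppression()` reports the ratio of flank mean to window
  mean.
* `replicateCorrelation()` computes squared Pearson correlation of two
  samples over genes at ≥ 1 TPM in both, on log10 scale by default
  (replicate scatter spans decades and is judged log–log; the linear
  scale is a flag). Genes below the threshold in either sample are
  excluded.
* `lengthVsTpm()` sorts genes by summed exon length (gene id as the tie
  break, so bins are deterministic) into bins of 1000 and reports
  five-number TPM summaries; a trailing partial bin is kept and flagged.
* `stochasticErrorTpm()` gives the Monte-Carlo sampling error of a TPM
  estimate: at 1 TPM and 16 million tags the count is Poisson(16), hence
  ≈ 25% relative error.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on simulated
data at deliberately desk-sized scales: toy genomes of 20 kb–1 Mb, 10–200
genes, libraries of $10^4$–$10^6$ tags, calibration studies of 1500–5000
genes over 6 time points × 3 replicates, 3–10 Monte-Carlo seeds per
study. These sizes give stable statistics (e.g. the end-to-end
truth-recovery correlation is ≥ 0.999 at 1 Mb/10⁶ tags) while keeping a
full run in minutes. Fractional accumulation uses double precision;
mass-conservation checks use an absolute tolerance of $10^{-6}$, and the
TPM-sums-to-$10^6$ identity a tolerance of $10^{-3}$ over million-cell
arrays.

What passing these simulations shows — and what it does not: the pipeline
arithmetic (encoding, mapping, 1/n assignment, extension geometry, TPM),
the statistical machinery, and the recoverability of planted structure
are verified end to end; fidelity to any particular organism's genome
(repeat content, base composition, annotation quality) and to instrument
error profiles is not, since the toy genomes are i.i.d. random sequence
with a uniform color-error model.

## Known limitations

* No splice-aware mapping and no simulation of junction-spanning tags;
  reads from exon–exon boundaries of real data would go unmapped.
* No two-color error correction; an isolated sequencing error costs one
  mismatch of the budget of two.
* Welch ANOVA calibration at triplicate depth is approximate (above).
* The SOM is the classic online algorithm on a small grid; it is meant
  for profile grouping, not density estimation, and node occupancy
  depends on the data geometry.
* The bias profiler estimates a single multiplicative factor over a fixed
  window; it does not model position-dependent suppression shapes.
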