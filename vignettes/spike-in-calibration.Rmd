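---
title: "Spike-in calibration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calq)
```

# Why calibrate against an exogenous genome

Per-library normalization (equal depth, or composition-based size factors
computed from the measured genes themselves) is built on the assumption
that most of the signal does not change between conditions. Perturbations
of broadly acting chromatin regulators violate that assumption outright: if
a histone modification accumulates uniformly across the genome, or
transcription drops globally, every per-library scheme maps the two
conditions onto the same scale and reports near-zero change. The remedy is
an internal standard: a fixed proportion of cells from a second species is
mixed into each sample before library preparation, so reads aligning to the
spike-in genome measure the effective per-cell sequencing depth of that
library. Placing all samples on the per-spike-cell scale makes global
shifts measurable. `calq` implements this calibration for fragment-level
data (ChIP/ATAC) and for count matrices (RNA), together with the interval
annotation and quantification machinery such analyses use downstream.

# The calibration model

For ChIP/ATAC sample $i$ with matched input/gDNA control, with $S_i, M_i$
the spike-in and target fragment counts of the ChIP/ATAC library and
$s_i, m_i$ those of its control:

$$\alpha_i = s_i / m_i, \qquad D_i = S_i/\alpha_i, \qquad
  p_i = \min_j D_j \,/\, D_i.$$

The control library is not enriched, so $\alpha_i$ is proportional to the
realized spike:target cell mixing of that particular sample. Dividing
$S_i$ by $\alpha_i$ cancels mixing variation — doubling the spike-in cell
input doubles both $S_i$ and $\alpha_i$ — leaving a corrected spike depth
$D_i$ that varies only with sequencing depth and per-cell target signal.
Retaining each sample's target fragments with probability $p_i$ equalizes
per-spike-cell depth across samples. Two consequences worth stating:

* **The reference is the minimum-depth sample.** Defining $p_i$ against
  $\min_j D_j$ is the only choice with every $p_i \le 1$; any other
  reference would require duplicating reads. Exactly one sample keeps all
  its fragments.
* **The sample with genuinely more signal is the reference.** At fixed
  sequencing depth, a condition with elevated per-cell occupancy spends
  more of its reads on the target genome, so its spike share — and hence
  its $D$ — is *smaller*. It keeps everything, and the other condition is
  subsampled. On a simulated uniform 2× shift the quieter condition gets
  $p \approx 0.5$.

Assumptions: spike-in cells are biologically inert with respect to the
perturbation (their per-cell signal is constant across conditions); the
antibody or transposase treats spike-in chromatin consistently across
samples; duplicate removal and blacklist filtering have happened upstream
(an optional blacklist filter is provided). Fragments, not read pairs, are
the counting unit. Spike-in fragments are discarded after factor
computation; they carry no further information once $D_i$ is known.

For RNA, the same cancellation runs through counts. The per-sample gDNA
spike/target total-read ratio $\rho_i$ plays the role of $\alpha_i$:
spike-in gene counts are divided by $\rho_i$ (`prenormalize_spike()`),
median-of-ratios size factors are computed from the prenormalized spike
block (`size_factors()`), and those factors normalize the target genes. A
global shift of the target transcriptome changes every target count but
neither the spike counts nor $\rho$, so it survives normalization — whereas
size factors computed from the target block itself absorb it. Both routes
are exposed (`size_factor_source = "spike"` or `"target"`); their
disagreement *is* the measurement of the global shift.

# The differential expression test

The NB model is fit per gene in closed form for a two-group design, a
deliberate simplification of the full GLM machinery of the established
DE frameworks (which remain the right tool for multi-factor designs):

* Group means by size-factor weighting: $\hat q_c = \sum_{i \in c} k_i /
  \sum_{i \in c} \mathrm{sf}_i$, the MLE under the NB model with a common
  per-condition concentration. A group whose total count is zero receives
  a half-count continuity correction so one-sided-zero genes remain
  testable; genes with zero counts everywhere are reported `NA` and
  excluded from the number of tests used by the Benjamini–Hochberg
  adjustment.
* Dispersion: the per-gene method-of-moments estimate
  $\hat\alpha = \max\{(v-\bar\mu)/\bar\mu^2, 10^{-8}\}$ (pooled
  within-condition variance $v$ of size-factor-normalized counts) is very
  noisy at typical replication (df = 4 for 3 vs 3), so it is shrunk toward
  a mean–dispersion trend. The trend is fit log-log through
  expression-bin *averages* of $\hat\alpha$ (per-gene logs would be
  Jensen-biased low), and the shrink is precision-weighted: the weight on
  the per-gene estimate is $\tau^2/(\tau^2 + \mathrm{Var}(\hat\alpha))$
  with the sampling variance from the delta method and the prior variance
  $\tau^2$ moment-matched from the residuals around the trend. When true
  dispersions are homogeneous the estimator collapses to the trend and the
  Wald test stays calibrated; when they are heterogeneous the per-gene
  signal is retained. A fixed 50/50 mixture was evaluated first and left
  the test visibly anti-conservative at 3 vs 3; the adaptive weight is the
  package's resolution of that trade-off.
* Wald test: $\mathrm{lfc} = \log_2(\hat q_B/\hat q_A)$ with the standard
  error from the NB observed information, referred to a standard normal,
  two-sided. On simulations at the suite's scale (2000 genes, 3 vs 3,
  dispersion 0.05) the raw-p type-I error is ~0.05, empirical FDR at
  `padj < 0.05` is below 0.07 on a 10%-signal mixture, and power for a
  true two-fold change at baseline 500 exceeds 0.9. Power at a BH
  threshold is ensemble-dependent: the power figure is measured on a
  simulation whose tested genes all carry the effect, while the FDR figure
  comes from the mixed simulation, where the implied cutoff is stricter.
* Shrinkage: an adaptive zero-centered normal prior on the log2 fold
  change. The prior variance solves
  $\mathrm{mean}\{\mathrm{lfc}^2/(\tau^2+\mathrm{se}^2)\} = 1$, the
  marginal moment equation under the prior. Two details matter. The
  *uncentered* second moment is used, because matching the variance would
  collapse $\tau^2$ to zero whenever the fold-change distribution is
  displaced as a whole — precisely the global-shift signal the calibrated
  pipeline must preserve. And the standardized form (rather than
  differencing raw moments) keeps $\tau^2$ stable when a few low-count
  genes have enormous standard errors. Significance classes use the
  shrunken fold change against the fold-change threshold and the MLE-based
  Wald p against the adjusted-p threshold (`shrink_for_classes = FALSE`
  switches to the MLE).
* Expression threshold: per-gene RPKM is computed from replicate-averaged
  normalized counts, and the expressed/unexpressed split is the antilog of
  the Gaussian-KDE valley between the two highest modes of the
  `log2(RPKM + 1)` distribution (`expression_valley()`). If the
  distribution is unimodal the package refuses to guess and asks for an
  explicit threshold. The pseudocount of 1 is added to RPKM before the
  log2 transform (the alternative — adding it to the normalized counts —
  is a documented switch away; the two differ only for genes near the
  detection floor).

# What the generators emulate, and what they do not

The synthetic module exists so that every downstream stage can be scored
against recorded truth. All generators are pure functions of their
parameters and a seed, with one RNG stream per sample keyed by
`(seed, sample id)`, so adding a sample never perturbs the others and
reruns are byte-identical.

`simulate_chip_experiment()` draws each library as a multinomial over
genomic positions: target intensity proportional to a per-state enrichment
(times `global_shift` in condition B), spike intensity proportional to the
realized cell mixing, at fixed total depth — so a genuine occupancy shift
moves the target:spike read ratio exactly as in a real sequencer run.
Matched inputs share their ChIP sample's realized mixing, which is what
makes the $\alpha$ correction meaningful. Defaults: mixing 0.4 (the
4×10⁶ : 1×10⁷ spike:target cell design; the cross-linked alternative of
2×10⁶ : 5×10⁷ corresponds to 0.04), lognormal mixing jitter with σ = 0.15
emulating pipetting variation in cell mixing, fragment length 200 bp,
2×10⁵ fragments per sample, and a toy genome of 2 × 5 Mb with a 1 × 2 Mb
spike-in — sizes chosen so the full suite runs in well under a minute while
keeping per-10-kb-bin counts high enough (~100) that binomial noise does
not dominate the quantities under test.

`simulate_rna_counts()` draws target counts as NB with mean
$\mathrm{baseline} \times \mathrm{sf}_i \times 2^{\mathrm{lfc}\cdot[c=B]}$
and spike counts scaling only with depth and mixing; $\rho_i$ is emitted
exactly proportional to the realized mixing. That last point is an
idealization: real gDNA libraries estimate $\rho$ with sampling noise. It
is deliberate — the generator isolates the mixing variation the
prenormalization is supposed to cancel — but it means the suite does not
probe sensitivity to a poorly sequenced gDNA control.

Not emulated at all: read-level sequence, mappability and GC bias, PCR
duplicates, fragment-length variation (sonication produces a distribution;
the counting logic is insensitive to it), chromatin contact structure, and
antibody efficiency differences between samples. Passing tests therefore
demonstrate the *arithmetic and statistical* correctness of the pipeline on
its stated model, not robustness to upstream artifacts — those must be
handled by the upstream aligner/deduplication/blacklist steps the package
assumes.

`make_fixture_annotations()` lays genes on a regular grid and plants
nonmethylated islands, RING1B/SUZ12 sites and ATAC/H3K27ac peaks with known
labels, including deliberately adversarial cases (single-mark promoters
that must *not* classify as Polycomb-occupied; accessibility peaks without
H3K27ac that must not become elements; gene-body enhancers that must not be
flagged intergenic). The classifiers are required to reproduce the labels
exactly, and the gene classes must partition the gene set — mirroring the
three-way split (no-NMI / Polycomb-occupied / other NMI genes) used in the
calibrated analyses this package supports.

# Interval and quantification conventions

* Coordinates are 0-based half-open (BED) everywhere; lengths are
  `end - start`; abutting intervals do not overlap. 1-based inputs are out
  of scope.
* The TSS of a minus-strand gene is `end - 1`, the 5′-most base inside the
  interval. Promoter windows are TSS ± 1 kb for classification, TSS ±
  2.5 kb for signal quantification (TSS ± 0.5 kb for Pol II-type assays,
  where gene-body signal would contaminate a wide window); windows are
  clipped to chromosome bounds and dropped with a warning if clipped away.
* Overlap means ≥ 1 shared bp unless a larger `min_bp` is requested.
  Nearest-neighbor distance is the gap between closest ends (0 for overlap
  or abutment), capped by `max_dist` (inclusive); ties break toward the
  lower start, then the lower row index.
* Region counting is any-overlap (a fragment spanning two abutting regions
  counts in both); genome-bin counting assigns each fragment to the single
  bin holding its midpoint, so bin counts sum exactly to the fragment
  count. Both semantics are exposed where they matter.
* Per-region quantification is `log2(count/kb + 1)`; fold changes are
  ratios of pseudocounted densities, which makes every LFC finite and
  antisymmetric under condition swap.
* Chromatin-state summaries tile the genome (default 10-kb bins), assign
  each bin the state at its midpoint, and report quartile boxes with
  1.5 × IQR whiskers per state against the median LFC of intergenic bins —
  the baseline that represents the genome-wide change.
* Replicates may be merged only when all pairwise Pearson correlations of
  per-region log2 densities exceed 0.9; an undefined correlation
  (zero-variance replicate) fails the gate.

# Numerical choices and degenerate inputs

Empty interval sets are legal wherever a complement or overlap makes them
meaningful; empty *regions* for counting are an error. A BED line with
`start >= end` is rejected with its line number. Unknown chromosomes are
dropped with a warning or escalated to an error, per caller choice.
Calibration refuses zero spike-in or control counts by naming the
offending sample. Subsampling probabilities outside (0, 1] are errors —
upsampling is never silently invented. The KDE valley uses the default
normal-reference bandwidth; with fewer than two density modes the
threshold is declared undefined rather than extrapolated. All statistical
wrappers (`t_test_report()`, `fisher_overlap()`) report failure for
zero-variance or empty-universe inputs instead of returning NaN.

# Suite and acceptance problem sizes

The test suite and `scripts/acceptance.R` run the full pipeline at desk
scale: 2 × 10⁵ fragments per ChIP sample over the 10-Mb toy genome for the
shift-recovery property; 2000 genes × 3 + 3 replicates at dispersion 0.05
for the DE properties (10 seeds for type-I error and FDR); 100 randomized
instances for each brute-force oracle comparison (interval algebra, region
counting, size factors, BH). These sizes were chosen so the binomial/NB
sampling error of each measured quantity sits comfortably inside the
asserted tolerance, and the entire suite completes in about a minute.

# Known limitations

* Two-group designs only; no multi-factor GLMs, interaction terms, or
  transcript-level inference.
* The Wald test relies on a normal approximation that degrades at very low
  counts (baseMean below ~10 with few replicates); the established GLM
  frameworks are preferable there.
* The RPKM library-size denominator is the total of size-factor-normalized
  target counts — under spike-in size factors this is a per-cell-scaled
  library size, which is the appropriate scale for a calibrated analysis
  but differs from conventional RPKM by a constant factor per condition.
* ChromHMM-style segmentations, peak calls and nonmethylated-island calls
  are consumed as interval sets, never computed.
* bigWig/BAM output is out of scope; tracks are tibbles (bedGraph-shaped)
  throughout.
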