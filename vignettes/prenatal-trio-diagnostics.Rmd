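---
title: "Methods: joint CNV and exome trio diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint CNV and exome trio diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prenataldx)
```

# Scope and model

`prenataldx` implements the analytic core of a simultaneous low-pass
whole-genome (CNV-seq) plus whole-exome trio diagnostic workflow for fetal
structural anomalies. The package takes aligned-read summaries — 20 kb bin
counts, exon-depth matrices, and trio variant records — and produces
inheritance-labeled, phenotype-prioritized candidate findings and
cohort-level diagnostic statistics. Read alignment, variant calling and
consequence annotation are upstream and out of scope: their outputs (or
simulated equivalents) are the package's inputs.

# Low-pass CNV calling

Read starts are counted in contiguous 20 kb bins (half-open intervals;
`bin_reads()`). All samples sequenced in one batch regularize each other
(`normalize_batch()`): samples are scaled to a common total, the per-bin
reference is the across-batch **median** of scaled counts, and per-bin
ratios are counts over that reference. The median reference is robust to
CNV carriers inside the batch; after the final scaling the per-bin batch
median of ratios is exactly 1 on usable bins. Bins whose reference falls
below `min_ref` (default 10 scaled counts) are masked everywhere — they are
empty or unmappable regions where a ratio is meaningless.

Breakpoints are detected per sample and chromosome
(`detect_breakpoints()`):

1. the log2-ratio series is smoothed with a centered **local linear
   regression** over `window` bins (default 15; edges use truncated
   windows). The regression family and window are method choices — any
   smoother trading Poisson noise against step blur would do;
2. the first-order difference `d[j] = s[j] - s[j-1]` of the smoothed series
   is taken; a copy-number step becomes a plateau in `|d|` of width about
   the smoothing window and height `|step| / window`;
3. a bin is a breakpoint candidate when `|d[j]|` exceeds
   `tau = max(k * 1.4826 * MAD(d), tau_floor)` with `k = 5`. The floor
   (default 0.02 log2 units) exists so that noise-free inputs, where the
   MAD is 0, still have a finite threshold. The floor must stay well below
   `log2(1.5) / window ≈ 0.039`, the plateau height of a single-copy gain
   at the default window — a larger floor would silently make gains
   uncallable;
4. each contiguous same-sign candidate run yields one breakpoint. Because
   the plateau is flat, the position of the maximal difference within a run
   is nearly arbitrary; the breakpoint is therefore **refined** to the cut
   maximizing the contrast between the mean raw log2 ratio over
   `ceiling(window/2)` bins on either side. The half-width contrast window
   matters: with a full-width window the flanks of short events dilute the
   contrast and boundary placement degrades by several bins.

Consecutive breakpoints assemble into calls (`assemble_cnv_calls()`): a
`down`→`up` pair brackets a loss segment, `up`→`down` a gain. Chromosome
ends and masked-bin gaps act as wildcard boundaries so terminal events are
callable. A segment is emitted iff it spans at least `min_bins` usable bins
(default 3, i.e. 60 kb) and its mean linear ratio falls outside
`[0.75, 1.25]` — midpoints between the integer copy-ratio levels 0.5, 1,
1.5 with margin. The copy number estimate is `round(2 * mean ratio)`
clipped to [0, 6]. These thresholds replace the manual review step of a
clinical workflow.

# Exonic CNV calling

The exonic caller is a deliberately simplified XHMM-style method. The
cohort exon-depth matrix is filtered on mean depth (exons within [10,
2000], samples within [25, 500]), column-mean-centered, and every principal
component whose variance exceeds `0.7 ×` the mean component variance is
removed — the standard relative-variance rule for stripping capture and
batch structure. Each sample's residual row is z-scored. The z series is
decoded per chromosome with a 3-state Viterbi: deletion emits
Normal(−M, 1), diploid Normal(0, 1), duplication Normal(+M, 1) with
`M = 3`; the diploid state leaves with probability `p_event = 1e-4` per
side, CNV states persist with `p_stay = 0.9`, and deletion and duplication
never interchange directly. Only runs of **at least 3 contiguous exons**
become calls; 1–2-exon runs are suppressed as unreliable at exome
resolution. Unlike XHMM v1.0 the emission means are fixed at ±M and
transitions are not distance-scaled; genotype-quality scores are not
computed.

A scale caveat measured during development: PCA normalization assumes any
single event is a vanishing fraction of the matrix. On a toy panel of ~80
exons, a 6–9-exon homozygous deletion is ~10% of the matrix, becomes the
dominant principal component, and is subtracted by the normalization
itself. The acceptance script therefore measures recall on a 600-exon
panel, where planted events of the modeled size range (1.75–74.35 kb) are
at most a few percent of the matrix — the realistic regime.

# Variant quality screening

A record passes for a given trio member iff genotype quality `GQ >= 15`,
variant read depth `DP >= 3`, and the fraction of low-quality bases at the
site is **strictly below** 0.4. The low-quality-base rule is stated as a
boundary alongside keep-criteria; we read it as an exclusion (a site
dominated by low-quality bases is untrustworthy), so exactly 0.4 fails.
Missing quality fields fail closed — conservative for a diagnostic
pipeline. What counts as a "low-quality base" is an upstream definition;
the fraction arrives as a per-member field (`LQF` in the VCF dialect).

# Trio integration and inheritance

Fetal variants and CNVs become unified candidates
(`integrate_trio_candidates()`). Parental presence of a variant is carrier
status of the genotype; parental presence of a CNV requires a same-state
parental call with at least 50% reciprocal overlap — trio genotypes alone
cannot phase a CNV, so overlap plus state is the practical origin rule.
Inheritance rules apply in order: de novo (neither parent carries),
X-linked maternal (male fetus hemizygous, mother heterozygous, father
non-carrier), biparental homozygous, single-parent paternal/maternal,
otherwise unclassified. Male X genotypes are normalized to hemizygous on
input; pseudoautosomal regions are not modeled.

Compound heterozygosity is detected within genes: two heterozygous carrier
candidates (variant or gene-overlapping CNV) with opposite parental
origins are in trans by origin (`phase_confidence = "certain"`) and are
relabeled `compound_heterozygous`; a de novo candidate paired with one
inherited candidate is kept as `"possible"` — true phase is unknowable from
trio genotypes, and discarding such pairs would hide real diagnoses.
Same-origin pairs are rejected as cis-by-origin. A diagnosis is **double**
when the reported findings include at least one CNV and at least one
sequence variant.

# Phenotype prioritization

Candidate genes are scored against the fetal phenotype profile with a
gene-centric information-content match over the ontology: with `n(t)` the
number of genes whose annotation closure contains term `t` and `n_pa(t)`
the number whose closure contains all parents of `t`, the marginal
information is `Phi(t) = -log2(n(t) / n_pa(t))` and the score sums
`Phi` over the intersection of the profile's ancestor closure with the
gene's annotation closure. `Phi` telescopes: along any root-to-leaf chain
the sum equals `-log2(n(leaf) / N)`, which the tests verify exactly.

Candidates then pass allele-frequency filters (dominant/de novo context:
AF ≤ 0.001; recessive context: AF ≤ 0.01 — standard diagnostic practice,
configurable) and are ranked by score, then consequence severity
(truncating > splice region > missense > other, CNVs ranking with
truncating), then genomic position: a deterministic total order.

Report tiers are an explicit simplification labeled **ACMG-lite**, not a
full guideline implementation: P requires loss-of-function + de novo +
phenotype match, or a CNV overlapping a configured known
microdeletion/microduplication-syndrome region; LP requires two of the
three evidence flags, or a recessive genotype (compound heterozygous *or*
biparental homozygous — the latter added so homozygous recessive diagnoses
are reportable at all) in a phenotype-matched gene; everything else
passing filters is VUS. Only P/LP findings enter a diagnosis. Candidates
in a configured secondary-findings list are flagged but withheld by
default.

# Cohort statistics

Diagnostic yield of a phenotypic class is
`100 × (double + cnv_only + variant_only) / cases`, rounded half-up to two
decimals (the CNV and variant columns of the bundled count table are
single-diagnosis counts; this is forced by the totals-row arithmetic).
Class yields are compared with an exact two-tailed Fisher test: conditional
on the margins, the two-sided p-value sums the probabilities of all tables
whose point probability is at most the observed one (relative tie
tolerance 1e-7). This is the standard two-sided definition and the tests
verify it against a binomial-coefficient enumeration oracle for every 2×2
table with total at most 30. The de novo fraction is the share of
diagnosed trios whose single-diagnosis finding is de novo; recurrence
percentages count carriers of each alteration key over the full cohort.

# The synthetic cohort generator

No patient-level data accompany the published cohort, so all algorithmic
guarantees are demonstrated on a generator with known ground truth:

* **Bin counts** are Poisson with mean
  `depth × bin_width/genome × bias_bin × batch_sample × copies/2`; bin bias
  and sample scaling are log-normal (defaults σ = 0.1 and 0.05). Poisson is
  the standard shallow-sequencing assumption; GC content is not modeled
  separately — bin bias subsumes it. Simulations anchor to roughly 5
  million short reads per genome-scaled sample (≥ 1000 expected reads per
  20 kb bin in the recovery studies).
* **Exon depths** are `base_sample × exon_efficiency × copies/2` with
  log-normal noise (default σ = 0.1) and low-rank latent factors providing
  PCA-removable structure. Planted events span at least one exon with
  genomic sizes drawn from 1.75–74.35 kb.
* **Trio genotypes**: parents drawn from population allele frequencies in
  Hardy–Weinberg proportions, fetus by Mendelian transmission, background
  de novo alleles injected at a configurable per-site rate. Designated
  causal mechanisms per trio: autosomal-dominant de novo, AR homozygous,
  AR compound het (SNV+SNV), AR compound het combining an inherited
  gene-deleting CNV with a het variant from the other parent, and X-linked
  maternal in a male fetus. Fetal sex is Bernoulli with P(male) = 0.58,
  the cohort's sex ratio.
* **Phenotypes**: the causal gene's terms with per-term dropout 0.2 plus 2
  decoy terms (the clinical transfer of ultrasound findings to ontology
  terms is manual and noisy; no published noise model exists, so these are
  package choices).

What the generator does **not** emulate: read-level artifacts, sequencing
error, mosaicism, segmental-duplication mappability structure, relatedness
beyond the trio, and realistic linkage between sites. Passing the recovery
properties therefore shows the algorithms are correct under their stated
noise model, not that clinical performance on real data is reproduced.

# Problem sizes and numerical choices

The test and acceptance simulations use a 14 Mb two-chromosome genome (700
bins of 20 kb), batches of 10 samples, 200 planted low-pass events across
25 batches, exon panels of 80 (unit tests) and 600 exons (recall
measurement), and cohorts of 100 trios — sizes chosen so the full suite
runs in about a minute while keeping every per-event statistic at its
asymptotic behavior. Viterbi ties (measure zero for continuous input)
resolve to the lower state index; ranking ties break by genomic position;
rounding of displayed percentages is half-up. Degenerate inputs are
handled explicitly: empty read lists give zero profiles, chromosomes
shorter than the smoothing window use a full-series window, zero-variance
residual rows z-score to zero, and an empty reported set yields an
undiagnosed trio.

# Known limitations

* The low-pass caller targets constitutional (integer copy) events;
  mosaic fractions and paired tumor/normal designs are out of scope.
* Whole-chromosome aneuploidy is not reported through a separate channel;
  arm-scale events are callable only insofar as the batch reference
  retains dosage contrast.
* The exonic caller does not compute XHMM's genotyping qualities, and its
  fixed ±M emissions understate uncertainty for shallow exons.
* Phase for de novo + inherited candidate pairs is genuinely unknowable
  from trio genotypes; such pairs are reported as `possible`, never
  `certain`.
* The tier table is a simplification; it is not a substitute for guideline
  classification in clinical use.
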