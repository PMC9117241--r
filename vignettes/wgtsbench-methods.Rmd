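---
title: "Methods: benchmarking analytics for clinical tumor WGS + RNA profiling"
author: "wgtsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking analytics for clinical tumor WGS + RNA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgtsbench)
```

## What this package models

Clinical programs increasingly analyze paired tumor/normal whole genomes
together with tumor RNA-seq (cWGTS) as a single integrated assay. The
analytics that make such a workflow trustworthy are not the individual
variant callers but the layer above them: merging several callers into a
consensus, filtering recurrent artifacts against a panel of normals, judging
whether a mutation missed by one assay reflects intratumor heterogeneity
(ITH) or a sensitivity failure, quantifying how detection sensitivity decays
with sequencing depth, summarizing mutation burden and mutational processes,
and deciding which findings a targeted panel would have missed. `wgtsbench`
implements that layer as testable functions, together with a synthetic-tumor
simulator rich enough to exercise every stage offline — clone trees,
allele-specific copy number, signature-structured trinucleotide contexts,
per-caller error models, a reference expression cohort, and cell-free DNA
with variable tumor fraction. Patient-level sequencing data of the kind this
pipeline targets is access-restricted by nature, so the simulator is a
first-class, tested component rather than a fixture.

## Consensus calling

Small variants are keyed by (chromosome, position, reference allele,
alternative allele). Because callers emit different padded representations
of the same indel, records are first split into biallelic form, trimmed, and
left-aligned against the reference; only caller-PASS records enter the
merge. A variant is *high-confidence* when it is passed by at least two
callers and survives the panel-of-normals filter: a site is treated as a
recurrent sequencing artifact when at least 3 mutant alleles appear in at
least 1% of the unmatched normals (both boundaries inclusive — "at least"
is read literally; the default panel size is 100).

Structural variants carry two breakpoints with orientations. Callers
disagree on exact breakpoint coordinates, so records are single-linkage
clustered: two records join when both breakpoints lie within a window
(default 200 bp, configurable — merging tools in this space do not publish a
canonical tolerance) and the orientations match; the cluster representative
takes median positions and support counts distinct callers. Fusions merge on
the ordered 5′/3′ gene pair; germline calls come from exactly two callers
and are high-confidence only when called by both.

## Cancer cell fractions and clone clustering

For a mutation at multiplicity $m$ on a segment of total tumor copy number
$C_t$ in a sample of purity $p$,

$$\mathrm{VAF} = \frac{m \cdot \mathrm{CCF} \cdot p}{p\,C_t + 2(1-p)},
\qquad
\mathrm{CCF} = \frac{\mathrm{VAF}\,(p\,C_t + 2(1-p))}{m\,p}.$$

The two functions are exact inverses, which the tests verify to machine
precision. Multiplicity is estimated by rounding the clonal solution and
clamping to $[1, \mathrm{major\ CN}]$. CCFs above 1 usually signal a
multiplicity misestimate; they are clamped at 1.5 and flagged rather than
silently truncated. A mutation is *subclonal* below CCF 0.9 (strict).

Clone structure is inferred by a finite binomial-mixture EM in CCF space:
variant $i$ in cluster $k$ contributes
$\mathrm{Binomial}(d_i,\ \pi_k c_i)$ likelihood, where
$c_i = m_i p / (p C_{t,i} + 2(1-p))$ maps CCF to expected VAF at that locus.
The number of clusters is chosen by BIC over $k = 1,\dots,k_{max}$ (default
5). A Dirichlet-process clusterer is the usual tool here; we use a finite
mixture deliberately: it is deterministic for a fixed seed, desk-scale, and
the published Gibbs-sampling implementations are themselves internally
tuned, so a canonical reference does not really exist. Initialization is
k-means on naive per-variant CCFs with 10 restarts; cluster CCFs are
re-optimized each M-step by bounded 1-D likelihood maximization on
$(10^{-4}, 1.5]$; convergence is declared when the log-likelihood changes by
less than a relative $10^{-6}$ (cap 500 iterations, with a warning and a
best-so-far fit on non-convergence). Mutational signatures are refitted per
cluster independently; clusters under 20 SNVs are flagged low-confidence.

## The ITH proportion test

When a panel assay reports a mutation that WGS does not call, two
explanations compete: the WGS biopsy genuinely lacks the subclone (ITH) or
WGS lacked power. The test compares clonal representation across assays:
alt counts are purity-normalized, $a' = \min(a/p,\ d)$, and a two-sided
two-sample proportion z-test with pooled variance is applied to the adjusted
(alt, depth) pairs. $p < 0.05$ indicates a real difference in clonal
representation. A missing call is then classified **ITH** when higher-depth
resequencing also fails to find it and/or the proportion test is
significant; a missing call with contrary resequencing evidence and a
non-significant test is flagged *indeterminate* (possible sensitivity
failure).

Two caveats are deliberate. There is no standardized algebra for a
purity-aware cross-assay proportion test; the pooled z-test on
purity-normalized counts is the simplest construction that compares clonal
representation while accounting for each assay's depth and purity. And the purity normalization rescales
counts but not their binomial variance, so the test is exact in size only
when the two purities are equal to 1; at lower purity it is mildly
anticonservative. The type-I-error check therefore runs the null — the same
clone sampled independently by both assays — at purity 1, where the two
sampling distributions are identical; over 10,000 simulated null pairs the
empirical size lands within 0.01 of the nominal 0.05.

## Depth downsampling and detection power

Read thinning follows the exact subsampling law of `samtools view -s`: with
thinning fraction $f = \text{target}/\text{original}$, retained depth is
$d' \sim \mathrm{Binomial}(d, f)$ and retained alt reads are hypergeometric
(drawing $d'$ reads from the original $d$ without replacement). Depth tiers
mirror clinical benchmarking practice: 100×, 80×, 60×, and a 30–40× tier
realized as 35×; a thinned set is accepted when its median depth lands
within ±5× of the target (inclusive).

The analytic counterpart is the probability of seeing at least two variant
reads,

$$P(X \ge 2) = 1 - (1-v)^n - n v (1-v)^{n-1}, \qquad
X \sim \mathrm{Binomial}(n, v),$$

with $n$ the effective local coverage (depth × purity; the axis convention
is taken literally even though purity then also shapes $v$) and $v$ the
variant allele fraction. Recall per tier is reported with Wilson 95%
intervals — benchmark reports rarely name their CI method, and Wilson
behaves well at proportions near 1 where these curves live. The optimal tier is the lowest one whose overall recall is within a
margin (default 0.01) of the best tier's.

## Burden, signatures, MSI

Coding TMB counts high-confidence somatic substitutions and indels inside
the coding mask (BED intervals are 0-based half-open; variant positions
1-based) and divides by 30, the conventional exome-Mb denominator.
Classification is strict: above 2 mutations/Mb is pediatric-high, above 10
hypermutator — exactly 2.0 or 10.0 stays in the lower class (strict
"greater than" convention).

SNV spectra use the 96 pyrimidine-normalized trinucleotide contexts;
purine-reference variants are reverse-complemented, and the spectrum always
sums to the number of usable SNVs. Refitting solves a non-negative least
squares problem against a catalog whose columns are signature profiles, then
iteratively drops signatures below a 1% exposure share and refits until the
active set is stable — NNLS bleeds small spurious exposures, and 1% is a
conservative floor in the absence of a published pruning rule. The
reconstruction cosine is reported; below 0.8 the fit is flagged. Treatment
signatures (platinum, temozolomide) are flagged at ≥5% share and ≥50
attributed mutations (both configurable). The bundled catalog is synthetic —
five well-separated block signatures — because real catalog matrices are
large external data; a loader for COSMIC-format TSVs is provided.

MSI is scored per microsatellite site: tumor and normal repeat-length
histograms (each with at least 20 supporting reads) are compared by
chi-square with 0.5 pseudo-counts, a site is unstable at $p < 0.05$, and the
score is 100 × unstable/assessed. Status bands — below 3 stable, 3–10
indeterminate, 10 and above high — were chosen to reproduce the qualitative
labels clinical reports attach to scores like 7.2 ("indeterminate"), since
the numeric cut-offs are folklore of the scoring tool rather than printed
constants.

## Prioritization

Oncogenicity is table-driven: a local driver table (gene, variant class,
optional specific alteration) stands in for the live annotation services a
production deployment would query, keeping runs deterministic and offline.
SVs are oncogenic when a breakpoint falls in a listed gene body; deletions
also capture fully contained genes. Expression biomarkers compare tumor TPM
to an empirical reference-cohort percentile (linear interpolation; default
cohort size 274, matching a realistic internal reference): over/under
beyond the 90th/10th percentile, severe beyond the 95th/5th. A biomarker is
*SV-supported* when its gene is hit by an SV/fusion or sits on an amplified
(CN ≥ 2×ploidy) or homozygously deleted segment with direction-consistent
expression. Germline review retains rare variants (max population AF < 0.01,
cohort recurrence capped) and lets pathogenic/likely-pathogenic assertions
override the frequency filters — the ACMG-style precedence.

Incremental findings are the keyed set difference between cWGTS findings
and panel findings. Each is assigned one clinical category with fixed
precedence `diagnostic > germline > therapy_informing > driver_fusion >
prognostic`; clinical reports assign one category per finding without
stating tie rules, so the precedence is declared here once and used
everywhere. WES/RNA capturability is rule-based: coding small variants and
SVs with a coding breakpoint are WES-capturable; fusion transcripts and
expression biomarkers are RNA-capturable; genome-wide signature/TMB/MSI
findings are treated as exome-derivable; noncoding SVs without an
expression consequence are capturable by neither — the enhancer-hijacking
case that motivates whole-genome sequencing in the first place.

## What the simulator does and does not emulate

Depth is negative-binomial around the assay mean (dispersion 10) — real WGS
depth is overdispersed but we do not model GC bias or mappability. Alt
reads are binomial at the expected VAF; there are no sequencing-error base
qualities, no FFPE chemistry, no read-level artifacts (caller false
positives are placed uniformly at non-truth loci as the simplest null for
consensus filtering). The reference genome is a small random sequence
(default two 1 Mb contigs; tests use two 200 kb contigs) written as
FASTA + BED so context extraction and coding masks run offline; it has the
trinucleotide composition of random sequence, not of a human genome. ITH
scenarios give the panel assay its own purity and clone subset; cfDNA is a
WGS assay whose purity is the circulating tumor fraction, optionally with a
cfDNA-private subclone. Indels are 1–10 bp; SVs are breakpoint pairs with
orientation; fusions join two gene bodies without frame checking.

Passing tests on this simulator therefore demonstrate the *analytics* —
merging, testing, power, refitting, reporting — under a controlled
generative model; they do not certify performance on real reads, real
artifact spectra, or real human genome composition.

## Problem sizes and numerical choices

The bundled checks run at deliberately desk-scale sizes, chosen once:
worked-example summary tables at reference clinical-cohort scale (221
panel-reported mutations, 114 patients); 10,000 null pairs for the ITH test size; a 50×50 grid for the
power formula against brute-force pmf summation (agreement to 1e-12); 5,000
variants per depth tier for recall (clonal VAF 0.5 for the power comparison;
a 0.5/0.25/0.10 VAF spectrum for tier curves, mirroring a clonal tumor with
a subclonal tail); 5,000 SNVs for a 60/40 two-signature refit (recovery
within ±0.05, cosine ≥ 0.95); 50 replicates of a 400-SNV biclonal tumor
(CCF 1.0/0.4, purity 0.8, depth 100) for clone recovery within ±0.05; and a
2,000-SNV clonal tumor for cfDNA tumor-fraction recovery at fractions
0.1–0.83 (±0.05) — VAF-density estimation in real data draws on thousands
of genome-wide SNVs, so sparser inputs would understate the method. The
tumor-fraction mode uses a Sheather–Jones plug-in bandwidth, which is less
biased at the density mode than the rule-of-thumb default.

## Known limitations

The proportion test's purity adjustment is approximate at purity < 1 (see
above). The clone clusterer assumes a shared purity per assay and estimated
multiplicities; heavy copy-number complexity degrades CCF accuracy before
it degrades clustering. The "at least 94%" style derived concordance
figures occasionally quoted around discordant-mutation counts are not
recomputed — the summary reports raw counts and percentages it can define
exactly. CNA concordance is reduced to length-weighted total-CN agreement
within ±1 copy; qualitative profile comparison is out of scope, as are read
alignment, the individual callers, CN inference, fusion detection from raw
reads, telomere length, chromothripsis/WGD detection, and report rendering.
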