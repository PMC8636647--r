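---
title: "Methods: RNA-associated PIR classification, enrichment and validation readouts"
author: "rnapir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA-associated PIR classification, enrichment and validation readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnapir)
```

# Overview

`rnapir` implements a positional-overlap analysis connecting three kinds
of interval data from the same genome: promoter-interacting regions
(PIRs) from promoter-capture Hi-C, DNA regions contacted by RNAs from a
MARGI-style assay, and transcription-factor binding-site tracks. The
question it answers is statistical, not mechanistic: *are architectural
binding sites (CTCF, YY1) over-represented in the PIRs that RNAs touch,
once fragment size is accounted for, and do the genes wired to those PIRs
express differently?* Validation readouts from qPCR and 3C-qPCR
experiments are quantified alongside.

# Coordinate model

All file I/O uses the BED convention: 0-based, half-open intervals on a
named assembly. Internally intervals live in `GRanges` (1-based, closed);
the conversion happens in exactly one place (`makeTrack()` /
`writeBed()`), so the half-open semantics are preserved: intervals that
merely abut share no base and never count as overlapping, while a single
shared base does count ("any degree of intersection"). Strand is ignored
throughout — the analysis is purely positional — and an assembly
(`Seqinfo`) bound to a track makes out-of-bounds or unknown-chromosome
coordinates a hard error rather than a silent anomaly.

PIR identity is the exact coordinate triple. PIRs are restriction
fragments: fragment boundaries are fixed by the enzyme, so near-identical
fragments are distinct and no fuzzy merging is ever applied. When the
same fragment appears in several promoter interactions it is collapsed to
one record carrying the union of its bait gene symbols.

Contact tables are cleaned of rows mapping to unlocalized or unplaced
scaffolds: any chromosome name containing an underscore (`chrUn_…`,
`…_random`) or absent from the bound assembly. Duplicate contact pairs
are collapsed so counts refer to unique RNA–DNA interactions, and the
unique contacted DNA regions form the track against which PIRs are
classified.

# Consensus binding sites

Replicate peak tracks for one factor are combined by per-base
intersection: each track is first reduced to its covered bases, then only
bases covered by *every* track survive, yielding maximal disjoint
intervals (`consensusIntervals()`). This is the strict all-datasets-agree
reading of a replicate consensus. A second reading — the PIR must overlap
each replicate track somewhere, possibly at different positions — is
genuinely different (a PIR can satisfy it with no commonly covered base),
and is available as `annotateTfbs(…, rule = "each-track")`. The per-base
rule is the default because "consensus genomic intervals" are a concrete
interval set one can shuffle, which the permutation null requires; the
tests exercise both rules on a case where they disagree.

# Enrichment model

For each factor the unit of analysis is the unique PIR, with outcome
`site` (overlaps the consensus), exposure `rna` (overlaps an
RNA-contacted region), and fragment length as covariate:

$$\operatorname{logit} P(\text{site}_i) = \beta_0 + \beta_1\,
\text{rna}_i + \beta_2 \log_{10}(\text{len}_i).$$

The length covariate is the crux: the probability that a fragment
overlaps *anything* grows with its length, and RNA contacts are
themselves length-biased, so the crude 2×2 odds ratio confounds
enrichment with size. Fragment lengths span two orders of magnitude,
hence the log10 scale by default (`covariate = "raw-length"` and
`"none"` are available; without the covariate the fitted `exp(β₁)`
equals the sample 2×2 odds ratio exactly, an identity the tests assert to
1e-10). The regression direction is also configurable
(`direction = "rna-on-tfbs"`): with a covariate the two directions are
not identical, and the package defaults to modelling site presence on RNA
status, reading the result as "RNA-PIRs have γ-fold higher odds of
carrying a site of this factor".

Fitting is maximum likelihood via iteratively reweighted least squares
(`glm.fit`, binomial family, convergence tolerance 1e-14, at most 100
iterations), with an explicit error when any coefficient exceeds ±30
log-odds — the practical signature of complete or quasi-complete
separation, where the MLE diverges. Inference is Wald:
`OR = exp(β₁)`, CI `exp(β₁ ± 1.959964·se)`, two-sided normal p-value.
Wald (rather than profile-likelihood) intervals are the standard output
of binary logistic regression and are accurate at the sample sizes this
analysis runs at (10⁴–10⁵ fragments with cell counts in the hundreds).

# Permutation null

Analytic p-values from the regression assume the model; the permutation
test does not. The consensus track is built once, then each permutation
re-places every consensus interval uniformly at random in the genome —
chromosome chosen with probability proportional to its number of valid
start positions (`L − w + 1`), start uniform among them, overlaps among
placed intervals allowed, no excluded regions — and the identical
regression is re-fitted against the re-annotated outcome. With `r`
permuted p-values strictly below the observed one out of `n` valid
permutations, the reported p-value is the add-one estimator
`(r + 1)/(n + 1)`, which never returns an impossible zero: at `r = 0`,
`n = 1000` it yields 1/1001, printed as `< 1.0e-3` since the observed
statistic merely beat the resolution of the null sample. Permuted fits
that fail (separation can occur when a shuffled set barely intersects the
PIRs, which happens routinely on toy-sized data and essentially never at
study scale) are excluded with a warning and `n` reduced accordingly.

Each permutation draws its randomness from a sub-seed
`subSeed(seed, i) = ((seed mod m)·69069 + i·41651) mod m + 1`
(`m = 2³¹ − 1`), a fixed affine mixing function computed exactly in
double precision, so results are reproducible across platforms and the
permutations of one run are independent of loop order or parallel
chunking. One design choice worth recording: the *consensus* is shuffled,
not the individual replicate tracks before consensus — the consensus is
the interval set the analysis actually uses, and shuffling upstream
replicates would destroy their concordance and thus test a different
(and uninteresting) null.

# Expression comparison

Transcript-level TPM tables (one per replicate) are aggregated by
averaging replicates per transcript, then summing transcript TPMs within
gene — a gene's abundance is the total abundance of its transcripts
(`transcriptAgg = "mean"` is available). Genes are attached to the four
PIR categories (RNA+site, RNA-only, site-only, neither) as the union of
bait symbols over the PIRs in each cell; the categories partition PIRs,
not genes, so a gene wired to PIRs of different kinds legitimately
appears in several lists, and all genes with a TPM entry are used
(zero-TPM genes retained — restricting to "expressed" genes would
condition on the outcome). Category distributions are compared with a
two-sided Mann–Whitney test on the per-gene TPM vectors (means are what
one plots; a test needs the distributions). The p-value is exact by
enumeration when both samples have ≤ 8 tie-free observations, otherwise
the normal approximation with tie-corrected variance and continuity
correction. Exhaustive enumeration at the 8-vs-8 boundary puts the
approximation within 0.0109 of exact everywhere, and within 0.01
wherever the exact p is below 0.35 — amply accurate in the regime where
the answer matters.

# qPCR and 3C-qPCR quantification

Relative quantification uses the 2^−ΔΔCt method on the scale where qPCR
noise is approximately normal: per statistical unit,
ΔCt = Ct(target) − Ct(reference); ΔΔCt is the difference of group mean
ΔCt (test − control); fold = 2^−ΔΔCt. The reference assay is an
invariant internal control measured in the same wells — an *IPO8* assay
for expression, an *ERCC3* ligation junction for 3C, where the quantified
fold is a relative interaction frequency (ΔΔCt = −1 means the loop is
detected twice as often). Two identities are load-bearing and tested
exactly: a constant plate offset cancels (ΔCt subtracts it within-unit),
and swapping test and control maps the fold to its reciprocal.

Technical replicates are averaged within sample before group statistics
whenever a group contains two or more samples; with a single sample the
replicates themselves are the units. SE(ΔΔCt) pools the two group
standard errors, `sqrt(SE² test + SE² control)`, and the fold interval
`2^−(ΔΔCt ± SE)` is reported asymmetrically — no delta-method
symmetrisation, since the fold scale is log-symmetric. Group comparison
is a two-sided Welch t-test on the ΔCt units (never on folds), with
Bonferroni adjustment `min(1, m·p)` across the `m` targets of a panel.
Degenerate zero-variance groups with equal means return p = 1 with a
warning rather than NaN. Primer-efficiency correction (Pfaffl), standard
curves and melt-curve QC are out of scope.

# The synthetic-data generator

`generateDataset()` emulates the statistical structure the analysis
assumes, with all randomness flowing from one seed through named
substreams (placement, RNA, sites, genes, expression, qPCR) so modules
regenerate independently:

- **Fragments.** 20,000 PIRs by default, lengths log-normal
  (`meanlog = log 4000`, `sdlog = 0.8`, clamped to 0.5–50 kb) — a
  HindIII-like distribution with median ~4 kb and a long right tail —
  tiled without overlap along five 50-Mb chromosomes with 0.5–2.5 kb
  gaps.
- **RNA contacts.** `logit P(rna) = −4 + 1.0·log₁₀(len)` (≈ 40%
  RNA-PIRs at the median length; deliberately length-confounded). Each
  RNA-PIR receives 1+Poisson(0.5) contacts whose DNA ends lie strictly
  inside the fragment, so classification recovers the planted flags
  exactly; decoy rows (interchromosomal interactions, duplicate pairs,
  `chrUn` scaffolds) are appended to the emitted files to exercise the
  loaders' filters.
- **Binding sites.** `logit P(site) = −5.8 + log(1.78)·rna +
  1.0·log₁₀(len)`: the planted conditional odds ratio is 1.78, the
  baseline gives ≈ 10% site-bearing nonRNA-PIRs, and the shared length
  term makes the crude odds ratio biased upward (≈ 1.9) while the
  covariate-adjusted regression is correctly specified and unbiased —
  the generator exists precisely to make that distinction demonstrable.
  Each flagged fragment hosts one 200-bp site placed ≥ 11 bp from the
  fragment edges; background sites (half as many) land only in the gaps
  between fragments.
- **Replicate tracks.** Three copies of the true placements with
  endpoints jittered by ±10 bp, mirroring ENCODE replicate concordance:
  the per-base consensus of the jittered copies contains the true site
  shrunk by at most the jitter, stays inside the host fragment, and so
  recovers the planted flags exactly (the generator rejects configs with
  `2·jitter ≥ site width`, where the consensus could vanish).
- **Expression.** Log-normal baseline TPM (`meanlog = log 5`,
  `sdlog = 1.2`) times a multiplicative category effect (3× for
  RNA+site, 1.5× for RNA-only, 1× otherwise), split across two
  transcripts per gene and emitted as two replicates with 0.1 log-sd
  noise.
- **qPCR.** Ct tables with planted fold changes (test-group ΔCt shifted
  by −log₂ fold): 2× *MSX1* expression, 0.25× *STX18AS1* (the
  knocked-down RNA), 2× the *MSX1* promoter–PIR 3C junction — the
  direction in which removing a repressive RNA strengthens its insulating
  loop — with 3 samples × 3 technical replicates per group and 0.1-cycle
  well noise.

What the generator does **not** emulate: realistic Hi-C contact-frequency
decay, sequence content, read-level noise, CHiCAGO-style interaction
calling, mappability or GC structure in the background site placement,
and biological (rather than multiplicative) expression covariance.
Passing tests therefore demonstrate that the statistical machinery is
correct under its stated model, not that the model captures every bias of
real chromatin data.

# Numerical choices and degenerate inputs

- IRLS tolerance 1e-14 so the saturated 2×2 fit reproduces the
  closed-form odds ratio to 1e-10; separation detected at |β| > 30.
- Wald p-values are floored at the smallest positive double so a
  p-value of exactly 0 (impossible in theory) cannot propagate.
- Sorting is lexicographic (chromosome in assembly order, then start,
  then end); every track constructor returns sorted output and the
  overlap machinery verifies sortedness in O(n).
- Empty track list, single-class outcomes, empty expression categories,
  missing reference assays and groups with fewer than two ΔCt units are
  all explicit errors naming the offending object.
- The permutation loop uses a linearised-coordinate overlap path (two
  `findInterval` lookups per shuffle) when the PIRs are disjoint and
  sorted — always true for restriction fragments — and falls back to the
  generic interval machinery otherwise; the tests assert both paths give
  identical fits.

# Problem sizes used in the test suite

The suite validates calibration and recovery at deliberately chosen
sizes: permutation calibration on 100 null datasets (no conditional
association, length confounding retained) of 5,000 PIRs × 200 shuffles;
odds-ratio recovery on 100 replicates at the full 20,000-PIR scale
(mean log-OR within 3 Monte-Carlo SE of log 1.78, crude estimator
demonstrably biased); estimator consistency contrasting 2,000 against
20,000 fragments; and exhaustive small-n enumeration for the
Mann–Whitney and overlap oracles. The whole suite completes in roughly a
quarter hour on one core.

# Known limitations

- The enrichment model treats PIRs as independent units; spatial
  autocorrelation between neighbouring fragments is not modelled (the
  permutation null inherits the same assumption, so the comparison is
  internally consistent).
- PIRs are restriction fragments, not biological element boundaries;
  overlap indicates proximity, not the site of action.
- No Firth correction: datasets small enough to separate should be
  analysed exactly, not with this package's Wald machinery.
- The unlocalized-scaffold filter is name-based (underscore convention);
  assemblies with exotic naming need a pre-mapped chromosome table.
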