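---
title: "Classifying zygotic promoters by H2A.Z: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying zygotic promoters by H2A.Z: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zgakit)
```

`zgakit` analyses the chromatin landscape of zygotic genome activation
(ZGA): which promoters fire when the embryo's genome switches on, which
of them depend on the pioneer factor Zelda, which carry the histone
variant H2A.Z on the +1/-1 nucleosome, and how transcription, H2A.Z
occupancy and 3D genome structure respond when the H2A.Z chaperone is
depleted from the maternal supply. This vignette documents the models
and numerical choices behind each stage; the README shows the surface.

## Coordinate conventions

All internal coordinates are 0-based, half-open; GTF input (1-based,
closed) is converted once at the boundary by `load_annotation()`. The
TSS of a plus-strand unit is `start`; of a minus-strand unit `end - 1`.
"Downstream" always means increasing signed offset along the
transcript's strand (`strand_offset()`), which makes every rule below
strand-symmetric; the test suite verifies the symmetry by mirroring
chromosomes.

## Promoter activity from nascent transcription

Fragments are reduced to their 5' ends and extended 100 bp (`extsize`)
in the strand direction, giving one coverage track per strand with
replicates pooled. The external peak caller used in this field is
re-implemented as a self-contained Poisson scan: candidate regions are
maximal runs of coverage above the genome-wide mean (merged across gaps
up to `extsize`); each candidate's summit height is tested against
`lambda_local = max(lambda_genome, lambda_1kb, lambda_10kb)` (window
means centered on the summit, which include the peak itself and are
therefore conservative); q-values are Benjamini-Hochberg over all
candidates of both strands, kept at q <= 0.05. Summit ties break
leftmost for determinism. This is a documented simplification - the
same statistical idea, not a bit-compatible clone of the external
tool.

A promoter is *active* iff a peak summit on its strand lies within
150 nt (inclusive, unsigned) of the TSS. The distance is measured to
the summit, not the peak edge, because summits are what the upstream
caller explicitly reports; the choice is logged per promoter via the
supporting-peak provenance columns. Regions of merged accessibility
peaks spanning strictly more than 12 kb (peaks merged across gaps up
to 1 kb) are blacklisted, and promoters inside them are forced
inactive.

*Unique promoters*: transcripts of one gene whose TSS +/- 150 windows
overlap on the same strand collapse into one promoter; the
representative is the transcript with the smallest differential FDR
when differential results exist, otherwise the most upstream TSS.
Promoters whose window overlaps another gene's promoter window on the
same strand are discarded as non-unique. The +/-150 window reuses the
activity distance for internal consistency, since the source analysis
leaves the overlap window unspecified.

## Nucleosome dyads and H2A.Z classes

Fragments are first filtered to nucleosome footprints (130-200 bp,
inclusive). Dyads are local maxima of the fragment-midpoint density
smoothed with a 30-bp-sd Gaussian kernel, thresholded at 2x the
chromosome median density (with a tiny relative floor against FFT
round-off on sparse chromosomes), kept greedily in decreasing
occupancy at >= 120 bp spacing. This kernel-density caller replaces
the published nucleosome caller: the classification logic downstream,
not the caller internals, is the contribution under test here.

Flanking nucleosomes follow two replicate-consistency rules, evaluated
in order and combined by OR:

* **Rule 1**: the nearest dyad within 350 nt of the TSS in *either*
  replicate (plain OR over replicates; ties by distance, then leftmost).
* **Rule 2**: dyads within 600 nt in *both* replicates whose centers
  differ by strictly less than 80 nt; the reported position is their
  midpoint (symmetric in the replicates).

Distances are unsigned but filtered by direction first (downstream
offsets >= 0 for the +1, upstream < 0 for the -1), which preserves the
+1/-1 semantics including dyads sitting exactly on the TSS. A promoter
is `H2AZ_POS` iff a +1 was assigned, else `H2AZ_NEG_MINUS1` iff a -1
was assigned, else `H2AZ_NEG_NONE`; the three labels partition the
Zelda-independent active promoters, and Zelda-dependent promoters are
excluded from the partition while keeping their flank calls for
reporting.

## Origin classification and Zelda zygotic targets

TPM is computed as length-normalized rates scaled to one million per
sample; effective length is the annotated span (no fragment-length
correction), and gene-level values sum isoform rates, since the
analysis operates at gene level without an isoform model. Maternal
genes have TPM strictly above 5 in at least 3 unfertilized-egg
replicates. Origin is the set partition zygotic / maternal /
maternal-zygotic / silent against the active set. Zelda zygotic
targets are the conjunction: mean control-embryo TPM > 5 (the
unfertilized rule is stated per replicate, the embryo rule is not, so
the mean is the default with a per-replicate option), Zelda-dependent,
strictly zygotic, and active.

## The negative-binomial engine

One NB engine stands behind both differential stages (nascent
transcription and Pol II occupancy): features with mean raw count
below 10 are removed; per-feature dispersions are method-of-moments
estimates on size-factor-normalized counts pooled within condition
(floored at 1e-8); the GLM (log link, condition covariate, optional
replicate blocking, size factors as offsets) is fitted by IRLS; the
condition coefficient is Wald-tested. The reference distribution is a
t with the model's residual degrees of freedom: the plug-in variance
rests on a moment dispersion carrying only ~(n - p) df, and on
simulated nulls the normal reference is visibly anticonservative
(~9% of null p-values below 0.05 at 3 vs 3) while the t reference is
calibrated (inside [0.03, 0.07], Kolmogorov-Smirnov-uniform). The
cost of that honesty is power at very small n: with two replicates
per condition (t with 2 df) even a four-fold change cannot clear
FDR < 0.01 among hundreds of features, which is why the synthetic
Pol II contrast uses three replicates per condition (see below).
Zelda dependence is logFC < -1 AND FDR < 0.01, both strict, matching
the rule's wording. Empirical-Bayes dispersion shrinkage, exact
tests and fold-change shrinkage are deliberately out of scope; the
installed general-purpose differential packages serve as independent
cross-checks in the test suite, never as the implementation.

Size factors are geometric median-of-ratios computed on a reference
feature set only (e.g. Zelda zygotic targets, a set expected to be
unchanged in the chaperone knockdown), with zero-containing reference
features excluded and the output normalized to geometric mean one -
size factors are defined up to scale, and this normalization makes
the scale-equivariance property exact on factor ratios.

## Quantitative ChIP scaling

The RELACS-style double ratio over active promoters (TSS +/- 400 nt)
is `[(IP_KD/L)/(IP_Ctrl/L)] / [(In_KD/L)/(In_Ctrl/L)]` with counts
summed over regions and replicates (pooled; the per-region median is
also reported since the source analysis does not say which was
printed) and L the sample's main-genome fragment total. A factor of
0.5 means half the control H2A.Z at promoters. Spike-in size factors
are inversely proportional to each sample's spike-contig read share,
normalized to geometric mean one. The published regularized-log
transform is replaced by a shifted log2 after size-factor scaling - a
documented variance-stabilization stand-in. Genome bins are 500 nt,
fragments assigned by midpoint (each fragment counted exactly once
per sample), and bins with mean count <= 25 are discarded.

## Hi-C insulation

Contacts are binned at 2 kb and balanced by iterative correction to
equal row sums - the same fixed-point family as KR balancing, with
zero-marginal bins masked and convergence required at a 1e-5 relative
residual (balanced row-sum CV < 1e-4 is asserted in the tests). The
insulation score at bin *i* averages, over window sizes 20-100 kb in
2-kb steps, the log2 of the diamond mean (balanced counts over
`[i-w, i-1] x [i+1, i+w]`) relative to its chromosome mean; 0 is
average insulation, lower is more insulated, and bins within the
maximum window of a chromosome edge are NA, never 0. Multi-depth
aggregation is an unweighted mean since the published tool's
aggregation is not documented. Boundaries are local minima at least
delta = 0.01 below both flanking maxima; this simplifies the
published rank-based boundary test to a prominence rule, which is why
the synthetic matrices are deep (see below). Group profiles orient
windows by strand and report pointwise medians with standard errors,
excluding uncovered bins.

## IP-MS statistics

After removing contaminant/decoy/site-only rows, proteins need at
least 2 valid values in the bait group *or* the control group - so a
protein seen only in the bait survives, and after imputation such
proteins get low control values, which is exactly how presence/absence
enrichment is meant to surface. Per-sample median centering to the
grand median stands in for variance-stabilizing normalization (the
arcsinh fit is out of scope). Missing values are imputed per sample
from `Normal(mu - 1.8 sd, (0.5 sd)^2)` of that sample's observed
distribution - per-sample rather than global, the standard choice for
this imputation. The moderated t shrinks per-protein variances toward
a prior estimated by moments on the log residual variances (the prior
df via a trigamma inversion); p-values use d0 + d degrees of freedom
and Benjamini-Yekutieli correction, and enrichment requires
padj <= 0.05 and a fold change of at least 1.5, both inclusive.

## The synthetic embryo study

`sim_config()` defines the study the tests run on: 2 chromosomes x
1 Mb plus a 50-kb spike contig, 400 genes at >= 3 kb TSS spacing, 60%
active, 10% of active Zelda-dependent, 69.7% of the Zelda-independent
H2A.Z-positive and 26% of the remainder -1-only - the class geometry
of the real promoter landscape. Planted +1 dyads sit at +120 nt and
-1 dyads at -180 nt (both inside the 350-nt rule-1 window by
construction) with 20-bp phasing noise. Sequencing depths are
150k fragments per nascent-transcription replicate (x3), 300k per
ChIP sample, three Pol II replicates per condition (two-replicate
designs leave the honest Wald-t with no power at FDR 0.01; see
above), RNA counts are negative-binomial (dispersion 0.05), and each
ChIP sample carries a 5% spike-in share. One RNG stream per assay is
derived from the master seed, so adding an assay never perturbs
another's data.

Two generative choices matter for identifiability and are worth
stating plainly:

* **Nucleosome-free regions.** Chromatin background fragments of the
  nucleosomal assays are excluded from +/-520 bp around active TSSs,
  reflecting the accessible, nucleosome-depleted state of active
  promoters. Without an NFR, background inside the +/-400 quantification
  windows biases the double ratio toward 1 and caps recoverable
  depletion around 0.6; with it, the estimator recovers planted
  factors in {0.25, 0.5, 0.75, 1.0} within +/-0.05. Background is a
  stable (chaperone-independent) compartment, so promoter depletion
  shows against it; a uniform global depletion would be invisible to
  any library-size-corrected composition measure.
* **Deep contact matrices.** 2e7 expected contacts per chromosome, as
  in merged replicate matrices. The delta = 0.01 prominence cutoff is
  small in log2 units; because the published boundary test's rank
  statistics were simplified away, matrix noise must sit well below
  delta for the false-boundary rate to stay near zero, and at this
  depth it does (boundary recovery is evaluated where the score is
  defined, i.e. outside the max-window edge margin).

What the generator does *not* emulate: sequence content and
mappability or GC bias, enhancer chromatin, isoform structure (one
transcript per gene), inter-chromosomal contacts, replicate batch
effects, and the tag-density artifacts of real libraries. Passing
tests therefore demonstrate that the rules and estimators recover
planted structure under their stated assumptions - not that the
pipeline is robust to every artifact of real embryo data.

## Problem sizes and determinism

The default study runs end to end in well under a minute on one CPU;
the test suite uses a half-size configuration for unit tests and the
default scale for the end-to-end and scaling checks. Every stage is
deterministic given `sim_config(seed = )`: the pipeline run, the
classification table and the JSON report are reproduced byte-for-byte
under the same configuration, and the report embeds the seed and a
configuration hash for audit.
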