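# zgakit

Promoter classification and quantitative chromatin analysis at zygotic
genome activation (ZGA), for genomicists studying how the embryo's own
transcriptional program starts. In *Drosophila*, the pioneer factor
Zelda activates only a minority of zygotic promoters; most of the
remainder carry the histone variant H2A.Z on the nucleosome flanking
the transcription start site. `zgakit` re-implements, as a tested and
reusable R pipeline, the analysis chain with which such a promoter
landscape is mapped and quantified:

* **Promoter activity** from nascent-transcription (GRO-seq style)
  fragments: strand-specific coverage (5' ends extended 100 bp),
  a Poisson-background peak scan with local lambda correction and BH
  q-values (q <= 0.05), and the activity rule *peak summit on the same
  strand within 150 nt of the TSS*. Hyper-accessible regions (merged
  accessibility peaks spanning > 12 kb) are blacklisted.
* **H2A.Z promoter classes** from nucleosome-sized fragments
  (130-200 bp): dyads are local maxima of the Gaussian-smoothed
  midpoint density; a +1 (-1) nucleosome is assigned when a dyad lies
  within 350 nt of the TSS in either replicate, or within 600 nt in
  both replicates with centers differing by < 80 nt. Promoters are
  H2A.Z-positive (+1 present), -1-only, or H2A.Z-negative.
* **Maternal/zygotic origin** via TPM: maternal = TPM > 5 in >= 3
  unfertilized-egg replicates; zygotic/maternal-zygotic/silent as the
  set partition against the active promoters; Zelda zygotic targets as
  the four-way conjunction with Zelda dependence.
* **Differential occupancy**: a self-contained negative-binomial engine
  (median-of-ratios size factors on a reference gene set, moment
  dispersions, IRLS-fitted GLM, Wald t test, BH), with the
  Zelda-dependence rule logFC < -1 and FDR < 0.01.
* **Quantitative ChIP scaling**: RELACS-style library-size-corrected
  double ratios of IP and input over active promoters (+/-400 nt),
  spike-in size factors, shifted-log quantification, 500-nt genome
  bins.
* **Hi-C insulation**: 2-kb contact matrices, iterative-correction
  balancing, multi-depth diamond insulation scores (20-100 kb windows,
  2 kb step), delta-prominence boundary calls (delta 0.01), TSS-group
  profiles and boundary distances.
* **IP-MS enrichment statistics**: flag filtering, median centering,
  shifted-normal imputation (width 0.5, downshift 1.8), moderated t
  with empirical-Bayes variance shrinkage, Benjamini-Yekutieli
  correction, enrichment at padj <= 0.05 and fold change >= 1.5.
* **Synthetic embryo genomics**: every assay above can be simulated
  from one `sim_config()` with planted ground truth (active fractions,
  Zelda dependence, +1/-1 dyad offsets, knockdown depletion factors,
  spike-in shares, TAD boundaries, bait-enriched proteins), so the
  whole pipeline is testable end to end without external data.

## Worked example

```r
library(zgakit)

cfg <- sim_config(seed = 1)     # 2 x 1 Mb toy genome, 400 genes
run <- run_zga_pipeline(cfg)
print(run)
```

```
zga_run (seed 1, config 5b32fa66)
  400 promoters, 239 active (239 genes)
  zld                22 promoters (9.2% of active), median logFC(KD) +0.02
  h2az_pos          151 promoters (63.2% of active), median logFC(KD) -1.13
  h2az_neg_minus1    17 promoters (7.1% of active), median logFC(KD) -0.45
  h2az_neg_none      49 promoters (20.5% of active), median logFC(KD) -0.14
  RELACS promoter H2A.Z factor (KD/Ctrl): 0.525
```

Reading the output: of the 239 promoters called active from simulated
nascent transcription, 22 (9.2%) lose Pol II in the simulated Zelda
knockdown (planted: 10%), 151 (63.2%) carry H2A.Z on the +1 nucleosome
(planted: 62.9%), and 17 carry it only on the -1 nucleosome. Upon the
simulated chaperone knockdown, H2A.Z-positive promoters are the most
downregulated (median log2 fold change -1.13, planted -1.2) while
Zelda-dependent promoters are unchanged, and the RELACS double ratio
reports promoter H2A.Z at 0.525 of control (planted depletion 0.5 -
a 47% reduction). Compare against the planted truth with:

```r
evaluate_against_truth(run)
#> $activity_balanced_accuracy  0.998
#> $class_balanced_accuracy     zld 0.958, h2az_pos 1, ...
#> $max_fraction_error          0.008
write_report(run, "run_summary.json")
```

The methods vignette (`vignettes/zga-methods.Rmd`) documents the model
behind every stage, the thresholds and their defaults, and what the
synthetic data does and does not emulate.

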