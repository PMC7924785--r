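# decaylens

Transcriptome characterization of a 3'-5' RNA-decay mutant across a staged
oocyte-to-embryo time course.

During the oocyte-to-embryo transition the genome is transcriptionally
silent, so mRNA levels change only through decay. When the cytoplasmic RNA
exosome pathway (Ski complex / Ski7 adaptor) is lost, its substrates are
stabilized and acquire a recognizable composite signature. decaylens
implements the statistics that detect each facet of that signature in a
two-genotype (WT vs mutant), three-period (oogenesis O1–O4; mature eggs
UNA/ACT/FER; embryogenesis E1–E4), three-replicate RNA-seq design:

* **DEG calling** — per-period expression filter (≥ 10 CPM in ≥ 3
  libraries), a simplified negative-binomial exact test per stage
  (conditional negative-hypergeometric; Binomial(total, ½) at zero
  dispersion), Benjamini–Hochberg FDR, and the classification rules
  up / down (FDR < 0.05), unchanged (FDR > 0.05, 0.8 < FC < 1.2).
* **Overlap vs expression-matched nulls** — sharing of DEG sets within and
  between periods compared against control sets of unchanged genes matched
  on wild-type expression (20 quantile bins, resampled), with a
  Yates-corrected χ² on proportions and an empirical resampling quantile.
* **3'-bias statistics** — metagene 100-bin coverage profiles (proportional
  binning, per-transcript mean normalization) and per-region read densities
  (reads / region length; boundary-spanning reads counted in both regions;
  both-zero ratios excluded), with Wilcoxon tests of mutant vs WT densities.
* **Transcript features** — region lengths from the longest isoform (KS
  tests), codon adaptation index CAI = exp(mean ln w), w = freq / max
  synonymous-family freq (stops and single-codon families excluded), with a
  random-sequence background, and Wilcoxon comparisons of wild-type TPM per
  DEG class.
* **Synthetic-data generator** — negative-binomial counts, annotation, CDS
  sequences and positionally biased coverage that inject all of the above
  signatures with known truth labels, so the entire pipeline is testable
  with no external data.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → DE → overlap → coverage → features), each writing its tables to
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_overlap_analysis.R
Rscript analysis/04_coverage_profiles.R
Rscript analysis/05_transcript_features.R
```

At the default seed (11) the run prints, among others:

```
stabilized set:  200 genes (median WT abundance rank 366 of 2000)

up-class mutant/WT density ratios by region:
 region   n median_ratio     wilcox_p
   utr5 195    0.7948718 6.416213e-02
    cds 195    2.7759857 1.131301e-12
   utr3 195    7.5208333 2.925307e-36

CAI: up median 0.750 vs unchanged 0.809 (KS D 0.98, p 0.00e+00)

wild-type TPM of DEG classes vs unchanged:
 group   n n_unchanged median_group median_unchanged statistic       pvalue
    up 195        1207     41.29984         192.9734     45836 1.072875e-42
```

Reading: the 200 simulated decay targets are recovered as up-regulated DEGs
in their stabilized periods (> 97% of gene-by-stage calls); they sit ~4.7×
below unchanged genes in wild-type expression; their mutant/WT read-density
ratio climbs monotonically toward the 3'UTR (0.79 → 2.78 → 7.52, the
3'-5'-decay-loss signature); and their codon adaptation is clearly below
both unchanged genes and the random-sequence background.

The same computations are available programmatically via `run_pipeline()`:

```r
library(decaylens)
report <- run_pipeline(run_config(seed = 11))
report$density$region_tests
```

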