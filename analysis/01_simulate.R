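#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data set.
#
# Emulates the RNA-seq design of the decay-mutant time course: 2 genotypes
# (WT, mut) x 11 stages across 3 periods (oogenesis O1-O4, mature eggs
# UNA/ACT/FER, embryogenesis E1-E4) x 3 replicates, 2000 genes. 10% of genes
# are "stabilized" decay targets: drawn preferentially from low wild-type
# expression, 4-fold up in the mutant during eggs and embryogenesis,
# 3'-biased in mutant coverage, and enriched for rare codons.

library(decaylens)

seed <- 11
out <- "results/sim"

sim <- write_simulation(sim_params(seed = seed), out)

truth <- sim$counts$truth
cat("genes:          ", nrow(sim$annotation$models), "\n")
cat("samples:        ", nrow(sim$counts$design), "\n")
cat("stabilized set: ", sum(truth$stabilized), "genes (median WT abundance rank",
    round(median(rank(truth$baseline)[truth$stabilized])), "of",
    nrow(truth), ")\n")
cat("files written to", out, "\n")
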