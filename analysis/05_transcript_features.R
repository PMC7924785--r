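#!/usr/bin/env Rscript
# Stage 5: transcript features of the DEG classes — region lengths (KS),
# codon adaptation index with a random-sequence background, and wild-type
# expression levels (Wilcoxon vs unchanged genes).

library(decaylens)

seed <- 11
models <- select_longest_isoform(parse_gtf("results/sim/annotation.gtf"))
cds <- read_cds_fasta("results/sim/cds.fa")
usage <- load_codon_usage("results/sim/codon_usage.tsv")
deg <- import_deg_table("results/deg_table.tsv")
counts_tab <- read.delim("results/sim/counts.tsv", check.names = FALSE)
counts <- as.matrix(counts_tab[, -1]); rownames(counts) <- counts_tab$gene_id
design <- read.delim("results/sim/design.tsv", stringsAsFactors = FALSE)

rep_stage <- design_periods()[["M"]][1]
cls_stage <- deg[deg$stage == rep_stage, ]
classes <- setNames(cls_stage$class, cls_stage$gene_id)
unch <- names(classes)[classes == "unchanged"]

lens <- region_lengths(models)
rownames(lens) <- lens$gene_id
len_rows <- list()
for (feat in c("full", "utr5", "cds", "utr3")) {
  for (cl in c("up", "down")) {
    gs <- names(classes)[classes == cl]
    if (length(gs) < 3) next
    ks <- ks_compare(lens[gs, feat], lens[unch, feat])
    len_rows[[paste(feat, cl)]] <- data.frame(
      feature = feat, group = cl, D = ks$D, pvalue = ks$pvalue,
      median_group = median(lens[gs, feat]),
      median_unchanged = median(lens[unch, feat]))
  }
}
len_res <- do.call(rbind, len_rows)
write.table(len_res, "results/length_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cai_tab <- cai_all(cds, usage)
cai_tab$gene_id <- models$gene_id[match(cai_tab$transcript_id,
                                        models$transcript_id)]
write.table(cai_tab, "results/cai_per_gene.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cai_of <- setNames(cai_tab$cai, cai_tab$gene_id)
up <- intersect(names(classes)[classes == "up"], names(cai_of))
ks <- ks_compare(cai_of[up], cai_of[unch])
bg <- cai_background(usage, length(up),
                     round(mean(models$cds_len[models$gene_id %in% up] / 3)),
                     seed = seed)
cat(sprintf("CAI: up median %.3f vs unchanged %.3f (KS D %.2f, p %.2e)\n",
            median(cai_of[up]), median(cai_of[unch]), ks$D, ks$pvalue))
cat(sprintf("random-sequence background median %.3f [5%%-95%%: %.3f-%.3f]\n",
            bg$quantiles[3], bg$quantiles[1], bg$quantiles[5]))

tx_len <- setNames(models$tx_len, models$gene_id)
tp <- tpm(counts, tx_len)
wt_sel <- design$sample[design$stage == rep_stage & design$genotype == "WT"]
cmp <- expression_level_compare(rowMeans(tp[, wt_sel]), classes)
write.table(cmp, "results/expression_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwild-type TPM of DEG classes vs unchanged:\n")
print(cmp, row.names = FALSE)
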