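test_that("identical parameters and seed reproduce outputs byte-for-byte", {
  p <- sim_params(n_genes = 40, seed = 7)
  a1 <- simulate_annotation(p)
  a2 <- simulate_annotation(p)
  expect_identical(a1$cds, a2$cds)
  c1 <- simulate_counts(a1$models, p)
  c2 <- simulate_counts(a2$models, p)
  expect_identical(c1$counts, c2$counts)
  v1 <- simulate_coverage(a1$models, c1$truth, p)
  v2 <- simulate_coverage(a2$models, c2$truth, p)
  expect_identical(lapply(v1$mut, `[[`, "reads"), lapply(v2$mut, `[[`, "reads"))
  f1 <- tempfile(); f2 <- tempfile()
  write_cds_fasta(a1$cds, f1); write_cds_fasta(a2$cds, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("without codon bias, simulated codon frequencies follow the usage table", {
  usage <- default_codon_usage()
  p <- sim_params(n_genes = 120, codon_bias = 0, stabilized_fraction = 0.5,
                  cds_codons_meanlog = log(1000), cds_codons_sdlog = 0.05,
                  seed = 3)
  ann <- simulate_annotation(p, usage)
  cds <- paste(ann$cds, collapse = "")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  # drop the deterministic start and sampled stop codons from the check
  inner <- codons[!codons %in% c("ATG", "TAA", "TAG", "TGA")]
  expect_gt(length(inner), 1e5)
  sense <- names(usage$freq)[usage$code != "*"]
  sense <- setdiff(sense, "ATG")
  obs <- table(factor(inner, levels = sense))
  expected_p <- usage$freq[sense] / sum(usage$freq[sense])
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = expected_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("counts approach the Poisson limit as dispersion goes to zero", {
  p <- sim_params(n_genes = 1000, dispersion = 0, stabilized_fraction = 0,
                  baseline_sdlog = 0, lib_sdlog = 0, seed = 9)
  ann <- simulate_annotation(p)
  cnt <- simulate_counts(ann$models, p)
  x <- cnt$counts[, cnt$design$sample[1:66]]
  # with identical means everywhere, each gene's counts are iid Poisson
  m <- rowMeans(x)
  v <- apply(x, 1, var)
  expect_gt(mean(m), 100)
  ratio <- mean(v) / mean(m)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("stabilized fold change is the null at 1 and recovered at 4", {
  p1 <- sim_params(n_genes = 300, stabilized_fc = 1, seed = 21)
  ann <- simulate_annotation(p1)
  cnt <- simulate_counts(ann$models, p1)
  cc <- cpm(cnt$counts)
  wt <- rowMeans(cc[, cnt$design$genotype == "WT"])
  mu <- rowMeans(cc[, cnt$design$genotype == "mut"])
  keep <- wt > 50
  expect_lt(abs(median(mu[keep] / wt[keep]) - 1), 0.05)

  # fixed conditions: every gene at NB mean 100, fc = 4 in the mutant
  p4 <- sim_params(n_genes = 300, stabilized_fc = 4, stabilized_fraction = 0.5,
                   stabilized_low_expression_weight = 0, dispersion = 0.01,
                   baseline_sdlog = 0, lib_meanlog = log(3e4), lib_sdlog = 0,
                   seed = 22)
  ann4 <- simulate_annotation(p4)
  cnt4 <- simulate_counts(ann4$models, p4)
  des <- cnt4$design
  m_sel <- des$sample[des$genotype == "mut" & des$period == "M"]
  stab <- cnt4$truth$stabilized
  draws <- cnt4$counts[stab, m_sel]          # > 1000 replicate draws at mu=400
  expect_gt(length(draws), 1000)
  expect_lt(abs(mean(draws) - 400) / 400, 0.05)
})

test_that("read starts are uniform without 3' bias and 3'-shifted with it", {
  p0 <- sim_params(n_genes = 60, bias3 = 0, stabilized_fraction = 1,
                   reads_per_gene = 400, seed = 31)
  ann <- simulate_annotation(p0)
  cnt <- simulate_counts(ann$models, p0)
  cov <- simulate_coverage(ann$models, cnt$truth, p0)
  half_depths <- function(tracks) {
    t(vapply(tracks, function(tr) {
      L <- length(tr$depth)
      h <- floor(L / 2)
      c(sum(tr$depth[1:h]), sum(tr$depth[(h + 1):L]))
    }, numeric(2)))
  }
  hd <- half_depths(cov$mut)
  expect_gt(sum(hd), 1e4 * 100)          # >= 1e4 reads of length 100 placed
  ratio <- sum(hd[, 1]) / sum(hd[, 2])
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)

  p5 <- sim_params(n_genes = 60, bias3 = 5, stabilized_fraction = 1,
                   reads_per_gene = 400, seed = 32)
  ann5 <- simulate_annotation(p5)
  cnt5 <- simulate_counts(ann5$models, p5)
  cov5 <- simulate_coverage(ann5$models, cnt5$truth, p5)
  st5 <- unlist(lapply(names(cov5$mut), function(tid) {
    L <- ann5$models$tx_len[ann5$models$transcript_id == tid]
    tr <- cov5$mut[[tid]]
    if (nrow(tr$reads) == 0) return(numeric(0))
    tr$reads[, "start"] / L
  }))
  expect_gt(mean(st5 >= 0.5), 0.8)       # >80% of read starts in the 3' half
})

test_that("zero-expression genes get empty coverage tracks", {
  p <- sim_params(n_genes = 20, seed = 41, reads_per_gene = 50)
  ann <- simulate_annotation(p)
  truth <- simulate_counts(ann$models, p)$truth
  truth$baseline[1] <- 0
  cov <- suppressWarnings(simulate_coverage(ann$models, truth, p))
  expect_equal(nrow(cov$WT[[1]]$reads), 0)
  expect_true(all(cov$WT[[1]]$depth == 0))
})

test_that("stabilized genes concentrate at low wild-type expression", {
  sim <- default_sim()
  tr <- sim$truth
  expect_lt(median(tr$baseline[tr$stabilized]),
            median(tr$baseline[!tr$stabilized]))
  w <- suppressWarnings(wilcox.test(tr$baseline[tr$stabilized],
                                    tr$baseline[!tr$stabilized]))
  expect_lt(w$p.value, 1e-10)
})

test_that("simulated CDSes start with ATG, end with a stop, length multiple of 3", {
  sim <- default_sim()
  cds <- sim$cds[1:100]
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  last <- substring(cds, nchar(cds) - 2, nchar(cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
})

test_that("write_simulation emits a complete, re-loadable file set", {
  dir <- tempfile()
  p <- sim_params(n_genes = 25, seed = 51)
  sim <- write_simulation(p, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "annotation.gtf", "cds.fa", "counts.tsv", "design.tsv",
    "truth_labels.tsv", "codon_usage.tsv",
    "reads_WT.bed", "reads_mut.bed",
    "coverage_WT.bedGraph", "coverage_mut.bedGraph")))))
  m <- parse_gtf(file.path(dir, "annotation.gtf"))
  expect_equal(nrow(m), 25L)
  u <- load_codon_usage(file.path(dir, "codon_usage.tsv"))
  expect_equal(length(u$freq), 64L)
  cnt <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  expect_equal(dim(cnt), c(25L, 67L))  # gene_id + 66 samples
})
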