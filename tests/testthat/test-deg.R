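test_that("cpm scales columns to one million", {
  x <- matrix(c(5, 15, 80), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.vector(cpm(x)), c(50000, 150000, 800000))
  y <- cbind(s1 = c(0, 10), s2 = c(0, 5))
  rownames(y) <- c("zero", "g")
  expect_equal(cpm(y)["zero", ], c(s1 = 0, s2 = 0))
  expect_true(all(abs(colSums(cpm(y)) - 1e6) < 1e-6 * 1e6))
  bad <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  colnames(bad) <- c("s1", "szero")
  expect_error(cpm(bad), "szero")
})

test_that("tpm normalizes by length then library", {
  x <- matrix(c(10, 10), ncol = 1, dimnames = list(c("g1", "g2"), "s"))
  tp <- tpm(x, c(g1 = 1000, g2 = 2000))
  expect_equal(as.vector(tp), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # equal lengths: TPM proportional to CPM
  x2 <- matrix(c(3, 7, 10, 30), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  tp2 <- tpm(x2, c(g1 = 500, g2 = 500))
  expect_equal(tp2, cpm(x2))
  # single expressed gene takes the full million
  x3 <- matrix(c(5, 0), ncol = 1, dimnames = list(c("g1", "g2"), "s"))
  expect_equal(unname(tpm(x3, c(g1 = 100, g2 = 100))["g1", ]), 1e6)
  expect_warning(tpm(x, c(g1 = 1000)), "dropped")
})

test_that("expression filter requires the CPM threshold in enough libraries", {
  # 6 libraries of one period; thresholds are inclusive on both margins
  mk <- function(v) {
    counts <- rbind(gene = v, filler = 1e6 - v)
    colnames(counts) <- paste0("s", 1:6)
    counts
  }
  design <- data.frame(sample = paste0("s", 1:6), period = "O")
  pass <- mk(c(12, 11, 10, 0, 0, 0))   # cpm == count here (lib 1e6)
  expect_true("gene" %in% filter_expressed(pass, design, "O"))
  fail <- mk(c(12, 11, 9.9, 0, 0, 0))
  expect_false("gene" %in% filter_expressed(fail, design, "O"))
  expect_false("gene" %in% filter_expressed(mk(rep(0, 6)), design, "O"))
  expect_error(filter_expressed(pass, design[1:2, ], "O"), "fewer than")
})

test_that("nb_test matches the exact binomial at zero dispersion", {
  r <- nb_test(10, 0, dispersion = 0)
  expect_equal(r$pvalue, 2 * 0.5^10)
  r2 <- nb_test(c(3, 4, 3), c(3, 3, 4), dispersion = 0)
  expect_gte(r2$pvalue, 0.999)
  expect_equal(r2$log2fc, 0)
  r3 <- nb_test(30, 60, dispersion = 0)
  expect_equal(r3$log2fc, log2(60.5 / 30.5), tolerance = 1e-12)
  rz <- nb_test(c(0, 0), c(0, 0), dispersion = 0.1)
  expect_equal(rz$pvalue, 1)
  expect_equal(rz$flag, "all_zero")
})

test_that("nb_test is symmetric under group swap", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnbinom(3, mu = 50, size = 10)
    b <- rnbinom(3, mu = 120, size = 10)
    d <- runif(1, 0, 0.3)
    r1 <- nb_test(a, b, dispersion = d)
    r2 <- nb_test(b, a, dispersion = d)
    expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-12)
    expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches worked example and the reference oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_true(all(bh_adjust(c(0.5, 0.01, 0.9)) >= c(0.5, 0.01, 0.9)))
  set.seed(7)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("gene classification follows the FDR/fold-change rules exhaustively", {
  expect_equal(classify_genes(0.03, 1.6), "up")
  expect_equal(classify_genes(0.03, 0.5), "down")
  expect_equal(classify_genes(0.2, 1.1), "unchanged")
  expect_equal(classify_genes(0.2, 1.5), "other")
  expect_equal(classify_genes(0.2, 0.8), "other")   # window is open
  set.seed(13)
  cls <- classify_genes(runif(500), exp(rnorm(500)))
  expect_true(all(cls %in% c("up", "down", "unchanged", "other")))
})

test_that("DEG calling recovers stabilized genes and controls type I direction", {
  sim <- default_sim()
  deg <- sim$deg
  stab <- sim$truth$gene_id[sim$truth$stabilized]
  hit <- deg[deg$period %in% c("M", "E") & deg$gene_id %in% stab, ]
  expect_gt(mean(hit$class == "up"), 0.7)
  # in the un-stabilized period the same genes are not systematically up
  null_p <- deg[deg$period == "O" & deg$gene_id %in% stab, ]
  expect_lt(mean(null_p$class == "up", na.rm = TRUE), 0.1)
  # every tested gene lands in exactly one class
  expect_true(all(table(deg$gene_id, deg$stage) == 1))
})

test_that("PCA embedding is deterministic and stable under sample duplication", {
  sim <- default_sim()
  counts <- sim$counts[, 1:12]
  p1 <- pca_embed(counts, n_top = 500)
  expect_equal(p1$scores, pca_embed(counts, n_top = 500)$scores)
  expect_lte(sum(p1$var_explained), 1 + 1e-12)
  # identical samples coincide in the embedding
  dup <- cbind(counts, dup1 = counts[, 1])
  p2 <- pca_embed(dup, n_top = 500)
  expect_lt(sum((p2$scores[1, 1:2] - p2$scores[13, 1:2])^2), 1e-12)
  # duplicating every sample leaves the leading gene-loading subspace intact
  p3 <- pca_embed(cbind(counts, counts), n_top = 500)
  v1 <- p1$rotation[, 1:2]
  v3 <- p3$rotation[, 1:2]
  # principal angles via singular values of V1' V3
  sv <- svd(t(v1) %*% v3)$d
  expect_lt(max(abs(sv - 1)), 1e-8)
  expect_warning(pca_embed(counts[1:50, ], n_top = 1000), "fewer genes")
})
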