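test_that("bin_profile: flat coverage gives flat unit profile", {
  tr <- coverage_track("t", rep(3.5, 237))
  bp <- bin_profile(tr)
  expect_equal(length(bp), 100L)
  expect_equal(bp, rep(1, 100), tolerance = 1e-12)
})

test_that("bin_profile: 3'-half coverage yields 0/2 split after normalization", {
  tr <- coverage_track("t", c(rep(0, 100), rep(2, 100)))
  bp <- bin_profile(tr)
  expect_equal(bp[1:50], rep(0, 50))
  expect_equal(bp[51:100], rep(2, 50))
})

test_that("bin_profile excludes short and all-zero transcripts", {
  expect_null(bin_profile(coverage_track("t", rep(1, 99))))
  expect_null(bin_profile(coverage_track("t", rep(0, 500))))
})

test_that("binning conserves total coverage at fractional lengths", {
  set.seed(21)
  for (L in c(100, 101, 137, 250, 999)) {
    depth <- rpois(L, 3)
    if (sum(depth) == 0) depth[1] <- 1
    tr <- coverage_track("t", depth)
    raw <- bin_profile(tr, normalize = FALSE)
    expect_equal(sum(raw * L / 100), sum(depth), tolerance = 1e-9)
    norm <- bin_profile(tr)
    expect_equal(mean(norm), 1, tolerance = 1e-9)
  }
})

test_that("metagene of one gene equals its bin profile; flat sets stay flat", {
  tracks <- list(t1 = coverage_track("t1", rep(2, 150)),
                 t2 = coverage_track("t2", c(rep(1, 100), rep(3, 100))))
  mg1 <- metagene(tracks, "t2")
  expect_equal(mg1$profile, bin_profile(tracks$t2))
  flat <- metagene(tracks, "t1")
  expect_equal(flat$profile, rep(1, 100), tolerance = 1e-12)
  expect_error(metagene(tracks, character(0)), "no usable")
})

test_that("metagene recovers the injected mutant 3' bias and a flat WT", {
  sim <- default_sim()
  stab_tx <- sim$models$transcript_id[sim$truth$stabilized]
  mg_mut <- metagene(sim$cov$mut, stab_tx)
  mg_wt <- metagene(sim$cov$WT, stab_tx)
  expect_gt(mg_mut$profile[90], mg_mut$profile[10])
  expect_lt(abs(mg_wt$profile[90] - mg_wt$profile[10]), 0.25)
})

test_that("reads spanning a region boundary are counted for both regions", {
  regions <- list(utr5 = c(0L, 60L), cds = c(60L, 360L), utr3 = c(360L, 500L))
  inside <- matrix(c(250L, 350L), 1, dimnames = list(NULL, c("start", "end")))
  expect_equal(count_reads_by_region(inside, regions),
               c(utr5 = 0, cds = 1, utr3 = 0))
  spanning <- matrix(c(350L, 380L), 1, dimnames = list(NULL, c("start", "end")))
  expect_equal(count_reads_by_region(spanning, regions),
               c(utr5 = 0, cds = 1, utr3 = 1))
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  expect_equal(count_reads_by_region(empty, regions),
               c(utr5 = 0, cds = 0, utr3 = 0))
})

test_that("region counts sum to at least the read count", {
  sim <- default_sim()
  models <- sim$models[1:30, ]
  for (i in seq_len(nrow(models))) {
    tr <- sim$cov$mut[[models$transcript_id[i]]]
    cnt <- count_reads_by_region(tr$reads, region_map(models, models$transcript_id[i]))
    expect_gte(sum(cnt), nrow(tr$reads))
  }
})

test_that("density ratios follow the density definition and exclusion rules", {
  mk <- function(gene, reads) data.frame(
    gene_id = gene, region = c("utr5", "cds", "utr3"),
    reads = reads, length = c(100, 300, 100),
    density = reads / c(100, 300, 100), stringsAsFactors = FALSE)
  wt <- mk("g", c(10, 30, 20))
  mut <- mk("g", c(10, 60, 60))
  rr <- region_density_ratio(wt, mut)
  expect_equal(rr$ratio[match(c("utr5", "cds", "utr3"), rr$region)],
               c(1, 2, 3))
  # both-zero -> excluded; WT-zero -> excluded and tallied separately
  wt2 <- mk("g2", c(0, 0, 5)); mut2 <- mk("g2", c(0, 4, 10))
  rr2 <- region_density_ratio(wt2, mut2)
  expect_true(is.na(rr2$ratio[rr2$region == "utr5"]))
  expect_equal(rr2$reason[rr2$region == "utr5"], "both_zero")
  expect_true(is.na(rr2$ratio[rr2$region == "cds"]))
  expect_equal(rr2$reason[rr2$region == "cds"], "wt_zero")
  expect_equal(rr2$ratio[rr2$region == "utr3"], 2)
})

test_that("adding 3'UTR reads raises only the 3'UTR ratio", {
  mk <- function(reads) data.frame(
    gene_id = "g", region = c("utr5", "cds", "utr3"),
    reads = reads, length = c(100, 300, 100),
    density = reads / c(100, 300, 100), stringsAsFactors = FALSE)
  wt <- mk(c(10, 30, 10))
  r1 <- region_density_ratio(wt, mk(c(10, 30, 10)))
  r2 <- region_density_ratio(wt, mk(c(10, 30, 25)))
  expect_gt(r2$ratio[r2$region == "utr3"], r1$ratio[r1$region == "utr3"])
  expect_equal(r2$ratio[r2$region == "utr5"], r1$ratio[r1$region == "utr5"])
})

test_that("region density Wilcoxon behaves at the null and under a shift", {
  x <- rlnorm(100, 0, 0.5)
  same <- compare_region_densities(x, x)
  expect_gte(same$pvalue, 0.99)
  shift <- compare_region_densities(x, 2 * x)
  expect_lt(shift$pvalue, 1e-6)
  small <- compare_region_densities(c(1, 2), c(1, 2, 3))
  expect_equal(small$flag, "too_few")
  expect_true(is.na(small$pvalue))
})

test_that("up-regulated genes show the 3'-biased density-ratio signature", {
  sim <- default_sim()
  dens_wt <- region_density(sim$cov$WT, sim$models)
  dens_mut <- region_density(sim$cov$mut, sim$models)
  rr <- region_density_ratio(dens_wt, dens_mut)
  rep_stage <- design_periods()[["M"]][1]
  cls <- sim$deg[sim$deg$stage == rep_stage, ]
  up <- cls$gene_id[cls$class == "up"]
  r3 <- rr$ratio[rr$region == "utr3" & rr$gene_id %in% up]
  r5 <- rr$ratio[rr$region == "utr5" & rr$gene_id %in% up]
  expect_gt(median(r3, na.rm = TRUE), median(r5, na.rm = TRUE))
  w3 <- compare_region_densities(
    dens_wt$density[dens_wt$region == "utr3" & dens_wt$gene_id %in% up],
    dens_mut$density[dens_mut$region == "utr3" & dens_mut$gene_id %in% up])
  expect_lt(w3$pvalue, 0.01)
  expect_gt(w3$median_mut, w3$median_wt)
})
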