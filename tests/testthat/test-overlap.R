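test_that("shared_degs counts exact intersections", {
  s <- shared_degs(list(x = c("A", "B", "C"), y = c("B", "C", "D")))
  expect_equal(s$pairwise$shared, 2L)
  ident <- shared_degs(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(ident$pairwise$shared, 5L)
  expect_equal(ident$all, 5L)
  tri <- shared_degs(list(a = c("1", "2"), b = c("2", "3"), c = c("3", "1")))
  expect_equal(tri$all, 0L)
})

test_that("matched controls reproduce the DEG set's expression bin histogram", {
  set.seed(5)
  expr <- setNames(rlnorm(2200, 3, 1.5), paste0("g", 1:2200))
  deg <- paste0("g", 1:200)
  pool <- paste0("g", 201:2200)
  ctl <- sample_expression_matched(deg, pool, expr)
  expect_equal(length(ctl$controls), length(deg))
  expect_true(all(ctl$controls %in% pool))         # disjoint from DEGs
  expect_equal(anyDuplicated(ctl$controls), 0L)    # without replacement
  # with a large pool there are no fallback moves and histograms match exactly
  expect_equal(nrow(ctl$moves), 0L)
  expect_equal(tabulate(ctl$bin_control, 20), tabulate(ctl$bin_deg, 20))
  expect_error(sample_expression_matched(deg, pool[1:100], expr), "smaller")
  expect_error(sample_expression_matched(deg, c(deg[1], pool), expr), "overlaps")
})

test_that("controls match the expression distribution of a low-tail DEG set", {
  set.seed(6)
  expr <- setNames(rlnorm(10000, 3, 1.5), paste0("g", 1:10000))
  low <- names(sort(expr))[1:2000]                # low-expression quintile
  deg <- sample(low, 200)
  pool <- setdiff(names(expr), deg)
  ok <- 0L
  for (r in 1:100) {
    ctl <- sample_expression_matched(deg, pool, expr)
    ks <- suppressWarnings(ks.test(expr[ctl$controls], expr[deg]))
    ok <- ok + (ks$p.value > 0.1)
  }
  expect_gte(ok, 95)
})

test_that("Yates chi-squared closed form matches hand value and stats oracle", {
  cs <- overlap_chisq(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(cs$statistic, 5.4, tolerance = 1e-12)
  even <- overlap_chisq(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$pvalue, 1)
  set.seed(8)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    mine <- overlap_chisq(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$pvalue, unname(ref$p.value), tolerance = 1e-8)
  }
  expect_error(overlap_chisq(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("chi-squared statistic is invariant under row and column swaps", {
  set.seed(9)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    s0 <- overlap_chisq(tab)$statistic
    expect_equal(overlap_chisq(tab[2:1, ])$statistic, s0, tolerance = 1e-12)
    expect_equal(overlap_chisq(tab[, 2:1])$statistic, s0, tolerance = 1e-12)
  }
})

test_that("overlap significance flags a fully nested DEG pair as extreme", {
  set.seed(10)
  expr <- setNames(c(rlnorm(100, 0, 0.1), rlnorm(2000, 5, 0.1)),
                   paste0("g", 1:2100))
  A <- paste0("g", 1:100)            # low-expression island
  B <- A                             # A subset of B
  pool <- paste0("g", 101:2100)      # disjoint, higher expression
  ov <- overlap_significance(A, B, pool, expr, n_resamples = 50, seed = 4)
  expect_equal(ov$observed, 100L)
  expect_lt(ov$pvalue, 1e-6)
  expect_equal(ov$quantile, 1.0)
  expect_error(overlap_significance(A, B, pool, expr, n_resamples = 0),
               "n_resamples")
})

test_that("resampling is reproducible under a fixed seed", {
  set.seed(11)
  expr <- setNames(rlnorm(1100), paste0("g", 1:1100))
  A <- paste0("g", 1:50); B <- paste0("g", 30:80)
  pool <- paste0("g", 101:1100)
  o1 <- overlap_significance(A, B, pool, expr, n_resamples = 20, seed = 99)
  o2 <- overlap_significance(A, B, pool, expr, n_resamples = 20, seed = 99)
  expect_identical(o1$control_shared, o2$control_shared)
  expect_identical(o1$quantile_rand, o2$quantile_rand)
})

test_that("under the null the overlap test rejects near its nominal rate", {
  set.seed(12)
  n_pairs <- 500
  expr <- setNames(rlnorm(1200, 3, 1), paste0("g", 1:1200))
  ids <- names(expr)
  rej <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    A <- sample(ids, 40)
    B <- sample(ids, 40)
    pool <- setdiff(ids, A)
    ov <- overlap_significance(A, B, pool, expr, n_resamples = 99,
                               seed = 1000 + i)
    rej[i] <- ov$quantile_rand > 0.975 || ov$quantile_rand < 0.025
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})

test_that("expression breadth counts filter-passing periods", {
  passed <- rbind(g1 = c(TRUE, TRUE, FALSE),
                  g2 = c(FALSE, FALSE, FALSE),
                  g3 = c(TRUE, TRUE, TRUE))
  colnames(passed) <- c("O", "M", "E")
  br <- expression_breadth(passed)
  expect_equal(br$breadth, c(2L, 0L, 3L))
  expect_equal(br$periods[1], "O,M")
  expect_true(br$not_identified[2])
})

test_that("cross-period status follows DEG > unchanged > other precedence", {
  deg <- data.frame(
    gene_id = "g1",
    period = c("O", "O", "M", "M", "M"),
    stage = c("O1", "O2", "UNA", "ACT", "FER"),
    class = c("up", "up", "unchanged", "unchanged", "unchanged"),
    stringsAsFactors = FALSE
  )
  expect_equal(cross_period_status(deg, "g1", "O", "M"), "unchanged")
  deg$class[5] <- "up"
  expect_equal(cross_period_status(deg, "g1", "O", "M"), "DEG")
  deg$class[3:5] <- "filtered"
  expect_equal(cross_period_status(deg, "g1", "O", "M"), "untested")
  expect_equal(cross_period_status(deg, "g1", "O", "E"), "untested")
  deg$class[1:2] <- "unchanged"
  expect_error(cross_period_status(deg, "g1", "O", "M"), "not a DEG")
})
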