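#' Intersection counts of DEG sets
#'
#' Pairwise and k-way intersection cardinalities of gene sets.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return list with `pairwise` (data.frame set_a, set_b, shared,
#'   frac_of_a = shared/|A|) and `all` (size of the intersection of every
#'   set).
#' @export
shared_degs <- function(sets) {
  stopifnot(length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  cmb <- utils::combn(names(sets), 2)
  pw <- data.frame(
    set_a = cmb[1, ], set_b = cmb[2, ],
    shared = apply(cmb, 2, function(ab) {
      length(intersect(sets[[ab[1]]], sets[[ab[2]]]))
    }),
    stringsAsFactors = FALSE
  )
  pw$frac_of_a <- ifelse(lengths(sets)[pw$set_a] > 0,
                         pw$shared / lengths(sets)[pw$set_a], 0)
  list(pairwise = pw, all = length(Reduce(intersect, sets)))
}

#' Sample an expression-matched control set
#'
#' Draws, for each gene of a DEG set, one control gene from the pool of
#' unchanged genes with a matching wild-type expression level. Genes are
#' binned by quantiles of expression over the union of DEG set and pool into
#' `n_bins` bins; controls are sampled uniformly without replacement from the
#' DEG gene's bin. When a bin is exhausted the draw falls back to the nearest
#' non-empty bin and the move is recorded.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param deg_set character vector of DEG gene ids.
#' @param pool character vector of candidate control (unchanged) gene ids,
#'   disjoint from `deg_set`, at least as large.
#' @param expr named numeric vector of wild-type expression covering both.
#' @param n_bins number of quantile bins (default 20).
#' @return list with `controls` (character, same length as `deg_set`),
#'   `bin_deg`/`bin_control` (bin index per selected gene) and `moves`
#'   (data.frame of fallback moves: from_bin, to_bin).
#' @export
sample_expression_matched <- function(deg_set, pool, expr, n_bins = 20) {
  if (length(intersect(deg_set, pool)) > 0) stop("pool overlaps the DEG set")
  if (length(pool) < length(deg_set)) {
    stop("control pool (", length(pool), ") smaller than DEG set (",
         length(deg_set), ")")
  }
  all_ids <- c(deg_set, pool)
  e <- expr[all_ids]
  if (any(is.na(e))) stop("expression missing for some genes")
  br <- unique(quantile(e, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(e, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bins) <- all_ids
  bd <- bins[deg_set]
  bp <- bins[pool]
  nb <- length(br) - 1L
  avail <- split(pool, factor(bp, levels = seq_len(nb)))
  # randomize within-bin order once; then draws are simple pops
  avail <- lapply(avail, function(v) if (length(v) > 1) sample(v) else v)
  need <- tabulate(bd, nbins = nb)
  controls <- character(0)
  ctrl_bin <- integer(0)
  moves <- list()
  for (b in seq_len(nb)) {
    take <- min(need[b], length(avail[[b]]))
    if (take > 0) {
      controls <- c(controls, avail[[b]][seq_len(take)])
      ctrl_bin <- c(ctrl_bin, rep(b, take))
      avail[[b]] <- avail[[b]][-seq_len(take)]
    }
    deficit <- need[b] - take
    if (deficit > 0) {
      for (k in seq_len(deficit)) {
        # nearest non-empty bin, ties toward lower expression
        cand <- order(abs(seq_len(nb) - b), seq_len(nb))
        cand <- cand[lengths(avail)[cand] > 0]
        if (length(cand) == 0) stop("control pool exhausted")
        nb2 <- cand[1]
        controls <- c(controls, avail[[nb2]][1])
        ctrl_bin <- c(ctrl_bin, nb2)
        avail[[nb2]] <- avail[[nb2]][-1]
        moves[[length(moves) + 1L]] <- data.frame(from_bin = b, to_bin = nb2)
      }
    }
  }
  list(controls = controls,
       bin_deg = unname(bd),
       bin_control = ctrl_bin,
       moves = if (length(moves)) do.call(rbind, moves) else
         data.frame(from_bin = integer(0), to_bin = integer(0)))
}

#' Pearson chi-squared test with Yates continuity correction (2x2)
#'
#' Closed form: chi2 = N * (max(0, |ad - bc| - N/2))^2 /
#' ((a+b)(c+d)(a+c)(b+d)); p from the upper tail of chi-squared with 1 df.
#'
#' @param tab 2x2 matrix of non-negative integer counts; all margins must be
#'   positive.
#' @return list with `statistic` and `pvalue`.
#' @export
overlap_chisq <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-squared test undefined")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  stat <- n * max(0, abs(a * d - b * c) - n / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, pvalue = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Overlap of a DEG set with another set versus expression-matched controls
#'
#' Observed sharing |A intersect B| is compared with the sharing of
#' `n_resamples` expression-matched control sets drawn for A from the
#' unchanged pool. Reported are (i) a Yates-corrected chi-squared test of the
#' observed shared proportion against the mean matched-control shared
#' proportion and (ii) the empirical resampling quantile of the observed
#' count, both plain (fraction of control values <= observed) and randomized
#' (uniform on (0,1) under the null despite the discreteness of counts).
#'
#' @param deg_set_a,deg_set_b character vectors of gene ids.
#' @param pool unchanged-gene pool for matching (disjoint from `deg_set_a`).
#' @param expr named wild-type expression vector.
#' @param n_resamples number of matched control sets (>= 1).
#' @param seed integer seed for the resampling stream.
#' @param n_bins quantile bins for matching (default 20).
#' @return list of class `overlap_result`: observed count/fraction, control
#'   counts, chi-squared statistic and p (NA when a margin is zero), plain
#'   and randomized quantiles, n_resamples, seed.
#' @export
overlap_significance <- function(deg_set_a, deg_set_b, pool, expr,
                                 n_resamples = 100, seed = 1L, n_bins = 20) {
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  observed <- length(intersect(deg_set_a, deg_set_b))
  set.seed(seed)
  shared_ctrl <- vapply(seq_len(n_resamples), function(r) {
    ctl <- sample_expression_matched(deg_set_a, pool, expr, n_bins)
    length(intersect(ctl$controls, deg_set_b))
  }, numeric(1))
  nA <- length(deg_set_a)
  mc <- round(mean(shared_ctrl))
  tab <- matrix(c(observed, nA - observed, mc, nA - mc), 2, byrow = TRUE)
  cs <- tryCatch(overlap_chisq(tab),
                 error = function(e) list(statistic = NA_real_, pvalue = NA_real_))
  q_plain <- mean(shared_ctrl <= observed)
  q_rand <- (sum(shared_ctrl < observed) +
               runif(1) * (sum(shared_ctrl == observed) + 1)) / (n_resamples + 1)
  structure(list(
    observed = observed,
    observed_frac = if (nA > 0) observed / nA else 0,
    control_shared = shared_ctrl,
    control_mean = mean(shared_ctrl),
    statistic = cs$statistic, pvalue = cs$pvalue,
    quantile = q_plain, quantile_rand = q_rand,
    n_resamples = n_resamples, seed = seed
  ), class = "overlap_result")
}

#' Expression breadth of genes across periods
#'
#' Number of periods (out of the three) in which each gene passes the
#' expression filter in either genotype.
#'
#' @param passed logical matrix genes x periods (TRUE = passed the filter).
#' @return data.frame `gene_id`, `breadth` (0-3), `periods` (comma string);
#'   breadth 0 genes are flagged `not_identified`.
#' @export
expression_breadth <- function(passed) {
  stopifnot(is.matrix(passed) || is.data.frame(passed))
  passed <- as.matrix(passed)
  breadth <- rowSums(passed)
  data.frame(
    gene_id = rownames(passed),
    breadth = as.integer(breadth),
    periods = apply(passed, 1, function(r) paste(colnames(passed)[r], collapse = ",")),
    not_identified = breadth == 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Regulation status of a DEG in another period
#'
#' A gene that is a DEG in its home period is looked up in another period and
#' labelled by precedence: "DEG" if up or down at any stage of that period,
#' else "unchanged" if unchanged at at least one stage, else "untested" if it
#' never passed the filter there, else "other".
#'
#' @param deg a `deg_table` from [call_degs()].
#' @param gene gene id (must be a DEG at some stage of `home_period`).
#' @param home_period,other_period period ids.
#' @return one of "DEG", "unchanged", "other", "untested".
#' @export
cross_period_status <- function(deg, gene, home_period, other_period) {
  home <- deg[deg$gene_id == gene & deg$period == home_period, ]
  if (!any(home$class %in% c("up", "down"))) {
    stop(gene, " is not a DEG in period ", home_period)
  }
  cls <- deg$class[deg$gene_id == gene & deg$period == other_period]
  if (length(cls) == 0) return("untested")
  if (any(cls %in% c("up", "down"))) return("DEG")
  if (any(cls == "unchanged")) return("unchanged")
  if (all(cls == "filtered")) return("untested")
  "other"
}
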