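#' Counts per million
#'
#' @param counts genes x samples numeric matrix of raw counts.
#' @return matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  libs <- colSums(counts)
  zero <- libs == 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, libs, "/") * 1e6
}

#' Transcripts per million
#'
#' Length-normalized abundance: per-gene rate = count / length, scaled so each
#' column sums to 1e6. Genes without a length are dropped with a warning.
#'
#' @param counts genes x samples matrix.
#' @param lengths named vector of transcript lengths (nt) covering the genes.
#' @return matrix over the genes with lengths; columns sum to 1e6.
#' @export
tpm <- function(counts, lengths) {
  len <- lengths[rownames(counts)]
  missing <- is.na(len) | len <= 0
  if (any(missing)) {
    warning(sum(missing), " gene(s) without a valid length dropped from TPM")
    counts <- counts[!missing, , drop = FALSE]
    len <- len[!missing]
  }
  rate <- counts / len
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Expression filter of a period
#'
#' Keeps genes with at least `cpm_min` counts-per-million in at least
#' `min_libraries` libraries of the period, libraries pooled across genotypes
#' and stages (the two boundary cases both count: cpm exactly at the threshold
#' passes, and exactly `min_libraries` qualifying libraries pass).
#'
#' @param counts genes x samples matrix (all samples).
#' @param design design data.frame with columns `sample`, `period`.
#' @param period period id to filter in.
#' @param cpm_min CPM threshold (default 10).
#' @param min_libraries minimum qualifying libraries (default 3).
#' @return character vector of passing gene ids.
#' @export
filter_expressed <- function(counts, design, period, cpm_min = 10,
                             min_libraries = 3) {
  sel <- design$sample[design$period == period]
  if (length(sel) < min_libraries) {
    stop("period ", period, " has fewer than ", min_libraries, " libraries")
  }
  cc <- cpm(counts)[, sel, drop = FALSE]
  pass <- rowSums(cc >= cpm_min) >= min_libraries
  rownames(counts)[pass]
}

#' Simplified negative-binomial exact test for one gene
#'
#' Replicate counts are scaled to a common effective library size, summed per
#' group, and the wild-type group sum is tested conditionally on the total.
#' Under equal group means the conditional law of the group-A sum is negative
#' hypergeometric with shape `n_a/d` and `n_b/d` (d = dispersion); at d = 0 it
#' reduces to Binomial(total, n_a/(n_a+n_b)). Two-sided p doubles the smaller
#' tail (capped at 1). log2 fold change (mut over WT) uses
#' replicate-equalized group sums with pseudocount 0.5 per group.
#'
#' @param counts_wt,counts_mut replicate count vectors of the gene.
#' @param norm_wt,norm_mut per-replicate normalization factors (effective
#'   scaling to the reference library; default 1, i.e. already comparable).
#' @param dispersion NB dispersion (>= 0).
#' @return list with `log2fc`, `pvalue`, `flag` ("ok" or "all_zero").
#' @export
nb_test <- function(counts_wt, counts_mut, norm_wt = 1, norm_mut = 1,
                    dispersion = 0) {
  stopifnot(length(counts_wt) >= 1, length(counts_mut) >= 1, dispersion >= 0)
  sa <- round(sum(counts_wt * norm_wt))
  sb <- round(sum(counts_mut * norm_mut))
  if (sa == 0 && sb == 0) {
    return(list(log2fc = 0, pvalue = 1, flag = "all_zero"))
  }
  na <- length(counts_wt); nb <- length(counts_mut)
  t <- sa + sb
  if (dispersion == 0) {
    pr <- na / (na + nb)
    lo <- pbinom(sa, t, pr)
    hi <- pbinom(sa - 1, t, pr, lower.tail = FALSE)
  } else {
    ra <- na / dispersion; rb <- nb / dispersion
    k <- 0:t
    lw <- lgamma(k + ra) - lgamma(k + 1) + lgamma(t - k + rb) - lgamma(t - k + 1)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    lo <- sum(w[k <= sa])
    hi <- sum(w[k >= sa])
  }
  p <- min(1, 2 * min(lo, hi))
  K <- max(na, nb)
  log2fc <- log2((sb * K / nb + 0.5) / (sa * K / na + 0.5))
  list(log2fc = log2fc, pvalue = p, flag = "ok")
}

#' Method-of-moments common NB dispersion
#'
#' Per gene, the pooled within-group variance v and mean m of normalized
#' counts satisfy E[v] = m + phi m^2 under the NB model; the common
#' dispersion is the pooled moment estimate sum(v - m) / sum(m^2) over genes
#' with mean >= `min_mean`, floored at 0. Pooling weights well-measured
#' genes most, is nearly unbiased, and is stable at small replicate numbers.
#'
#' @param counts genes x samples matrix.
#' @param groups factor/character vector of group labels per sample.
#' @param norm per-sample normalization factors (reference/library).
#' @param min_mean minimum normalized mean for a gene to contribute.
#' @return scalar dispersion >= 0.
#' @export
estimate_dispersion <- function(counts, groups, norm = NULL, min_mean = 1) {
  if (is.null(norm)) {
    libs <- colSums(counts)
    norm <- exp(mean(log(libs))) / libs
  }
  x <- sweep(counts, 2, norm, "*")
  groups <- as.character(groups)
  gl <- unique(groups)
  df <- 0
  mean_all <- rowMeans(x)
  ssr <- numeric(nrow(x))
  for (g in gl) {
    xs <- x[, groups == g, drop = FALSE]
    ng <- ncol(xs)
    if (ng < 2) next
    mg <- rowMeans(xs)
    ssr <- ssr + rowSums((xs - mg)^2)
    df <- df + ng - 1
  }
  if (df == 0) stop("no group with >= 2 replicates; cannot estimate dispersion")
  v <- ssr / df
  keep <- mean_all >= min_mean
  if (!any(keep)) return(0)
  max(0, sum(v[keep] - mean_all[keep]) / sum(mean_all[keep]^2))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in [0, 1] (NAs propagated).
#' @return FDR vector, elementwise >= the input p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  n <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (n > 0) {
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
    out[ok] <- q
  }
  out
}

#' Classify tested genes into DEG categories
#'
#' up: FDR < `alpha` and FC > 1; down: FDR < `alpha` and FC < 1; unchanged:
#' FDR > `alpha` and FC strictly inside the `unchanged_window`; everything
#' else tested is "other". Genes failing the expression filter are labelled
#' "filtered" upstream. The five classes are exhaustive and mutually
#' exclusive.
#'
#' @param fdr,fc vectors of FDR and (linear) fold change mut/WT.
#' @param alpha DEG threshold on FDR (default 0.05, strict <).
#' @param unchanged_window open FC interval of unchanged genes, default
#'   (0.8, 1.2).
#' @return character vector of class labels.
#' @export
classify_genes <- function(fdr, fc, alpha = 0.05, unchanged_window = c(0.8, 1.2)) {
  cls <- rep("other", length(fdr))
  cls[fdr < alpha & fc > 1] <- "up"
  cls[fdr < alpha & fc < 1] <- "down"
  cls[fdr > alpha & fc > unchanged_window[1] & fc < unchanged_window[2]] <- "unchanged"
  cls[is.na(fdr) | is.na(fc)] <- NA_character_
  cls
}

#' Per-stage differential expression over the whole design
#'
#' For every period: apply the expression filter (pooled libraries of the
#' period), estimate a common dispersion from the period's samples (grouped by
#' genotype x stage) unless one is supplied, then for every stage test WT vs
#' mutant replicates with [nb_test()], adjust within the stage with
#' [bh_adjust()], and classify. Genes failing the period's filter appear with
#' class "filtered" and NA statistics.
#'
#' @param counts genes x samples integer matrix.
#' @param design design data.frame (`sample`, `genotype`, `period`, `stage`,
#'   `replicate`).
#' @param dispersion optional fixed dispersion; estimated per period if NULL.
#' @param alpha,cpm_min,min_libraries,unchanged_window thresholds (defaults:
#'   0.05, 10, 3, (0.8, 1.2)).
#' @return a `deg_table` data.frame: `gene_id`, `period`, `stage`, `log2fc`,
#'   `fc`, `pvalue`, `fdr`, `class`.
#' @export
call_degs <- function(counts, design, dispersion = NULL, alpha = 0.05,
                      cpm_min = 10, min_libraries = 3,
                      unchanged_window = c(0.8, 1.2)) {
  libs <- colSums(counts)
  ref <- exp(mean(log(libs)))
  norm <- ref / libs
  res <- list()
  for (period in unique(design$period)) {
    keep <- filter_expressed(counts, design, period, cpm_min, min_libraries)
    dsub <- design[design$period == period, , drop = FALSE]
    d <- dispersion
    if (is.null(d)) {
      grp <- paste(dsub$genotype, dsub$stage)
      d <- estimate_dispersion(counts[keep, dsub$sample, drop = FALSE], grp,
                               norm[dsub$sample])
    }
    for (stage in unique(dsub$stage)) {
      wt_s <- dsub$sample[dsub$stage == stage & dsub$genotype == "WT"]
      mu_s <- dsub$sample[dsub$stage == stage & dsub$genotype == "mut"]
      lf <- pv <- rep(NA_real_, length(keep))
      for (i in seq_along(keep)) {
        r <- nb_test(counts[keep[i], wt_s], counts[keep[i], mu_s],
                     norm[wt_s], norm[mu_s], d)
        lf[i] <- r$log2fc; pv[i] <- r$pvalue
      }
      fdr <- bh_adjust(pv)
      cls <- classify_genes(fdr, 2^lf, alpha, unchanged_window)
      filt <- setdiff(rownames(counts), keep)
      res[[paste(period, stage)]] <- data.frame(
        gene_id = c(keep, filt),
        period = period, stage = stage,
        log2fc = c(lf, rep(NA_real_, length(filt))),
        fc = c(2^lf, rep(NA_real_, length(filt))),
        pvalue = c(pv, rep(NA_real_, length(filt))),
        fdr = c(fdr, rep(NA_real_, length(filt))),
        class = c(cls, rep("filtered", length(filt))),
        dispersion = d,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Import an externally produced DE table
#'
#' Accepts tables from external DE tools (gene, stage, log2FC, p, FDR, and
#' optionally period/class) so real DE output can drive the downstream
#' overlap/coverage/feature modules unchanged. Missing classes are derived
#' with [classify_genes()].
#'
#' @param path TSV with columns `gene_id`, `stage`, `log2fc`, `pvalue`,
#'   `fdr`, optionally `period`, `class`.
#' @param alpha,unchanged_window classification thresholds used when `class`
#'   is absent.
#' @return a `deg_table` data.frame.
#' @export
import_deg_table <- function(path, alpha = 0.05, unchanged_window = c(0.8, 1.2)) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "stage", "log2fc", "pvalue", "fdr")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$fc)) d$fc <- 2^d$log2fc
  if (is.null(d$class)) {
    d$class <- classify_genes(d$fdr, d$fc, alpha, unchanged_window)
  }
  if (is.null(d$period)) d$period <- NA_character_
  class(d) <- c("deg_table", "data.frame")
  d
}

#' PCA embedding of samples
#'
#' log2(CPM + 1) transform (a simple variance-stabilizing stand-in for a
#' regularized log), restriction to the `n_top` most variable genes, then
#' centered SVD. Sign convention: within each component the gene with the
#' largest absolute loading is made positive, so embeddings are reproducible.
#'
#' @param counts genes x samples matrix (>= 2 samples).
#' @param n_top number of most-variable genes used (default 1000; all genes,
#'   with a warning, when fewer are available).
#' @return list with `scores` (samples x PCs), `var_explained` (fraction per
#'   PC), `rotation` (gene loadings).
#' @export
pca_embed <- function(counts, n_top = 1000) {
  stopifnot(ncol(counts) >= 2)
  lc <- log2(cpm(counts) + 1)
  v <- apply(lc, 1, var)
  if (nrow(lc) < n_top) {
    warning("fewer genes (", nrow(lc), ") than requested (", n_top, "); using all")
    n_top <- nrow(lc)
  }
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  x <- t(lc[top, , drop = FALSE])
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       rotation = pc$rotation)
}
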