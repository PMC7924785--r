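#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper over the standard two-sided two-sample KS test, with the size
#' guard used throughout the feature comparisons.
#'
#' @param x,y numeric samples (>= 3 values each).
#' @return list with `D` and `pvalue`.
#' @export
ks_compare <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) stop("ks_compare needs >= 3 values per sample")
  kt <- suppressWarnings(ks.test(x, y))
  list(D = unname(kt$statistic), pvalue = kt$p.value)
}

#' Codon adaptation index of a coding sequence
#'
#' Classical definition: the geometric mean (computed in log space) of the
#' relative adaptiveness w = frequency / max synonymous-family frequency over
#' the scored codons. Stop codons and single-codon families (ATG, TGG) are
#' excluded from scoring, as are codons containing ambiguous bases (counted).
#'
#' @param cds_sequence DNA string, length divisible by 3.
#' @param usage a `codon_usage`.
#' @param weights optional precomputed [codon_weights()] table (speeds up
#'   scoring many sequences against one table).
#' @return list of class `cai_result`: `cai`, `n_scored`, `n_excluded`.
#' @export
cai <- function(cds_sequence, usage, weights = NULL) {
  s <- toupper(chartr("Uu", "Tt", cds_sequence))
  if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3")
  if (is.null(weights)) weights <- codon_weights(usage)
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  known <- codons %in% weights$codon
  aa <- setNames(weights$aa, weights$codon)[codons[known]]
  single <- names(which(table(weights$aa) == 1))     # M and W
  scored <- codons[known][!(aa %in% c("*", single))]
  n_excluded <- length(codons) - length(scored)
  if (length(scored) == 0) stop("no scorable codons in sequence")
  w <- setNames(weights$w, weights$codon)[scored]
  list(cai = exp(mean(log(w))), n_scored = length(scored),
       n_excluded = n_excluded)
}

#' CAI of many sequences
#'
#' @param seqs named character vector of CDS sequences.
#' @param usage a `codon_usage`.
#' @return data.frame: `transcript_id`, `cai`, `n_scored`, `n_excluded`.
#' @export
cai_all <- function(seqs, usage) {
  w <- codon_weights(usage)
  res <- lapply(seqs, cai, usage = usage, weights = w)
  data.frame(
    transcript_id = names(seqs),
    cai = vapply(res, `[[`, numeric(1), "cai"),
    n_scored = vapply(res, `[[`, numeric(1), "n_scored"),
    n_excluded = vapply(res, `[[`, numeric(1), "n_excluded"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Random-sequence CAI background
#'
#' The control distribution used alongside group CAI comparisons: random
#' coding sequences with codons drawn proportionally to the usage table
#' (stop codons excluded from the draw so every sequence has exactly
#' `mean_cds_codons` scored-eligible codons). The number of sequences equals
#' the group size, or 500 when the group exceeds 1000 sequences.
#'
#' @param usage a `codon_usage`.
#' @param group_size size of the gene group being compared.
#' @param mean_cds_codons codons per random sequence (average CDS length of
#'   the group, in codons).
#' @param seed integer seed.
#' @return list with `values` (CAI per random sequence), `n`, `quantiles`
#'   (5%, 25%, 50%, 75%, 95%).
#' @export
cai_background <- function(usage, group_size, mean_cds_codons, seed = 1L) {
  stopifnot(group_size > 0, mean_cds_codons > 0)
  n <- if (group_size > 1000) 500L else as.integer(group_size)
  w <- codon_weights(usage)
  codons <- names(usage$freq)
  sense <- codons[usage$code[codons] != "*"]
  p <- usage$freq[sense] / sum(usage$freq[sense])
  set.seed(seed)
  vals <- vapply(seq_len(n), function(i) {
    s <- paste(sample(sense, mean_cds_codons, replace = TRUE, prob = p),
               collapse = "")
    cai(s, usage, weights = w)$cai
  }, numeric(1))
  list(values = vals, n = n,
       quantiles = quantile(vals, c(0.05, 0.25, 0.5, 0.75, 0.95)))
}

#' Wild-type expression of DEG classes versus unchanged genes
#'
#' Two-sided Wilcoxon rank-sum of wild-type TPM for the up and down classes
#' against the unchanged class at one stage, with group medians. Classes with
#' fewer than 2 genes are skipped with a note.
#'
#' @param tpm_wt named numeric vector of wild-type TPM per gene at the stage.
#' @param classes named character vector of DEG classes per gene at the
#'   stage ("up"/"down"/"unchanged"/...).
#' @return data.frame: `group`, `n`, `n_unchanged`, `median_group`,
#'   `median_unchanged`, `statistic`, `pvalue`, `note`.
#' @export
expression_level_compare <- function(tpm_wt, classes) {
  genes <- intersect(names(tpm_wt), names(classes))
  cls <- classes[genes]
  ex <- tpm_wt[genes]
  unch <- ex[cls == "unchanged"]
  rows <- lapply(c("up", "down"), function(g) {
    grp <- ex[cls == g]
    if (length(grp) < 2 || length(unch) < 2) {
      return(data.frame(group = g, n = length(grp), n_unchanged = length(unch),
                        median_group = if (length(grp)) unname(median(grp)) else NA_real_,
                        median_unchanged = if (length(unch)) unname(median(unch)) else NA_real_,
                        statistic = NA_real_, pvalue = NA_real_,
                        note = "skipped_small_group", stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(wilcox.test(grp, unch))
    data.frame(group = g, n = length(grp), n_unchanged = length(unch),
               median_group = unname(median(grp)),
               median_unchanged = unname(median(unch)),
               statistic = unname(wt$statistic), pvalue = wt$p.value,
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
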