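#' 100-bin coverage profile of one transcript
#'
#' Positions are partitioned into `n_bins` equal-width bins by proportional
#' overlap (fractional positions weighted), the bin value is the mean depth in
#' the bin, and (by default) values are normalized by the transcript's overall
#' mean depth so every usable transcript contributes on the same scale.
#' Transcripts shorter than `n_bins` and all-zero tracks are excluded (NULL),
#' never zero-filled.
#'
#' @param track a [coverage_track()].
#' @param n_bins number of bins (default 100).
#' @param normalize divide by the transcript mean depth (default TRUE).
#' @return numeric vector of `n_bins` values, or NULL when excluded.
#' @export
bin_profile <- function(track, n_bins = 100, normalize = TRUE) {
  depth <- track$depth
  L <- length(depth)
  if (L < n_bins) return(NULL)
  total <- sum(depth)
  if (total == 0) return(NULL)
  cum <- c(0, cumsum(depth))
  # integral of the piecewise-constant depth from 0 to fractional x
  S <- function(x) {
    i <- floor(x)
    frac <- x - i
    cum[i + 1] + ifelse(i < L, depth[pmin(i + 1, L)] * frac, 0)
  }
  edges <- (0:n_bins) * L / n_bins
  binsum <- diff(S(edges))
  vals <- binsum / (L / n_bins)       # mean depth per bin
  if (normalize) vals <- vals / (total / L)
  vals
}

#' Metagene profile of a gene set
#'
#' Per-transcript normalized bin profiles averaged across the usable
#' transcripts of a gene set (unweighted mean, so highly expressed genes do
#' not dominate). Replicate coverage should be averaged into the supplied
#' tracks beforehand.
#'
#' @param tracks named list of [coverage_track()] keyed by transcript id.
#' @param transcript_ids transcripts of the gene set to aggregate.
#' @param n_bins number of bins (default 100).
#' @return list of class `metagene_profile`: `profile` (length `n_bins`),
#'   `n_used`, `n_skipped_short`, `n_skipped_zero`.
#' @export
metagene <- function(tracks, transcript_ids, n_bins = 100) {
  transcript_ids <- intersect(transcript_ids, names(tracks))
  profs <- list()
  short <- zero <- 0L
  for (tid in transcript_ids) {
    tr <- tracks[[tid]]
    if (length(tr$depth) < n_bins) { short <- short + 1L; next }
    if (sum(tr$depth) == 0) { zero <- zero + 1L; next }
    profs[[tid]] <- bin_profile(tr, n_bins)
  }
  if (length(profs) == 0) stop("no usable transcript in the gene set")
  structure(list(
    profile = colMeans(do.call(rbind, profs)),
    n_used = length(profs),
    n_skipped_short = short,
    n_skipped_zero = zero
  ), class = "metagene_profile")
}

#' Count reads per gene-body region with the double-count rule
#'
#' A read increments every region (5'UTR, CDS, 3'UTR) it overlaps by at least
#' one nucleotide, so a boundary-spanning read is counted for both regions it
#' touches.
#'
#' @param reads integer matrix with columns `start`, `end` (0-based half-open
#'   transcript coordinates).
#' @param regions a region map from [region_map()].
#' @return named numeric vector `c(utr5=, cds=, utr3=)`.
#' @export
count_reads_by_region <- function(reads, regions) {
  out <- c(utr5 = 0, cds = 0, utr3 = 0)
  if (is.null(reads) || nrow(reads) == 0) return(out)
  for (rg in names(out)) {
    a <- regions[[rg]][1]; b <- regions[[rg]][2]
    if (b <= a) next
    out[rg] <- sum(reads[, "start"] < b & reads[, "end"] > a)
  }
  out
}

#' Per-gene per-region read densities of one genotype
#'
#' Density = region read count / region length, with the double-count rule of
#' [count_reads_by_region()]. Genes without an annotated CDS are skipped;
#' zero-length regions yield NA density for that gene.
#'
#' @param tracks named list of [coverage_track()] (reads attached), keyed by
#'   transcript id.
#' @param models a [gene_model_set()] (longest isoform per gene).
#' @return data.frame: `gene_id`, `region`, `reads`, `length`, `density`.
#' @export
region_density <- function(tracks, models) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    if (!models$has_cds[i]) next
    tid <- models$transcript_id[i]
    tr <- tracks[[tid]]
    if (is.null(tr)) next
    rm <- region_map(models, tid)
    cnt <- count_reads_by_region(tr$reads, rm)
    len <- vapply(rm, function(iv) iv[2] - iv[1], numeric(1))
    rows[[tid]] <- data.frame(
      gene_id = models$gene_id[i],
      region = names(cnt),
      reads = unname(cnt),
      length = unname(len),
      density = ifelse(len > 0, unname(cnt) / unname(len), NA_real_),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mutant/WT read-density ratios per gene and region
#'
#' ratio = mutant density / WT density. Genes where both densities are zero
#' are excluded (reason `both_zero`, following the convention that such
#' values are not considered); WT-zero with mutant-nonzero is excluded as
#' undefined and tallied separately (`wt_zero`); zero-length regions are
#' skipped (`no_region`). Exclusion tallies make the conventions auditable.
#'
#' @param dens_wt,dens_mut data.frames from [region_density()].
#' @return data.frame: `gene_id`, `region`, `density_wt`, `density_mut`,
#'   `ratio` (NA when excluded), `excluded`, `reason`.
#' @export
region_density_ratio <- function(dens_wt, dens_mut) {
  m <- merge(dens_wt, dens_mut, by = c("gene_id", "region"),
             suffixes = c("_wt", "_mut"))
  ratio <- rep(NA_real_, nrow(m))
  reason <- rep("", nrow(m))
  no_region <- is.na(m$density_wt) | is.na(m$density_mut)
  both_zero <- !no_region & m$density_wt == 0 & m$density_mut == 0
  wt_zero <- !no_region & m$density_wt == 0 & m$density_mut > 0
  ok <- !no_region & m$density_wt > 0
  ratio[ok] <- m$density_mut[ok] / m$density_wt[ok]
  reason[no_region] <- "no_region"
  reason[both_zero] <- "both_zero"
  reason[wt_zero] <- "wt_zero"
  data.frame(
    gene_id = m$gene_id, region = m$region,
    density_wt = m$density_wt, density_mut = m$density_mut,
    ratio = ratio, excluded = !ok, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Wilcoxon comparison of per-gene region densities between genotypes
#'
#' Two-sided Wilcoxon rank-sum (unpaired by default; set `paired = TRUE` for
#' the signed-rank variant on genes present in both genotypes).
#'
#' @param dens_wt,dens_mut numeric vectors of per-gene densities of one
#'   region (NA dropped; >= 3 values per side required).
#' @param paired use the paired signed-rank test (vectors aligned by
#'   position).
#' @return list with `statistic`, `pvalue`, `n_wt`, `n_mut`,
#'   `median_wt`, `median_mut`.
#' @export
compare_region_densities <- function(dens_wt, dens_mut, paired = FALSE) {
  if (paired) {
    keep <- !is.na(dens_wt) & !is.na(dens_mut)
    dens_wt <- dens_wt[keep]; dens_mut <- dens_mut[keep]
  } else {
    dens_wt <- dens_wt[!is.na(dens_wt)]
    dens_mut <- dens_mut[!is.na(dens_mut)]
  }
  if (length(dens_wt) < 3 || length(dens_mut) < 3) {
    return(list(statistic = NA_real_, pvalue = NA_real_,
                n_wt = length(dens_wt), n_mut = length(dens_mut),
                median_wt = median(dens_wt), median_mut = median(dens_mut),
                flag = "too_few"))
  }
  wt <- suppressWarnings(wilcox.test(dens_mut, dens_wt, paired = paired))
  list(statistic = unname(wt$statistic), pvalue = wt$p.value,
       n_wt = length(dens_wt), n_mut = length(dens_mut),
       median_wt = median(dens_wt), median_mut = median(dens_mut),
       flag = "ok")
}
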