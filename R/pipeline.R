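#' Validated run configuration
#'
#' Bundles every threshold of the pipeline. Defaults are the study's printed
#' values: FDR 0.05, 10 CPM in >= 3 libraries, unchanged fold-change window
#' (0.8, 1.2), minimum transcript length 100 nt, 100 metagene bins.
#'
#' @param fdr DEG threshold on FDR (strict <).
#' @param cpm_min,min_libraries expression-filter thresholds.
#' @param unchanged_window open fold-change interval of unchanged genes.
#' @param min_tx_len minimum transcript length for metagene profiles (nt).
#' @param n_bins metagene bins.
#' @param n_resamples matched-control resamples for overlap tests.
#' @param n_match_bins expression quantile bins for matching.
#' @param seed master seed.
#' @param sim a [sim_params()] describing the simulated inputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(fdr = 0.05, cpm_min = 10, min_libraries = 3,
                       unchanged_window = c(0.8, 1.2), min_tx_len = 100,
                       n_bins = 100, n_resamples = 100, n_match_bins = 20,
                       seed = 1L, sim = sim_params(seed = seed)) {
  cfg <- list(fdr = fdr, cpm_min = cpm_min, min_libraries = min_libraries,
              unchanged_window = unchanged_window, min_tx_len = min_tx_len,
              n_bins = n_bins, n_resamples = n_resamples,
              n_match_bins = n_match_bins, seed = as.integer(seed), sim = sim)
  if (!(fdr > 0 && fdr <= 1)) stop("invalid config: fdr must be in (0, 1]")
  if (cpm_min < 0) stop("invalid config: cpm_min must be >= 0")
  if (min_libraries < 1) stop("invalid config: min_libraries must be >= 1")
  if (!(length(unchanged_window) == 2 &&
        unchanged_window[1] > 0 && unchanged_window[1] < 1 &&
        unchanged_window[2] > 1)) {
    stop("invalid config: unchanged_window must straddle 1")
  }
  if (min_tx_len < n_bins) {
    stop("invalid config: min_tx_len must be >= n_bins")
  }
  if (n_resamples < 1) stop("invalid config: n_resamples must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

config_fingerprint <- function(cfg) {
  flat <- unlist(cfg[setdiff(names(cfg), "sim")])
  simf <- unlist(cfg$sim)
  paste0("decaylens/", paste(names(flat), flat, sep = "=", collapse = ";"),
         "|sim:", paste(names(simf), simf, sep = "=", collapse = ";"))
}

#' Run the full pipeline on a simulated data set
#'
#' simulate -> filter -> DE -> classify -> overlap -> coverage profiles ->
#' transcript features, as one reproducible, seeded run. All stage outputs
#' are returned in the report; with `out_dir` set they are also written as
#' TSVs (with the config fingerprint as a header comment).
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory for TSVs.
#' @return list of class `run_report`: `deg_counts` (per-stage class
#'   tallies), `deg` (the DEG table), `overlap` (between-period overlap
#'   tests), `metagene` (per-class profiles per genotype), `density`
#'   (ratio table and per-region Wilcoxon tests), `features` (length KS,
#'   CAI comparisons, expression comparisons), `truth`, `fingerprint`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  params <- config$sim
  ann <- simulate_annotation(params)
  cnt <- simulate_counts(ann$models, params)
  cov <- simulate_coverage(ann$models, cnt$truth, params)
  models <- ann$models
  counts <- cnt$counts
  design <- cnt$design

  deg <- call_degs(counts, design, alpha = config$fdr,
                   cpm_min = config$cpm_min,
                   min_libraries = config$min_libraries,
                   unchanged_window = config$unchanged_window)
  deg_counts <- as.data.frame(table(stage = deg$stage, class = deg$class),
                              stringsAsFactors = FALSE)

  # WT mean TPM per period (matching covariate for control sampling)
  tx_len <- setNames(models$tx_len, models$gene_id)
  tp <- tpm(counts, tx_len)
  periods <- design_periods()
  wt_tpm_period <- sapply(names(periods), function(p) {
    sel <- design$sample[design$period == p & design$genotype == "WT"]
    rowMeans(tp[, sel, drop = FALSE])
  })

  # shared-period DEG sets: DEG in the same direction at every stage
  shared_sets <- list()
  unchanged_pool <- list()
  for (p in names(periods)) {
    sub <- deg[deg$period == p, ]
    n_st <- length(periods[[p]])
    for (dir in c("up", "down")) {
      tab <- table(sub$gene_id[sub$class == dir])
      shared_sets[[paste(p, dir, sep = "_")]] <- names(tab)[tab == n_st]
    }
    tab_u <- table(sub$gene_id[sub$class == "unchanged"])
    unchanged_pool[[p]] <- names(tab_u)[tab_u == n_st]
  }

  pairs <- utils::combn(names(periods), 2)
  ov_rows <- list()
  for (j in seq_len(ncol(pairs))) {
    pa <- pairs[1, j]; pb <- pairs[2, j]
    for (dir in c("up", "down")) {
      A <- shared_sets[[paste(pa, dir, sep = "_")]]
      B <- shared_sets[[paste(pb, dir, sep = "_")]]
      pool <- setdiff(unchanged_pool[[pa]], A)
      if (length(A) < 5 || length(pool) < length(A)) next
      ov <- overlap_significance(A, B, pool, wt_tpm_period[, pa],
                                 n_resamples = config$n_resamples,
                                 seed = stream_seed(config$seed,
                                                    paste("ov", pa, pb, dir)),
                                 n_bins = config$n_match_bins)
      ov_rows[[paste(pa, pb, dir)]] <- data.frame(
        period_a = pa, period_b = pb, direction = dir,
        n_a = length(A), n_b = length(B),
        observed = ov$observed, observed_frac = ov$observed_frac,
        control_mean = ov$control_mean,
        chisq = ov$statistic, pvalue = ov$pvalue,
        quantile = ov$quantile, quantile_rand = ov$quantile_rand,
        stringsAsFactors = FALSE
      )
    }
  }
  overlap_tab <- if (length(ov_rows)) do.call(rbind, ov_rows) else NULL
  if (!is.null(overlap_tab)) rownames(overlap_tab) <- NULL

  # coverage profiles and region densities at a representative stabilized stage
  rep_stage <- periods[[params$stabilized_periods[1]]][1]
  stage_cls <- deg[deg$stage == rep_stage, ]
  cls_of <- setNames(stage_cls$class, stage_cls$gene_id)
  tid_of <- setNames(models$transcript_id, models$gene_id)
  mg <- list()
  for (cl in c("up", "down", "unchanged")) {
    ids <- tid_of[names(cls_of)[cls_of == cl]]
    for (gt in c("WT", "mut")) {
      mg[[paste(cl, gt, sep = "_")]] <- tryCatch(
        metagene(cov[[gt]], ids, config$n_bins), error = function(e) NULL)
    }
  }
  dens_wt <- region_density(cov$WT, models)
  dens_mut <- region_density(cov$mut, models)
  ratios <- region_density_ratio(dens_wt, dens_mut)
  up_genes <- names(cls_of)[cls_of == "up"]
  region_tests <- lapply(c("utr5", "cds", "utr3"), function(rg) {
    w <- compare_region_densities(
      dens_wt$density[dens_wt$region == rg & dens_wt$gene_id %in% up_genes],
      dens_mut$density[dens_mut$region == rg & dens_mut$gene_id %in% up_genes])
    data.frame(region = rg, statistic = w$statistic, pvalue = w$pvalue,
               median_wt = w$median_wt, median_mut = w$median_mut,
               n = w$n_wt, stringsAsFactors = FALSE)
  })
  region_tests <- do.call(rbind, region_tests)

  # transcript features of the classes at the representative stage
  lens <- region_lengths(models)
  rownames(lens) <- lens$gene_id
  feat_rows <- list()
  unch_genes <- names(cls_of)[cls_of == "unchanged"]
  for (feat in c("full", "utr5", "cds", "utr3")) {
    for (cl in c("up", "down")) {
      gs <- names(cls_of)[cls_of == cl]
      if (length(gs) < 3 || length(unch_genes) < 3) next
      ks <- ks_compare(lens[gs, feat], lens[unch_genes, feat])
      feat_rows[[paste(feat, cl)]] <- data.frame(
        feature = feat, group = cl, D = ks$D, pvalue = ks$pvalue,
        n_group = length(gs), n_unchanged = length(unch_genes),
        stringsAsFactors = FALSE)
    }
  }
  usage <- default_codon_usage()
  cai_tab <- cai_all(ann$cds, usage)
  cai_tab$gene_id <- models$gene_id[match(cai_tab$transcript_id,
                                          models$transcript_id)]
  cai_of <- setNames(cai_tab$cai, cai_tab$gene_id)
  cai_cmp <- NULL
  up_ok <- up_genes[up_genes %in% names(cai_of)]
  if (length(up_ok) >= 3 && length(unch_genes) >= 3) {
    ks <- ks_compare(cai_of[up_ok], cai_of[unch_genes])
    bg <- cai_background(usage, length(up_ok),
                         round(mean(models$cds_len[models$gene_id %in% up_ok] / 3)),
                         seed = stream_seed(config$seed, "cai_bg"))
    cai_cmp <- list(D = ks$D, pvalue = ks$pvalue,
                    median_up = median(cai_of[up_ok]),
                    median_unchanged = median(cai_of[unch_genes]),
                    background_quantiles = bg$quantiles)
  }
  wt_stage <- design$sample[design$stage == rep_stage & design$genotype == "WT"]
  expr_cmp <- expression_level_compare(rowMeans(tp[, wt_stage, drop = FALSE]),
                                       cls_of)

  report <- structure(list(
    deg_counts = deg_counts, deg = deg, shared_sets = shared_sets,
    overlap = overlap_tab,
    metagene = mg,
    density = list(ratios = ratios, region_tests = region_tests,
                   stage = rep_stage),
    features = list(length_ks = if (length(feat_rows))
      do.call(rbind, feat_rows) else NULL,
      cai = cai_tab, cai_compare = cai_cmp,
      expression_compare = expr_cmp),
    truth = cnt$truth,
    fingerprint = config_fingerprint(config)
  ), class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the tabular parts of a run report as TSVs
#'
#' Every file starts with a `#` comment carrying the config fingerprint.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# ", report$fingerprint), con)
    close(con)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  emit(report$deg_counts, "deg_counts.tsv")
  emit(report$deg, "deg_table.tsv")
  emit(report$overlap, "overlap_tests.tsv")
  emit(report$density$ratios, "region_density_ratios.tsv")
  emit(report$density$region_tests, "region_density_tests.tsv")
  emit(report$features$length_ks, "length_ks.tsv")
  emit(report$features$cai, "cai_per_gene.tsv")
  emit(report$features$expression_compare, "expression_compare.tsv")
  mg <- report$metagene
  if (length(mg)) {
    rows <- lapply(names(mg), function(k) {
      if (is.null(mg[[k]])) return(NULL)
      data.frame(set = k, bin = seq_along(mg[[k]]$profile),
                 value = mg[[k]]$profile, n_genes = mg[[k]]$n_used)
    })
    emit(do.call(rbind, rows), "metagene_profiles.tsv")
  }
  invisible(out_dir)
}
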