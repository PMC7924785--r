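#' Simulation parameters for the staged two-genotype design
#'
#' Bundles every knob of the synthetic-data generator that emulates a
#' wild-type vs decay-mutant RNA-seq time course: 2 genotypes (WT, mut) x
#' 3 developmental periods (oogenesis O1-O4; mature eggs UNA/ACT/FER;
#' embryogenesis E1-E4) x 3 replicates. A designated "stabilized" gene set
#' (putative decay targets) is drawn preferentially from low-expression genes,
#' up-regulated in the mutant during its stabilized periods, 3'-biased in
#' mutant coverage, and enriched for rare codons.
#'
#' @param n_genes number of simulated genes (one isoform each).
#' @param utr5_meanlog,utr5_sdlog log-normal parameters of 5'UTR length (nt).
#' @param cds_codons_meanlog,cds_codons_sdlog log-normal parameters of CDS
#'   length in codons (including start and stop).
#' @param utr3_meanlog,utr3_sdlog log-normal parameters of 3'UTR length (nt).
#' @param replicates libraries per genotype x stage.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of relative
#'   gene abundance (normalized to proportions internally).
#' @param lib_meanlog,lib_sdlog log-normal parameters of library size.
#' @param dispersion negative-binomial dispersion (Var = mu + mu^2 * disp);
#'   0 gives Poisson counts.
#' @param stabilized_fraction fraction of genes that are decay targets.
#' @param stabilized_low_expression_weight exponential rank-weighting strength
#'   of the preference for low-expression genes when picking targets
#'   (0 = uniform).
#' @param stabilized_fc fold change (> 1) applied to mutant means of
#'   stabilized genes during `stabilized_periods`.
#' @param stabilized_periods periods (subset of "O","M","E") in which targets
#'   are stabilized.
#' @param bias3 3' redistribution strength of mutant coverage for stabilized
#'   genes: read-start density proportional to exp(bias3 * x/L); 0 = uniform.
#' @param codon_bias mixing weight toward an inverted-frequency codon table
#'   for the rare-codon gene subset (by default the stabilized genes).
#' @param reads_per_gene mean coverage reads per gene (scaled by abundance).
#' @param read_length simulated read length (nt).
#' @param seed integer master seed; split into named substreams per stage of
#'   the generator so draws for one output do not shift another.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000,
                       utr5_meanlog = log(150), utr5_sdlog = 0.4,
                       cds_codons_meanlog = log(350), cds_codons_sdlog = 0.4,
                       utr3_meanlog = log(400), utr3_sdlog = 0.5,
                       replicates = 3,
                       baseline_meanlog = 0, baseline_sdlog = 1.5,
                       lib_meanlog = log(1e6), lib_sdlog = 0.2,
                       dispersion = 0.05,
                       stabilized_fraction = 0.1,
                       stabilized_low_expression_weight = 4,
                       stabilized_fc = 4,
                       stabilized_periods = c("M", "E"),
                       bias3 = 3,
                       codon_bias = 0.5,
                       reads_per_gene = 200,
                       read_length = 100,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    n_genes >= 1, replicates >= 1, dispersion >= 0,
    stabilized_fraction >= 0, stabilized_fraction <= 1,
    stabilized_low_expression_weight >= 0,
    stabilized_fc > 0, bias3 >= 0,
    codon_bias >= 0, codon_bias <= 1,
    all(stabilized_periods %in% c("O", "M", "E")),
    read_length >= 1, seed == floor(seed)
  )
  class(p) <- "sim_params"
  p
}

#' Stage layout of the simulated design
#' @return named list mapping period id to its stage names.
#' @export
design_periods <- function() {
  list(O = c("O1", "O2", "O3", "O4"),
       M = c("UNA", "ACT", "FER"),
       E = c("E1", "E2", "E3", "E4"))
}

#' Sample design table of a parameter set
#'
#' @param params a [sim_params()].
#' @return data.frame with columns `sample`, `genotype`, `period`, `stage`,
#'   `replicate`.
#' @export
sim_design <- function(params) {
  per <- design_periods()
  rows <- expand.grid(
    replicate = seq_len(params$replicates),
    stage = unlist(per, use.names = FALSE),
    genotype = c("WT", "mut"),
    stringsAsFactors = FALSE
  )
  stage2per <- rep(names(per), lengths(per))
  names(stage2per) <- unlist(per, use.names = FALSE)
  rows$period <- stage2per[rows$stage]
  rows$sample <- paste(rows$genotype, rows$stage, rows$replicate, sep = "_")
  rows[, c("sample", "genotype", "period", "stage", "replicate")]
}

# deterministic substream seed: polynomial string hash folded into [1, 2^31-2]
stream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((seed %% 2147483647) * 48271 %% 2147483647 + h) %% 2147483646L + 1L
}

#' Deterministic synthetic codon usage table
#'
#' A synthetic vertebrate-like usage table (per-thousand) built from a fixed
#' formula (GC-richer codons and C/G-ending codons more frequent), giving
#' distinct frequencies within almost every synonymous family. It is a
#' stand-in for a species usage table, not measured data.
#'
#' @return a `codon_usage` object.
#' @export
default_codon_usage <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  gc <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")),
               numeric(1))
  third <- substr(codons, 3, 3)
  f <- 8 + 5 * gc + c(A = 0, T = 1, G = 2.5, C = 4)[third]
  codon_usage(setNames(f, codons))
}

# inverse-frequency table used for the rare-codon gene subset
inverted_usage_freq <- function(usage) {
  f <- usage$freq
  inv <- 1 / pmax(f, min(f[f > 0]) / 2)
  inv / sum(inv) * 1000
}

# shared truth draws: baseline abundance, stabilized and rare-codon sets.
# Both simulate_annotation() and simulate_counts() derive these from the same
# substreams so the two outputs are mutually consistent.
sim_truth <- function(params) {
  n <- params$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  set.seed(stream_seed(params$seed, "baseline"))
  x <- rlnorm(n, params$baseline_meanlog, params$baseline_sdlog)
  baseline <- x / sum(x)
  n_stab <- round(params$stabilized_fraction * n)
  stabilized <- rep(FALSE, n)
  if (n_stab > 0) {
    set.seed(stream_seed(params$seed, "stabilized"))
    rk <- rank(baseline, ties.method = "first")
    wgt <- exp(-params$stabilized_low_expression_weight * (rk - 1) / max(n - 1, 1))
    stabilized[sample.int(n, n_stab, prob = wgt)] <- TRUE
  }
  per <- names(design_periods())
  fc <- matrix(1, n, length(per), dimnames = list(gene_id, per))
  for (p in intersect(params$stabilized_periods, per)) {
    fc[stabilized, p] <- params$stabilized_fc
  }
  data.frame(
    gene_id = gene_id,
    baseline = baseline,
    stabilized = stabilized,
    rare_codon = stabilized,   # decay targets carry the rare-codon signature
    stabilized_periods = ifelse(
      stabilized, paste(params$stabilized_periods, collapse = ","), ""),
    fc_O = fc[, "O"], fc_M = fc[, "M"], fc_E = fc[, "E"],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Simulate gene annotation and CDS sequences
#'
#' Generates single-isoform gene models with log-normal region lengths and CDS
#' sequences starting with ATG, ending with a stop, with internal codons drawn
#' from the usage table. The rare-codon gene subset draws internal codons from
#' a mixture of the usage table and its inverted-frequency counterpart
#' (mixing weight `codon_bias`), giving those genes lower codon adaptation.
#'
#' @param params a [sim_params()].
#' @param usage a `codon_usage` (default [default_codon_usage()]).
#' @return list with `models` (a [gene_model_set()]), `cds` (named character
#'   vector of CDS sequences) and `truth` (the truth-label table, see
#'   [simulate_counts()]).
#' @export
simulate_annotation <- function(params, usage = default_codon_usage()) {
  truth <- sim_truth(params)
  n <- params$n_genes
  set.seed(stream_seed(params$seed, "lengths"))
  utr5 <- pmax(20L, as.integer(round(rlnorm(n, params$utr5_meanlog, params$utr5_sdlog))))
  ncod <- pmax(12L, as.integer(round(rlnorm(n, params$cds_codons_meanlog,
                                            params$cds_codons_sdlog))))
  utr3 <- pmax(50L, as.integer(round(rlnorm(n, params$utr3_meanlog, params$utr3_sdlog))))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  codons <- names(usage$freq)
  stops <- codons[usage$code[codons] == "*"]
  sense <- setdiff(codons, stops)
  p_common <- usage$freq[sense] / sum(usage$freq[sense])
  inv <- inverted_usage_freq(usage)
  p_inv <- inv[sense] / sum(inv[sense])
  p_rare <- (1 - params$codon_bias) * p_common + params$codon_bias * p_inv
  p_stop <- usage$freq[stops] / sum(usage$freq[stops])

  set.seed(stream_seed(params$seed, "cds"))
  cds <- character(n)
  for (i in seq_len(n)) {
    probs <- if (truth$rare_codon[i]) p_rare else p_common
    inner <- sample(sense, ncod[i] - 2L, replace = TRUE, prob = probs)
    stop_codon <- sample(stops, 1L, prob = p_stop)
    cds[i] <- paste(c("ATG", inner, stop_codon), collapse = "")
  }
  tx_id <- sub("^gene", "tx", truth$gene_id)
  names(cds) <- tx_id
  models <- gene_model_set(
    gene_id = truth$gene_id, transcript_id = tx_id, strand = strand,
    utr5_len = utr5, cds_len = 3L * ncod, utr3_len = utr3
  )
  list(models = models, cds = cds, truth = truth)
}

#' Simulate the count matrix of the staged design
#'
#' Counts are negative-binomially distributed around `library size x relative
#' abundance`, with mutant means multiplied by `stabilized_fc` for stabilized
#' genes in their stabilized periods. Library sizes are log-normal. Each
#' sample's draws come from its own seed substream, so extending the design
#' does not shuffle other samples' counts.
#'
#' @param models a [gene_model_set()] from [simulate_annotation()].
#' @param params a [sim_params()].
#' @return list with `counts` (genes x samples integer matrix), `design`
#'   (see [sim_design()]), `lib_sizes` (named vector) and `truth`
#'   (data.frame: gene_id, baseline, stabilized, rare_codon,
#'   stabilized_periods, fc_O/fc_M/fc_E). Truth labels are for test
#'   assertions only and are not an input of any downstream analysis.
#' @export
simulate_counts <- function(models, params) {
  truth <- sim_truth(params)
  stopifnot(identical(models$gene_id, truth$gene_id))
  design <- sim_design(params)
  set.seed(stream_seed(params$seed, "libsizes"))
  libs <- rlnorm(nrow(design), params$lib_meanlog, params$lib_sdlog)
  names(libs) <- design$sample
  fc <- as.matrix(truth[, c("fc_O", "fc_M", "fc_E")])
  colnames(fc) <- c("O", "M", "E")
  counts <- matrix(0L, params$n_genes, nrow(design),
                   dimnames = list(truth$gene_id, design$sample))
  for (j in seq_len(nrow(design))) {
    s <- design[j, ]
    mult <- if (s$genotype == "mut") fc[, s$period] else 1
    mu <- libs[j] * truth$baseline * mult
    set.seed(stream_seed(params$seed, paste0("counts_", s$sample)))
    counts[, j] <- if (params$dispersion == 0) {
      rpois(params$n_genes, mu)
    } else {
      rnbinom(params$n_genes, mu = mu, size = 1 / params$dispersion)
    }
  }
  list(counts = counts, design = design, lib_sizes = libs, truth = truth)
}

#' Simulate per-transcript coverage and read intervals per genotype
#'
#' Fixed-length reads are placed on each transcript with start-position
#' density proportional to `exp(bias3 * x/L)` for stabilized genes in the
#' mutant (emulating the 3'-end protection signature of lost 3'-5' decay) and
#' uniformly otherwise. Read numbers are Poisson around
#' `reads_per_gene x n_genes x abundance`, with the mutant total of
#' stabilized genes scaled by `stabilized_fc`. Transcripts shorter than the
#' read length are skipped with a warning; zero-expression genes get empty
#' tracks.
#'
#' @param models a [gene_model_set()].
#' @param truth truth labels from [simulate_counts()] (or
#'   [simulate_annotation()]).
#' @param params a [sim_params()].
#' @return list with elements `WT` and `mut`, each a named list of
#'   [coverage_track()] with reads attached.
#' @export
simulate_coverage <- function(models, truth, params) {
  stopifnot(identical(models$gene_id, truth$gene_id))
  rl <- params$read_length
  out <- list()
  for (gt in c("WT", "mut")) {
    set.seed(stream_seed(params$seed, paste0("coverage_", gt)))
    tracks <- vector("list", nrow(models))
    names(tracks) <- models$transcript_id
    skipped <- 0L
    for (i in seq_len(nrow(models))) {
      L <- models$tx_len[i]
      if (L < rl) {
        skipped <- skipped + 1L
        tracks[[i]] <- coverage_track(models$transcript_id[i], numeric(L),
                                      cbind(start = integer(0), end = integer(0)))
        next
      }
      lambda <- params$reads_per_gene * params$n_genes * truth$baseline[i]
      if (gt == "mut" && truth$stabilized[i]) lambda <- lambda * params$stabilized_fc
      n_reads <- rpois(1, lambda)
      if (n_reads == 0) {
        tracks[[i]] <- coverage_track(models$transcript_id[i], numeric(L),
                                      cbind(start = integer(0), end = integer(0)))
        next
      }
      starts_at <- 0:(L - rl)
      w <- if (gt == "mut" && truth$stabilized[i] && params$bias3 > 0) {
        exp(params$bias3 * starts_at / L)
      } else {
        rep(1, length(starts_at))
      }
      st <- sample(starts_at, n_reads, replace = TRUE, prob = w)
      reads <- cbind(start = st, end = st + rl)
      tracks[[i]] <- coverage_track(models$transcript_id[i],
                                    depth_from_reads(reads, L), reads)
    }
    if (skipped > 0) {
      warning(skipped, " transcript(s) shorter than the read length skipped (", gt, ")")
    }
    out[[gt]] <- tracks
  }
  out
}

#' Write a complete simulated data set to disk
#'
#' Emits the files a real analysis would start from: annotation GTF, CDS
#' FASTA, counts TSV, design TSV, per-genotype BED and bedGraph, codon usage
#' TSV, and the truth labels (test-only) as TSV.
#'
#' @param params a [sim_params()].
#' @param dir output directory (created if needed).
#' @param usage a `codon_usage`.
#' @return invisible list of all simulated objects.
#' @export
write_simulation <- function(params, dir, usage = default_codon_usage()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(params, usage)
  cnt <- simulate_counts(ann$models, params)
  cov <- simulate_coverage(ann$models, cnt$truth, params)
  write_gtf(ann$models, file.path(dir, "annotation.gtf"))
  write_cds_fasta(ann$cds, file.path(dir, "cds.fa"))
  write.table(data.frame(gene_id = rownames(cnt$counts), cnt$counts,
                         check.names = FALSE),
              file.path(dir, "counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cnt$design, file.path(dir, "design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cnt$truth, file.path(dir, "truth_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(codon = names(usage$freq), freq = unname(usage$freq)),
              file.path(dir, "codon_usage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (gt in names(cov)) {
    write_bed(cov[[gt]], file.path(dir, paste0("reads_", gt, ".bed")))
    write_bedgraph(cov[[gt]], file.path(dir, paste0("coverage_", gt, ".bedGraph")))
  }
  invisible(list(params = params, annotation = ann, counts = cnt, coverage = cov))
}
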