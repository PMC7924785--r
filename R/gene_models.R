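#' Gene model sets in transcript coordinates
#'
#' A gene model set is a data.frame with one row per transcript carrying the
#' lengths of the three gene-body regions (5'UTR, CDS, 3'UTR) in transcript
#' coordinates. All internal coordinates are 0-based half-open; transcript
#' coordinate 0 is the biological 5' end regardless of genomic strand.
#' Conversion to/from 1-based inclusive happens only at the GTF boundary.
#'
#' @param gene_id,transcript_id character vectors.
#' @param strand "+" or "-" (the genomic strand of origin; informational once
#'   in transcript coordinates).
#' @param utr5_len,cds_len,utr3_len non-negative integer region lengths.
#' @param tx_len optional transcript lengths; defaults to the region sum.
#'   May exceed the region sum only for transcripts without an annotated CDS
#'   (those are kept for full-length analyses but skipped by region-based
#'   ones).
#' @return A data.frame of class `gene_model_set` with columns `gene_id`,
#'   `transcript_id`, `strand`, `utr5_len`, `cds_len`, `utr3_len`, `tx_len`,
#'   `has_cds`.
#' @export
gene_model_set <- function(gene_id, transcript_id, strand,
                           utr5_len, cds_len, utr3_len, tx_len = NULL) {
  models <- data.frame(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    strand = as.character(strand),
    utr5_len = as.integer(utr5_len),
    cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    stringsAsFactors = FALSE
  )
  models$tx_len <- if (is.null(tx_len)) {
    models$utr5_len + models$cds_len + models$utr3_len
  } else {
    as.integer(tx_len)
  }
  models$has_cds <- models$cds_len > 0L
  class(models) <- c("gene_model_set", "data.frame")
  validate_gene_models(models)
  models
}

#' Validate gene model invariants
#'
#' Checks: unique transcript ids, non-negative region lengths, CDS length
#' divisible by 3 where a CDS is present, region lengths summing to the
#' transcript length.
#'
#' @param models a `gene_model_set`.
#' @return `models`, invisibly; errors on violation.
#' @export
validate_gene_models <- function(models) {
  stopifnot(is.data.frame(models))
  if (anyDuplicated(models$transcript_id)) {
    stop("duplicated transcript_id: ",
         paste(unique(models$transcript_id[duplicated(models$transcript_id)]),
               collapse = ", "))
  }
  if (any(models$utr5_len < 0 | models$cds_len < 0 | models$utr3_len < 0)) {
    stop("negative region length")
  }
  bad <- models$has_cds & models$cds_len %% 3L != 0L
  if (any(bad)) {
    stop("CDS length not divisible by 3 for transcript(s): ",
         paste(models$transcript_id[bad], collapse = ", "))
  }
  sum_reg <- models$utr5_len + models$cds_len + models$utr3_len
  bad_sum <- (models$has_cds & models$tx_len != sum_reg) |
    (!models$has_cds & models$tx_len < sum_reg)
  if (any(bad_sum)) {
    stop("region lengths do not sum to transcript length for: ",
         paste(models$transcript_id[bad_sum], collapse = ", "))
  }
  invisible(models)
}

#' Region intervals of one transcript
#'
#' Returns the 5'UTR/CDS/3'UTR intervals of a transcript in 0-based half-open
#' transcript coordinates: contiguous, ordered 5'UTR < CDS < 3'UTR, covering
#' `[0, tx_len)`.
#'
#' @param models a `gene_model_set`.
#' @param transcript_id id of the transcript.
#' @return list with elements `utr5`, `cds`, `utr3`, each `c(start, end)`.
#' @export
region_map <- function(models, transcript_id) {
  i <- match(transcript_id, models$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  l5 <- models$utr5_len[i]; lc <- models$cds_len[i]; l3 <- models$utr3_len[i]
  list(utr5 = c(0L, l5),
       cds  = c(l5, l5 + lc),
       utr3 = c(l5 + lc, l5 + lc + l3))
}

#' Keep only the longest isoform per gene
#'
#' For genes with multiple isoforms only the longest (total transcript length)
#' is retained; length ties are broken by the lexicographically smallest
#' transcript id so the choice is deterministic.
#'
#' @param models a `gene_model_set`.
#' @return a `gene_model_set` with exactly one transcript per gene.
#' @export
select_longest_isoform <- function(models) {
  ord <- order(models$gene_id, -models$tx_len, models$transcript_id)
  m <- models[ord, , drop = FALSE]
  m <- m[!duplicated(m$gene_id), , drop = FALSE]
  m <- m[order(m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("gene_model_set", "data.frame")
  m
}

#' Per-gene region lengths
#'
#' Exact lengths of the full transcript and of each gene-body region, taken
#' from (longest-isoform) gene models. Genes lacking an annotated region get
#' length 0 for it and are flagged.
#'
#' @param models a `gene_model_set` (one transcript per gene).
#' @return data.frame with columns `gene_id`, `transcript_id`, `full`, `utr5`,
#'   `cds`, `utr3`, `incomplete` (TRUE when any region has length 0).
#' @export
region_lengths <- function(models) {
  data.frame(
    gene_id = models$gene_id,
    transcript_id = models$transcript_id,
    full = models$tx_len,
    utr5 = models$utr5_len,
    cds = models$cds_len,
    utr3 = models$utr3_len,
    incomplete = models$utr5_len == 0L | models$cds_len == 0L |
      models$utr3_len == 0L,
    stringsAsFactors = FALSE
  )
}
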