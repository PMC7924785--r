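#' Parse an Ensembl-style GTF into transcript-coordinate gene models
#'
#' Reads exon/CDS/five_prime_utr/three_prime_utr features (1-based inclusive
#' genomic coordinates) and collapses them to per-transcript region lengths in
#' 0-based half-open transcript coordinates, with transcript coordinate 0 at
#' the biological 5' end (i.e. strand is already accounted for). Transcripts
#' without an annotated CDS keep their exon-derived length but carry zero
#' region lengths and `has_cds = FALSE`; they are retained for full-length
#' (metagene) analyses and skipped by region-based ones.
#'
#' @param path path to a GTF file.
#' @return a [gene_model_set()].
#' @export
parse_gtf <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    stop("malformed GTF line ", which(body)[which(nf < 9L)[1]],
         " in ", path, " (fewer than 9 tab-separated fields)")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- gr$type %in% c("exon", "CDS", "five_prime_utr", "three_prime_utr")
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no exon/CDS/UTR features in ", path)
  tid <- as.character(gr$transcript_id)
  gid <- as.character(gr$gene_id)
  type <- as.character(gr$type)
  w <- GenomicRanges::width(gr)
  std <- as.character(GenomicRanges::strand(gr))

  # overlapping region features within a transcript are a validation error
  reg <- type != "exon"
  if (any(reg)) {
    by_tx <- split(gr[reg], tid[reg])
    ov <- vapply(by_tx, function(g) {
      # adjacency is fine; a genuine overlap shrinks the reduced width
      sum(GenomicRanges::width(g)) !=
        sum(GenomicRanges::width(GenomicRanges::reduce(g)))
    }, logical(1))
    if (any(ov)) {
      stop("overlapping region features in transcript(s): ",
           paste(names(by_tx)[ov], collapse = ", "))
    }
  }

  sum_by <- function(sel) {
    s <- tapply(w[sel], tid[sel], sum)
    s[is.na(s)] <- 0
    s
  }
  txs <- sort(unique(tid))
  get_len <- function(feature) {
    s <- sum_by(type == feature)
    out <- setNames(integer(length(txs)), txs)
    out[names(s)] <- as.integer(s)
    out
  }
  exon_len <- get_len("exon")
  utr5 <- get_len("five_prime_utr")
  cds <- get_len("CDS")
  utr3 <- get_len("three_prime_utr")

  first <- !duplicated(tid)
  gene_of <- setNames(gid[first], tid[first])[txs]
  strand_of <- setNames(std[first], tid[first])[txs]

  # for transcripts with exon features, exons define the transcript length
  # and must agree with the regions when a CDS is annotated
  tx_len <- ifelse(exon_len > 0L, exon_len, utr5 + cds + utr3)
  with_cds <- cds > 0L
  mismatch <- with_cds & exon_len > 0L & exon_len != utr5 + cds + utr3
  if (any(mismatch)) {
    stop("exon length != 5'UTR+CDS+3'UTR for transcript(s): ",
         paste(txs[mismatch], collapse = ", "))
  }
  no_cds <- !with_cds
  gene_model_set(
    gene_id = gene_of,
    transcript_id = txs,
    strand = strand_of,
    utr5_len = ifelse(no_cds, 0L, utr5),
    cds_len = cds,
    utr3_len = ifelse(no_cds, 0L, utr3),
    tx_len = as.integer(tx_len)
  )
}

#' Write gene models back to GTF
#'
#' Each transcript is laid out contiguously on its own sequence (named by its
#' transcript id) starting at base 1, with region features ordered so that the
#' 5'UTR sits at the 5' end of the declared strand. Round-trips through
#' [parse_gtf()] preserving ids, strands and region lengths.
#'
#' @param models a [gene_model_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    L <- m$tx_len
    feats <- data.frame(type = "exon", start = 1L, end = L)
    if (m$has_cds) {
      l5 <- m$utr5_len; lc <- m$cds_len; l3 <- m$utr3_len
      if (m$strand == "+") {
        seg <- data.frame(
          type = c("five_prime_utr", "CDS", "three_prime_utr"),
          start = c(1L, l5 + 1L, l5 + lc + 1L),
          end = c(l5, l5 + lc, l5 + lc + l3)
        )
      } else {
        # on the minus strand the 5'UTR occupies the genomic high end
        seg <- data.frame(
          type = c("three_prime_utr", "CDS", "five_prime_utr"),
          start = c(1L, l3 + 1L, l3 + lc + 1L),
          end = c(l3, l3 + lc, l3 + lc + l5)
        )
      }
      feats <- rbind(feats, seg[seg$end >= seg$start, ])
    }
    feats$seqnames <- m$transcript_id
    feats$strand <- m$strand
    feats$gene_id <- m$gene_id
    feats$transcript_id <- m$transcript_id
    rows[[i]] <- feats
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqnames,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand
  )
  gr$type <- tab$type
  gr$gene_id <- tab$gene_id
  gr$transcript_id <- tab$transcript_id
  gr$source <- "decaylens"
  gr$phase <- ifelse(tab$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Load a codon usage table
#'
#' Reads a two-column codon/frequency TSV (Kazusa-style exports vary between
#' raw counts and per-thousand frequencies; values are normalized internally
#' to per-thousand). RNA codons (U) are accepted and converted to DNA.
#'
#' @param path path to the TSV.
#' @return a `codon_usage` object: list with `freq` (named per-thousand
#'   frequencies over all 64 codons) and `code` (codon -> amino acid, standard
#'   genetic code).
#' @export
load_codon_usage <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(raw[[2]])) {   # header row present
    raw <- raw[-1, , drop = FALSE]
    raw[[2]] <- as.numeric(raw[[2]])
  }
  codon_usage(setNames(raw[[2]], raw[[1]]))
}

#' Construct and validate a codon usage table
#'
#' @param freq named numeric vector, codon -> frequency (counts or
#'   per-thousand; normalized to per-thousand).
#' @return a `codon_usage` object (see [load_codon_usage()]).
#' @export
codon_usage <- function(freq) {
  names(freq) <- toupper(chartr("Uu", "Tt", names(freq)))
  code <- Biostrings::GENETIC_CODE
  missing <- setdiff(names(code), names(freq))
  if (length(missing)) {
    stop("codon usage table missing codon(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(freq), names(code))
  if (length(extra)) {
    stop("unknown codon(s): ", paste(extra, collapse = ", "))
  }
  freq <- freq[names(code)]
  if (any(!is.finite(freq)) || any(freq < 0)) stop("negative or non-finite codon frequency")
  if (sum(freq) <= 0) stop("all codon frequencies are zero")
  freq <- freq / sum(freq) * 1000
  structure(list(freq = freq, code = code), class = "codon_usage")
}

#' Relative adaptiveness weights w of a usage table
#'
#' w(codon) = frequency / maximum frequency within the codon's synonymous
#' family. Zero-frequency codons are floored at `floor_frac / max family
#' frequency` (default 0.5 pseudo-observations) so log-weights stay finite;
#' floored codons are flagged.
#'
#' @param usage a `codon_usage`.
#' @param floor_frac pseudo-frequency used for zero-frequency codons.
#' @return data.frame with columns `codon`, `aa`, `w`, `floored`.
#' @export
codon_weights <- function(usage, floor_frac = 0.5) {
  stopifnot(inherits(usage, "codon_usage"))
  aa <- usage$code
  fam_max <- tapply(usage$freq, aa[names(usage$freq)], max)
  w <- usage$freq / fam_max[aa[names(usage$freq)]]
  floored <- usage$freq == 0
  w[floored] <- floor_frac / fam_max[aa[names(usage$freq)]][floored]
  data.frame(codon = names(usage$freq), aa = unname(aa[names(usage$freq)]),
             w = unname(w), floored = unname(floored),
             stringsAsFactors = FALSE)
}

#' Read CDS sequences from FASTA
#'
#' @param path FASTA path; record names are transcript ids.
#' @return a named character vector of DNA sequences.
#' @export
read_cds_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' Write CDS sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' A per-transcript coverage track
#'
#' @param transcript_id transcript id.
#' @param depth numeric vector of per-position depth (one entry per
#'   transcript position, 0-based positions `0 .. length-1`).
#' @param reads optional integer matrix with columns `start`, `end`
#'   (0-based half-open read intervals in transcript coordinates).
#' @return a `coverage_track` object.
#' @export
coverage_track <- function(transcript_id, depth, reads = NULL) {
  stopifnot(all(depth >= 0))
  if (!is.null(reads)) {
    reads <- matrix(as.integer(reads), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
  }
  structure(list(transcript_id = transcript_id,
                 depth = as.numeric(depth), reads = reads),
            class = "coverage_track")
}

#' Positional depth implied by read intervals
#'
#' @param reads integer matrix with columns start, end (0-based half-open).
#' @param tx_len transcript length.
#' @return numeric depth vector of length `tx_len`.
#' @export
depth_from_reads <- function(reads, tx_len) {
  depth <- numeric(tx_len)
  if (is.null(reads) || nrow(reads) == 0L) return(depth)
  # difference array: +1 at start, -1 at end, cumsum gives coverage
  d <- numeric(tx_len + 1L)
  for (i in seq_len(nrow(reads))) {
    d[reads[i, 1] + 1L] <- d[reads[i, 1] + 1L] + 1
    d[reads[i, 2] + 1L] <- d[reads[i, 2] + 1L] - 1
  }
  cumsum(d)[seq_len(tx_len)]
}

#' Load per-transcript coverage from a bedGraph file
#'
#' bedGraph records are 0-based half-open with chrom names equal to transcript
#' ids of `models`. Positions not covered by any record get depth 0; an empty
#' file yields all-zero tracks for every model.
#'
#' @param path bedGraph path.
#' @param models a [gene_model_set()].
#' @return named list of [coverage_track()], one per transcript in `models`.
#' @export
load_coverage <- function(path, models) {
  tracks <- lapply(seq_len(nrow(models)), function(i) {
    coverage_track(models$transcript_id[i], numeric(models$tx_len[i]))
  })
  names(tracks) <- models$transcript_id
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(tracks)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(tracks)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(chrom, models$transcript_id)
  if (length(unknown)) {
    stop("bedGraph names unknown transcript(s): ", paste(unknown, collapse = ", "))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)          # 1-based inclusive end == half-open end
  val <- gr$score
  tx_len <- setNames(models$tx_len, models$transcript_id)
  over <- end0 > tx_len[chrom] | start0 < 0L
  if (any(over)) {
    stop("bedGraph record beyond transcript length for: ",
         paste(unique(chrom[over]), collapse = ", "))
  }
  for (j in seq_along(gr)) {
    tid <- chrom[j]
    idx <- (start0[j] + 1L):end0[j]
    tracks[[tid]]$depth[idx] <- tracks[[tid]]$depth[idx] + val[j]
  }
  tracks
}

#' Load read intervals from a BED file
#'
#' BED records (0-based half-open) in transcript coordinates; chrom names are
#' transcript ids. Reads are attached to all-zero-initialized coverage tracks
#' and the depth recomputed from them.
#'
#' @param path BED path.
#' @param models a [gene_model_set()].
#' @return named list of [coverage_track()] with `reads` set.
#' @export
load_reads <- function(path, models) {
  gr <- rtracklayer::import(path, format = "bed")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(chrom, models$transcript_id)
  if (length(unknown)) {
    stop("BED names unknown transcript(s): ", paste(unknown, collapse = ", "))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  tx_len <- setNames(models$tx_len, models$transcript_id)
  over <- end0 > tx_len[chrom] | start0 < 0L
  if (any(over)) {
    stop("BED record beyond transcript length for: ",
         paste(unique(chrom[over]), collapse = ", "))
  }
  tracks <- lapply(seq_len(nrow(models)), function(i) {
    tid <- models$transcript_id[i]
    sel <- chrom == tid
    reads <- cbind(start = start0[sel], end = end0[sel])
    coverage_track(tid, depth_from_reads(reads, models$tx_len[i]), reads)
  })
  names(tracks) <- models$transcript_id
  tracks
}

#' Write coverage tracks as bedGraph
#'
#' Runs of equal nonzero depth become one record each (0-based half-open).
#'
#' @param tracks named list of [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    if (length(tr$depth) == 0L || all(tr$depth == 0)) next
    r <- rle(tr$depth)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", tr$transcript_id,
                       starts[keep], ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Write read intervals as BED6
#'
#' @param tracks named list of [coverage_track()] with `reads` set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    if (is.null(tr$reads) || nrow(tr$reads) == 0L) next
    writeLines(sprintf("%s\t%d\t%d\tread\t0\t+", tr$transcript_id,
                       tr$reads[, "start"], tr$reads[, "end"]), con)
  }
  invisible(path)
}
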