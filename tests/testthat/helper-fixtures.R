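# shared fixtures, built in code and memoized across test files

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the default study-scale simulation used by recovery tests (seed fixed)
default_sim <- function() {
  memo("default_sim", {
    p <- sim_params(seed = 11)
    ann <- simulate_annotation(p)
    cnt <- simulate_counts(ann$models, p)
    cov <- simulate_coverage(ann$models, cnt$truth, p)
    deg <- call_degs(cnt$counts, cnt$design)
    list(params = p, models = ann$models, cds = ann$cds,
         counts = cnt$counts, design = cnt$design, truth = cnt$truth,
         cov = cov, deg = deg)
  })
}

# a tiny three-gene/five-transcript annotation written as a GTF fixture
write_tiny_gtf <- function(path) {
  lines <- c(
    # geneA txA1: + strand, utr5 60, cds 300, utr3 140 (total 500)
    gtf_line("chr1", "exon", 1, 500, "+", "geneA", "txA1"),
    gtf_line("chr1", "five_prime_utr", 1, 60, "+", "geneA", "txA1"),
    gtf_line("chr1", "CDS", 61, 360, "+", "geneA", "txA1"),
    gtf_line("chr1", "three_prime_utr", 361, 500, "+", "geneA", "txA1"),
    # geneA txA2: shorter isoform, length 300
    gtf_line("chr1", "exon", 1000, 1299, "+", "geneA", "txA2"),
    gtf_line("chr1", "five_prime_utr", 1000, 1029, "+", "geneA", "txA2"),
    gtf_line("chr1", "CDS", 1030, 1269, "+", "geneA", "txA2"),
    gtf_line("chr1", "three_prime_utr", 1270, 1299, "+", "geneA", "txA2"),
    # geneB: minus strand, utr5 60 / cds 300 / utr3 140; 5'UTR at high coords
    gtf_line("chr2", "exon", 1, 500, "-", "geneB", "txB1"),
    gtf_line("chr2", "three_prime_utr", 1, 140, "-", "geneB", "txB1"),
    gtf_line("chr2", "CDS", 141, 440, "-", "geneB", "txB1"),
    gtf_line("chr2", "five_prime_utr", 441, 500, "-", "geneB", "txB1"),
    # geneC: two isoforms of equal length 600, ids tCb < tCa lexicographically
    gtf_line("chr3", "exon", 1, 600, "+", "geneC", "tCb"),
    gtf_line("chr3", "five_prime_utr", 1, 100, "+", "geneC", "tCb"),
    gtf_line("chr3", "CDS", 101, 400, "+", "geneC", "tCb"),
    gtf_line("chr3", "three_prime_utr", 401, 600, "+", "geneC", "tCb"),
    gtf_line("chr3", "exon", 1000, 1599, "+", "geneC", "tCa"),
    gtf_line("chr3", "five_prime_utr", 1000, 1099, "+", "geneC", "tCa"),
    gtf_line("chr3", "CDS", 1100, 1399, "+", "geneC", "tCa"),
    gtf_line("chr3", "three_prime_utr", 1400, 1599, "+", "geneC", "tCa")
  )
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start, end, strand, gene, tx) {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, type, start, end, strand, gene, tx)
}

# usage table with one two-codon family skewed 2:1 (GAA:GAG), rest uniform
skewed_usage <- function() {
  f <- setNames(rep(10, 64), names(Biostrings::GENETIC_CODE))
  f["GAA"] <- 20
  f["GAG"] <- 10
  codon_usage(f)
}

random_cds <- function(n_codons, rng_codons = NULL) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
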