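#' Mutant allele genotyping arithmetic
#'
#' The mutant allele carries a deletion partially compensated by a small
#' insertion; genotyping PCR distinguishes alleles by amplicon size. Given the
#' deleted and inserted lengths and the wild-type amplicon length, returns the
#' net deletion and the expected mutant amplicon length.
#'
#' @param deletion_nt nucleotides deleted (default 214).
#' @param insertion_nt nucleotides inserted (default 11).
#' @param wt_amplicon_nt wild-type PCR product length (default 330).
#' @return list with `net_deletion_nt` and `mutant_amplicon_nt`.
#' @export
genotyping_arithmetic <- function(deletion_nt = 214, insertion_nt = 11,
                                  wt_amplicon_nt = 330) {
  stopifnot(deletion_nt >= 0, insertion_nt >= 0, wt_amplicon_nt > 0)
  net <- deletion_nt - insertion_nt
  list(net_deletion_nt = net,
       mutant_amplicon_nt = wt_amplicon_nt - net)
}
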