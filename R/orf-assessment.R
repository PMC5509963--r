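## ORF conservation of a called retrocopy: frameshifts and premature stop
## codons relative to the parental protein, assessed in the parental reading
## frame as propagated through the alignment chain (re-anchored after every
## indel).

#' Assess ORF conservation of a retrocopy
#'
#' Walks the protein-to-genome chain over the retrocopy sequence. Every
#' inter-block indel whose net length is not a multiple of 3 (target-side
#' gap minus 3 bp per unaligned query residue) counts one frameshift; two
#' compensating frameshifts count as two events. Every aligned codon that
#' translates to a stop counts one premature stop. The ORF is conserved iff
#' both counts are zero.
#'
#' @param retro_sequence strand-corrected nucleotide sequence of the
#'   chain's target region (character or [Biostrings::DNAString]); position
#'   1 corresponds to the first strand-local base of the target
#' @param chain the protein-vs-genome `alignment_chain` of the call
#' @param genetic_code codon table, default [Biostrings::GENETIC_CODE]
#' @return list with `frameshift_count`, `premature_stops`, `orf_conserved`
#' @export
assess_orf <- function(retro_sequence, chain,
                       genetic_code = Biostrings::GENETIC_CODE) {
  stopifnot(chain$protein_query)
  s <- as.character(retro_sequence)
  b <- chain$blocks
  span_end <- b$tstart[nrow(b)] + 3L * b$len[nrow(b)] - 1L
  if (nchar(s) < span_end)
    stop("sequence shorter than the chain's target span (need ", span_end,
         " bp, got ", nchar(s), ")")
  fs <- 0L
  if (nrow(b) > 1) for (i in seq_len(nrow(b) - 1L)) {
    t_gap <- b$tstart[i + 1L] - (b$tstart[i] + 3L * b$len[i])
    q_gap <- b$qstart[i + 1L] - (b$qstart[i] + b$len[i])
    if ((t_gap - 3L * q_gap) %% 3L != 0L) fs <- fs + 1L
  }
  stops <- 0L
  for (i in seq_len(nrow(b))) {
    block_seq <- substring(s, b$tstart[i], b$tstart[i] + 3L * b$len[i] - 1L)
    codons <- substring(block_seq, seq(1, nchar(block_seq), 3),
                        seq(3, nchar(block_seq), 3))
    aas <- genetic_code[codons]
    stops <- stops + sum(aas == "*", na.rm = TRUE)
  }
  list(frameshift_count = fs, premature_stops = as.integer(stops),
       orf_conserved = fs == 0L && stops == 0L)
}

#' Append ORF reports to a calls table
#'
#' Runs [assess_orf()] for each call using the genome attached to the gene
#' set, and appends `frameshifts`, `premature_stops` and `orf_conserved`
#' columns.
#'
#' @param calls a `retrocopy_calls` data.frame (with chains attached)
#' @param genome a [Biostrings::DNAStringSet]
#' @return the calls with three ORF columns added
#' @export
annotate_orf <- function(calls, genome) {
  chains <- attr(calls, "chains")
  reports <- lapply(seq_len(nrow(calls)), function(i) {
    ch <- chains[[i]]
    seq <- genome[[calls$chrom[i]]]
    target <- Biostrings::subseq(seq, calls$start[i], calls$end[i])
    if (calls$strand[i] == "-") target <- Biostrings::reverseComplement(target)
    ## shift block coordinates so the locus starts at position 1
    ch$blocks$tstart <- ch$blocks$tstart - (ch$blocks$tstart[1] - 1L)
    assess_orf(target, ch)
  })
  calls$frameshifts <- vapply(reports, `[[`, 0L, "frameshift_count")
  calls$premature_stops <- vapply(reports, `[[`, 0L, "premature_stops")
  calls$orf_conserved <- vapply(reports, `[[`, NA, "orf_conserved")
  calls
}
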