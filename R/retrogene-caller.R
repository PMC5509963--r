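## KNOWN_PROTEIN_CODING retrogenes: annotated single-exon coding genes that
## arose by retroposition, recovered from proteome self-alignments. Here both
## query and target of a chain are proteins (query = candidate retrogene,
## target = potential parent); the parent's intron positions are tested
## against the target-side aligned span.

#' Remove self- and isoform-level alignments
#'
#' Drops chains whose query and target proteins belong to the same gene,
#' including trivial self-hits.
#'
#' @param chains list of protein-vs-protein `alignment_chain`
#' @param genes a `gene_set` mapping transcript ids to genes
#' @return filtered chain list
#' @export
filter_self_alignments <- function(chains, genes) {
  tmap <- transcript_gene_map(genes)
  keep <- vapply(chains, function(ch) {
    qg <- tmap[[ch$query_id]] %||% NA_character_
    tg <- tmap[[ch$t_name]] %||% NA_character_
    !is.na(qg) && !is.na(tg) && qg != tg
  }, NA)
  chains[keep]
}

#' Select retrogene candidate genes
#'
#' A candidate must have exactly one CDS exon in *every* transcript — an
#' intron anywhere in the gene rules out a processed origin.
#'
#' @param genes a `gene_set`
#' @return the filtered `gene_set`
#' @export
select_candidate_genes <- function(genes) {
  keep <- vapply(genes, function(g)
    length(g$transcripts) > 0 &&
      all(vapply(g$transcripts, function(tr) length(tr$cds_exons) == 1L, NA)),
    NA)
  structure(genes[keep], class = "gene_set", genome = attr(genes, "genome"))
}

#' Call KNOWN_PROTEIN_CODING retrogenes from proteome self-alignments
#'
#' Per candidate gene the best-scoring chain to a multi-exon gene is
#' examined: the call requires an aligned coding length of at least 150 bp
#' (50 aa), identity and coverage of at least 50%, and at least two
#' parental introns whose protein positions fall strictly inside the
#' parent-side aligned span after trimming `terminal_exclusion_aa` from
#' each end of that span.
#'
#' @param chains protein-vs-protein chains (already passed through
#'   [filter_self_alignments()]); query = candidate isoform, target =
#'   potential parent isoform
#' @param genes the full `gene_set`
#' @param thresholds a [retro_thresholds()] list
#' @param terminal_exclusion_aa amino acids trimmed from each end of the
#'   parent-side aligned span before counting spanned introns
#' @param trim_mode "aligned_span" trims the aligned span (default);
#'   "absolute" excludes introns within the first/last 10 aa of the whole
#'   parental protein instead
#' @return data.frame with one row per called retrogene: gene_id,
#'   parental_gene_id, identity, coverage, aligned_aa, introns_spanned
#' @export
call_retrogenes <- function(chains, genes, thresholds = retro_thresholds(),
                            terminal_exclusion_aa = 10L,
                            trim_mode = c("aligned_span", "absolute")) {
  trim_mode <- match.arg(trim_mode)
  tmap <- transcript_gene_map(genes)
  candidates <- select_candidate_genes(genes)
  chains <- filter_self_alignments(chains, genes)

  rows <- list()
  for (gid in sort(names(candidates))) {
    tids <- names(candidates[[gid]]$transcripts)
    idx <- which(vapply(chains, function(ch) ch$query_id %in% tids, NA))
    ## restrict to multi-exon targets
    idx <- idx[vapply(chains[idx], function(ch) {
      tg <- tmap[[ch$t_name]] %||% NA_character_
      !is.na(tg) &&
        length(genes[[tg]]$transcripts[[ch$t_name]]$cds_exons) >= 2L
    }, NA)]
    if (length(idx) == 0) next
    parent_gids <- vapply(chains[idx], function(ch) tmap[[ch$t_name]], "")
    best <- assign_parental(chains[idx], parent_gids)
    ch <- chains[[idx[best]]]
    st <- compute_stats(ch)
    aligned_aa <- sum(ch$blocks$len)
    if (aligned_aa * 3L < thresholds$min_aln_bp) next
    if (st$identity < thresholds$min_identity) next
    if (st$coverage < thresholds$min_coverage) next
    parent_tr <- genes[[parent_gids[best]]]$transcripts[[ch$t_name]]
    introns <- protein_intron_positions(parent_tr)
    n_span <- count_trimmed_spanned(ch, introns, terminal_exclusion_aa, trim_mode)
    if (n_span < 2L) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, parental_gene_id = parent_gids[best],
      parental_transcript = ch$t_name,
      identity = st$identity, coverage = st$coverage,
      aligned_aa = aligned_aa, introns_spanned = n_span,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), parental_gene_id = character(0),
                      parental_transcript = character(0), identity = numeric(0),
                      coverage = numeric(0), aligned_aa = integer(0),
                      introns_spanned = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

## count parental introns strictly inside the trimmed parent-side aligned span
count_trimmed_spanned <- function(chain, introns, trim_aa, trim_mode) {
  b <- chain$blocks
  t_lo <- min(b$tstart)                      # parent-side aligned span, aa
  t_hi <- max(b$tstart + b$len) - 1L
  if (trim_mode == "aligned_span") {
    lo <- t_lo + trim_aa
    hi <- t_hi - trim_aa
  } else {
    lo <- max(t_lo, 1L + trim_aa)
    hi <- min(t_hi, chain$t_size - trim_aa)
  }
  if (hi <= lo) return(0L)
  ## intron between parent aa a and a+1; strictly inside [lo, hi]
  sum(introns$aa_offset >= lo & introns$aa_offset <= hi - 1L)
}
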