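## The core caller: from protein-to-genome alignment chains and parental
## gene models, diagnose intron loss, apply the filters, resolve overlapping
## candidates, classify status against known pseudogenes and flag suspicious
## parents.

#' Filter thresholds for retrocopy calling
#'
#' Defaults are the published cut-offs: minimum alignment length 150 bp,
#' minimum identity and coverage 50% against the parental protein, loss of
#' at least two introns, 50% overlap with known pseudogene annotation for
#' KNOWN_PSEUDOGENE status, and parent-flagging counts of >50 retrocopies
#' for mammals and >5 for other organisms. `retained_intron_min_gap` is the
#' smallest target-side gap (bp) at an intron's protein position that still
#' counts as a retained intron; gaps below it (shorter than any credible
#' spliceosomal intron) count the intron as lost.
#'
#' @param min_aln_bp minimum aligned length on the genome, bp
#' @param min_identity minimum identity to the parental protein, in `[0,1]`
#' @param min_coverage minimum coverage of the parental protein, in `[0,1]`
#' @param min_lost_introns minimum number of lost introns
#' @param pseudo_overlap minimum overlap fraction with known pseudogenes
#'   for KNOWN_PSEUDOGENE status
#' @param retained_intron_min_gap bp; target gaps below this count as loss
#' @param mammal_flag_count,other_flag_count parent-flagging counts
#' @return a `retro_thresholds` list
#' @export
retro_thresholds <- function(min_aln_bp = 150L, min_identity = 0.50,
                             min_coverage = 0.50, min_lost_introns = 2L,
                             pseudo_overlap = 0.50,
                             retained_intron_min_gap = 30L,
                             mammal_flag_count = 50L, other_flag_count = 5L) {
  stopifnot(min_aln_bp >= 0, min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1, min_lost_introns >= 0,
            pseudo_overlap >= 0, pseudo_overlap <= 1,
            retained_intron_min_gap >= 0)
  structure(list(min_aln_bp = min_aln_bp, min_identity = min_identity,
                 min_coverage = min_coverage,
                 min_lost_introns = min_lost_introns,
                 pseudo_overlap = pseudo_overlap,
                 retained_intron_min_gap = retained_intron_min_gap,
                 mammal_flag_count = mammal_flag_count,
                 other_flag_count = other_flag_count),
            class = "retro_thresholds")
}

#' Diagnose intron loss from a protein-to-genome chain
#'
#' An intron of the parental transcript is *spanned* when its amino-acid
#' offset lies strictly inside the aligned query span (a junction at the
#' alignment edge is uninformative). A spanned intron is *lost* when the
#' target-side gap at that protein position — in excess of 3 bp per
#' unaligned query residue — is smaller than `retained_intron_min_gap`;
#' contiguous alignment through the position means gap 0, hence lost.
#'
#' @param chain protein-vs-genome `alignment_chain`
#' @param introns data.frame from [protein_intron_positions()]
#' @param thresholds a [retro_thresholds()] list
#' @return list with integer vectors `spanned`, `lost`, `retained`
#'   (intron indices)
#' @export
detect_intron_loss <- function(chain, introns, thresholds = retro_thresholds()) {
  stopifnot(chain$protein_query)
  if (is.null(introns) || nrow(introns) == 0)
    stop("empty intron list: parent must be multi-exon")
  b <- chain$blocks
  q_lo <- min(b$qstart)                       # first aligned aa (1-based)
  q_hi <- max(b$qstart + b$len) - 1L          # last aligned aa
  spanned <- integer(0); lost <- integer(0)
  for (r in seq_len(nrow(introns))) {
    a <- introns$aa_offset[r]                 # 0-based aa following the intron
    ## junction between aa positions a and a+1 (1-based)
    if (a < q_lo || a > q_hi - 1L) next
    spanned <- c(spanned, introns$index[r])
    gap <- junction_target_gap(b, a)
    if (gap < thresholds$retained_intron_min_gap)
      lost <- c(lost, introns$index[r])
  }
  list(spanned = spanned, lost = lost, retained = setdiff(spanned, lost))
}

## target-side excess gap (bp) at the junction between query aa `a` and `a+1`
junction_target_gap <- function(b, a) {
  q_end <- b$qstart + b$len - 1L
  within <- which(b$qstart <= a & q_end >= a + 1L)
  if (length(within)) return(0L)
  prev <- which(q_end <= a)
  nxt <- which(b$qstart >= a + 1L)
  prev_contain <- which(b$qstart <= a & q_end >= a)   # block ends exactly at a
  i <- if (length(prev_contain)) max(prev_contain) else max(prev)
  j <- min(nxt)
  t_prev_end <- b$tstart[i] + 3L * (min(a, q_end[i]) - b$qstart[i] + 1L) - 1L
  q_next <- max(a + 1L, b$qstart[j])
  t_next_start <- b$tstart[j] + 3L * (q_next - b$qstart[j])
  q_gap <- (b$qstart[j] - 1L) - q_end[i]              # unaligned query residues
  max(0L, (t_next_start - t_prev_end - 1L) - 3L * max(0L, q_gap))
}

#' Resolve overlapping candidate chains at one locus
#'
#' The best-scoring alignment wins; ties fall through to highest identity,
#' then highest coverage, then lexicographically smallest parental gene id,
#' so the outcome is independent of input order.
#'
#' @param chains list of `alignment_chain` overlapping one locus
#' @param parent_ids parental gene id per chain
#' @return index of the winning chain
#' @export
assign_parental <- function(chains, parent_ids) {
  stopifnot(length(chains) >= 1, length(parent_ids) == length(chains))
  st <- lapply(chains, compute_stats)
  score <- vapply(chains, function(ch) ch$score, 0)
  ident <- vapply(st, `[[`, 0, "identity")
  cov <- vapply(st, `[[`, 0, "coverage")
  order(-score, -ident, -cov, parent_ids)[1]
}

#' Classify a call against known pseudogene annotation
#'
#' The overlap fraction is the portion of the call locus covered by the
#' union of known-pseudogene intervals, relative to the call's own length;
#' at or above the cut-off (default 50%, inclusive) the status is
#' KNOWN_PSEUDOGENE, otherwise NOVEL.
#'
#' @param locus a length-1 GRanges
#' @param known_pseudogenes GRanges of annotated pseudogenes (or NULL)
#' @param pseudo_overlap overlap fraction cut-off
#' @return "KNOWN_PSEUDOGENE" or "NOVEL"
#' @export
classify_status <- function(locus, known_pseudogenes,
                            pseudo_overlap = 0.50) {
  if (is.null(known_pseudogenes) || length(known_pseudogenes) == 0)
    return("NOVEL")
  red <- GenomicRanges::reduce(known_pseudogenes, ignore.strand = TRUE)
  ov <- GenomicRanges::intersect(GenomicRanges::granges(locus), red,
                                 ignore.strand = TRUE)
  frac <- sum(GenomicRanges::width(ov)) / GenomicRanges::width(locus)
  if (frac >= pseudo_overlap) "KNOWN_PSEUDOGENE" else "NOVEL"
}

## map transcript (protein query) ids to gene ids
transcript_gene_map <- function(genes) {
  tid <- unlist(lapply(genes, function(g) names(g$transcripts)), use.names = FALSE)
  gid <- unlist(lapply(genes, function(g)
    rep(g$gene_id, length(g$transcripts))), use.names = FALSE)
  setNames(gid, tid)
}

#' Call retrocopies from protein-to-genome alignment chains
#'
#' Applies the retrocopy filters to each chain (aligned length, identity,
#' coverage against the parental protein, and loss of at least two
#' introns), removes chains overlapping their parental gene's own locus,
#' resolves overlapping candidates at a locus to the best-scoring parent
#' ([assign_parental()]), classifies each call against known pseudogenes
#' and flags suspicious parents.
#'
#' @param chains list of protein-vs-genome `alignment_chain`; query ids are
#'   transcript ids of genes in `genes`
#' @param genes a `gene_set` (multi-exon parents are used; other queries
#'   are ignored)
#' @param known_pseudogenes GRanges of annotated pseudogenes, or NULL
#' @param thresholds a [retro_thresholds()] list
#' @param clade "mammal" or "other"; sets the parent-flagging count
#' @param species_prefix prefix for deterministic retrocopy ids
#' @return a `retrocopy_calls` data.frame with one row per call; the
#'   winning chains are attached as attribute `chains`
#' @export
call_retrocopies <- function(chains, genes, known_pseudogenes = NULL,
                             thresholds = retro_thresholds(),
                             clade = c("mammal", "other"),
                             species_prefix = "RC") {
  clade <- match.arg(clade)
  tmap <- transcript_gene_map(genes)
  cand <- list(); cand_parent <- character(0)
  for (ch in chains) {
    gid <- tmap[[ch$query_id]] %||% NA_character_
    if (is.na(gid)) next
    g <- genes[[gid]]
    tr <- g$transcripts[[ch$query_id]]
    if (length(tr$cds_exons) < 2L) next       # single-exon query: not a parent
    st <- compute_stats(ch)
    if (st$aln_len_bp < thresholds$min_aln_bp) next
    if (st$identity < thresholds$min_identity) next
    if (st$coverage < thresholds$min_coverage) next
    loss <- detect_intron_loss(ch, protein_intron_positions(tr), thresholds)
    if (length(loss$lost) < thresholds$min_lost_introns) next
    ## self-locus exclusion: any overlap with the parent's own span
    if (ch$t_name == g$seq_id &&
        ch$t_start <= g$end && ch$t_end >= g$start) next
    cand[[length(cand) + 1L]] <- c(ch, list(.loss = loss, .stats = st))
    cand_parent <- c(cand_parent, gid)
  }
  if (length(cand) == 0) return(empty_calls())

  ## cluster candidates sharing a locus (>=1 bp overlap, same strand)
  gr <- GenomicRanges::GRanges(
    vapply(cand, `[[`, "", "t_name"),
    IRanges::IRanges(vapply(cand, function(x) x$t_start, 0L),
                     vapply(cand, function(x) x$t_end, 0L)),
    strand = vapply(cand, `[[`, "", "strand"))
  cl <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr), select = "first")
  winners <- integer(0)
  for (k in unique(cl)) {
    idx <- which(cl == k)
    w <- assign_parental(lapply(cand[idx], function(x) {
      x$.loss <- NULL; x$.stats <- NULL
      class(x) <- "alignment_chain"; x
    }), cand_parent[idx])
    winners <- c(winners, idx[w])
  }
  ## deterministic ids by genomic sort
  wgr <- gr[winners]
  ord <- order(as.character(GenomicRanges::seqnames(wgr)),
               GenomicRanges::start(wgr), GenomicRanges::end(wgr))
  winners <- winners[ord]

  rows <- lapply(seq_along(winners), function(i) {
    x <- cand[[winners[i]]]
    locus <- GenomicRanges::GRanges(x$t_name,
                                    IRanges::IRanges(x$t_start, x$t_end),
                                    strand = x$strand)
    data.frame(
      retrocopy_id = sprintf("%s_%04d", species_prefix, i),
      chrom = x$t_name, start = x$t_start, end = x$t_end, strand = x$strand,
      parental_gene = cand_parent[winners[i]],
      parental_transcript = x$query_id,
      identity = x$.stats$identity, coverage = x$.stats$coverage,
      aln_len_bp = x$.stats$aln_len_bp,
      introns_spanned = length(x$.loss$spanned),
      introns_lost = length(x$.loss$lost),
      status = classify_status(locus, known_pseudogenes,
                               thresholds$pseudo_overlap),
      flagged = FALSE, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  flagged_parents <- flag_suspicious_parents(calls, genes, clade, thresholds)
  calls$flagged <- calls$parental_gene %in% flagged_parents
  win_chains <- lapply(cand[winners], function(x) {
    x$.loss <- NULL; x$.stats <- NULL; class(x) <- "alignment_chain"; x
  })
  structure(calls, class = c("retrocopy_calls", "data.frame"),
            chains = win_chains)
}

empty_calls <- function() {
  structure(data.frame(retrocopy_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), parental_gene = character(0),
                       parental_transcript = character(0),
                       identity = numeric(0), coverage = numeric(0),
                       aln_len_bp = integer(0), introns_spanned = integer(0),
                       introns_lost = integer(0), status = character(0),
                       flagged = logical(0), stringsAsFactors = FALSE),
            class = c("retrocopy_calls", "data.frame"), chains = list())
}

#' Flag parents with implausibly many retrocopies and no described protein
#'
#' Parents accumulating more retrocopies than the clade cut-off (>50 for
#' mammals, >5 for other organisms) *and* annotated "protein unknown" are
#' candidate false positives (often transposon-derived). They are reported
#' for review, not removed.
#'
#' @param calls a `retrocopy_calls` data.frame
#' @param genes the `gene_set` with gene descriptions
#' @param clade "mammal" or "other"
#' @param thresholds a [retro_thresholds()] list
#' @return character vector of flagged parental gene ids
#' @export
flag_suspicious_parents <- function(calls, genes, clade = c("mammal", "other"),
                                    thresholds = retro_thresholds()) {
  clade <- match.arg(clade)
  cut <- if (clade == "mammal") thresholds$mammal_flag_count else
    thresholds$other_flag_count
  counts <- table(calls$parental_gene)
  many <- names(counts)[counts > cut]
  many[vapply(many, function(gid)
    grepl("protein unknown", genes[[gid]]$description %||% "",
          ignore.case = TRUE), NA)]
}

#' @export
print.retrocopy_calls <- function(x, ...) {
  cat("retrocopy_calls:", nrow(x), "call(s)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write retrocopy calls as TSV and BED12
#'
#' The TSV mirrors the per-retrocopy annotation record; the BED12 gives the
#' locus with one block per alignment block for genome-browser display.
#'
#' @param calls a `retrocopy_calls` data.frame
#' @param prefix output path prefix; writes `<prefix>.tsv` and `<prefix>.bed`
#' @export
write_calls <- function(calls, prefix) {
  write.table(as.data.frame(calls), paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  chains <- attr(calls, "chains")
  bed <- vapply(seq_len(nrow(calls)), function(i) {
    ch <- chains[[i]]
    b <- ch$blocks
    u <- if (ch$protein_query) 3L else 1L
    starts_local <- b$tstart - 1L
    sizes <- b$len * u
    if (ch$protein_query && ch$strand == "-") {
      starts_fwd <- ch$t_size - (starts_local + sizes)
      ord <- order(starts_fwd)
      starts_fwd <- starts_fwd[ord]; sizes <- sizes[ord]
    } else starts_fwd <- starts_local
    rel <- starts_fwd - (calls$start[i] - 1L)
    paste(calls$chrom[i], calls$start[i] - 1L, calls$end[i],
          calls$retrocopy_id[i], 0, calls$strand[i],
          calls$start[i] - 1L, calls$end[i], "0,0,0", length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(rel, collapse = ","), ","), sep = "\t")
  }, "")
  writeLines(bed, paste0(prefix, ".bed"))
  invisible(prefix)
}
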