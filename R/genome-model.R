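## Gene models: genes with transcripts, CDS exons, derived introns and the
## canonical protein. These feed both the retrocopy caller (protein-coordinate
## intron positions of parental genes) and the retrogene caller (single-exon
## candidates).

#' Load gene models from GFF3 and a genome FASTA
#'
#' Reads gene/mRNA/CDS features linked by ID/Parent, assembles per-transcript
#' CDS exon chains in transcription order, and translates each coding sequence
#' from the genome (strand- and phase-aware). CDS features are taken to
#' exclude the stop codon; a terminal stop in the translation is stripped.
#'
#' @param gff3_file path to a GFF3 file with gene/mRNA/CDS features
#' @param genome_fasta path to the genome FASTA covering all features, or a
#'   [Biostrings::DNAStringSet]
#' @return a `gene_set`: named list of `gene_model` objects, with the genome
#'   attached as attribute `genome`
#' @details A transcript whose phase-adjusted CDS length is not divisible by
#'   3 is skipped with a warning. A CDS or mRNA whose Parent is unknown is a
#'   parse error naming the offending feature.
#' @export
load_gene_models <- function(gff3_file, genome_fasta) {
  genome <- if (is(genome_fasta, "DNAStringSet")) genome_fasta else
    Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))

  gff <- rtracklayer::import(gff3_file, format = "gff3")
  if (length(gff) == 0) return(structure(list(), class = "gene_set", genome = genome))

  typ <- as.character(gff$type)
  genes_gr <- gff[typ == "gene"]
  mrna_gr  <- gff[typ %in% c("mRNA", "transcript")]
  cds_gr   <- gff[typ == "CDS"]

  gene_ids <- as.character(genes_gr$ID)
  mrna_parent <- vapply(mrna_gr$Parent, function(p) as.character(p)[1], "")
  bad <- which(!(mrna_parent %in% gene_ids))
  if (length(bad))
    stop("transcript feature '", as.character(mrna_gr$ID)[bad[1]],
         "' has unknown Parent '", mrna_parent[bad[1]], "'")
  mrna_ids <- as.character(mrna_gr$ID)
  cds_parent <- vapply(cds_gr$Parent, function(p) as.character(p)[1], "")
  bad <- which(!(cds_parent %in% mrna_ids))
  if (length(bad))
    stop("CDS feature at ", as.character(GenomicRanges::seqnames(cds_gr))[bad[1]], ":",
         GenomicRanges::start(cds_gr)[bad[1]],
         " has unknown Parent '", cds_parent[bad[1]], "'")

  out <- vector("list", length(genes_gr))
  names(out) <- gene_ids
  for (i in seq_along(genes_gr)) {
    gid <- gene_ids[i]
    g <- genes_gr[i]
    tr_idx <- which(mrna_parent == gid)
    transcripts <- list()
    for (j in tr_idx) {
      tid <- mrna_ids[j]
      cds <- cds_gr[cds_parent == tid]
      if (length(cds) == 0) next
      strand <- as.character(GenomicRanges::strand(mrna_gr[j]))
      ## transcription order: ascending on +, descending on -
      ord <- order(GenomicRanges::start(cds),
                   decreasing = identical(strand, "-"))
      cds <- cds[ord]
      phase0 <- suppressWarnings(as.integer(as.character(cds$phase[1])))
      if (is.na(phase0)) phase0 <- 0L
      tr <- build_transcript(tid, cds, strand, phase0, genome)
      if (is.null(tr)) {
        warning("transcript '", tid, "': CDS length not divisible by 3; skipped")
        next
      }
      transcripts[[tid]] <- tr
    }
    out[[gid]] <- structure(list(
      gene_id = gid,
      seq_id = as.character(GenomicRanges::seqnames(g)),
      strand = as.character(GenomicRanges::strand(g)),
      start = GenomicRanges::start(g),
      end = GenomicRanges::end(g),
      biotype = as.character(g$biotype %||% "protein_coding"),
      description = as.character(g$description %||% ""),
      transcripts = transcripts
    ), class = "gene_model")
  }
  structure(out, class = "gene_set", genome = genome)
}

build_transcript <- function(tid, cds, strand, phase0, genome) {
  ## phase adjustment trims incomplete leading codon bases in transcription order
  if (phase0 > 0) {
    if (strand == "-") {
      GenomicRanges::end(cds)[1] <- GenomicRanges::end(cds)[1] - phase0
    } else {
      GenomicRanges::start(cds)[1] <- GenomicRanges::start(cds)[1] + phase0
    }
  }
  total <- sum(GenomicRanges::width(cds))
  if (total %% 3L != 0L) return(NULL)
  seqs <- lapply(seq_along(cds), function(k) {
    s <- GenomicRanges::seqnames(cds)[k]
    sub <- Biostrings::subseq(genome[[as.character(s)]],
                              GenomicRanges::start(cds)[k],
                              GenomicRanges::end(cds)[k])
    if (strand == "-") sub <- Biostrings::reverseComplement(sub)
    as.character(sub)
  })
  cds_seq <- Biostrings::DNAString(paste(unlist(seqs), collapse = ""))
  prot <- as.character(suppressWarnings(
    Biostrings::translate(cds_seq, if.fuzzy.codon = "X")))
  if (nchar(prot) > 0 && substring(prot, nchar(prot)) == "*")
    prot <- substring(prot, 1, nchar(prot) - 1L)
  names(cds) <- NULL
  list(transcript_id = tid, cds_exons = cds, strand = strand, protein = prot)
}

#' Write gene models back to GFF3
#'
#' Inverse of [load_gene_models()] (coordinates, strands and hierarchy
#' round-trip exactly).
#'
#' @param genes a `gene_set`
#' @param path output GFF3 path
#' @export
write_gene_models <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$seq_id, start = g$start, end = g$end, strand = g$strand,
      type = "gene", ID = g$gene_id, Parent = NA_character_,
      description = if (nzchar(g$description)) g$description else NA_character_,
      phase = NA_integer_, stringsAsFactors = FALSE)
    for (tr in g$transcripts) {
      ex <- tr$cds_exons
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = g$seq_id,
        start = min(GenomicRanges::start(ex)), end = max(GenomicRanges::end(ex)),
        strand = tr$strand, type = "mRNA", ID = tr$transcript_id,
        Parent = g$gene_id, description = NA_character_, phase = NA_integer_,
        stringsAsFactors = FALSE)
      for (k in seq_along(ex)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = g$seq_id, start = GenomicRanges::start(ex)[k],
          end = GenomicRanges::end(ex)[k], strand = tr$strand, type = "CDS",
          ID = paste0(tr$transcript_id, ".cds", k), Parent = tr$transcript_id,
          description = NA_character_, phase = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqid, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(lapply(df$Parent, function(p)
    if (is.na(p)) character(0) else p))
  gr$phase <- df$phase
  gr$description <- df$description
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Keep genes with a multi-exon coding transcript
#'
#' A gene qualifies as a potential retrocopy parent if at least one of its
#' transcripts has two or more CDS exons.
#'
#' @param genes a `gene_set`
#' @return the filtered `gene_set`
#' @export
select_multi_exon <- function(genes) {
  keep <- vapply(genes, function(g)
    any(vapply(g$transcripts, function(tr) length(tr$cds_exons) >= 2L, NA)),
    NA)
  structure(genes[keep], class = "gene_set", genome = attr(genes, "genome"))
}

#' Canonical transcript and protein of a gene
#'
#' The canonical transcript is the one with the longest protein; ties are
#' broken by lexicographically smallest transcript id so the choice is
#' deterministic.
#'
#' @param gene a `gene_model`
#' @return list with elements `transcript` and `protein`
#' @export
canonical_protein <- function(gene) {
  trs <- gene$transcripts
  trs <- trs[vapply(trs, function(tr) nchar(tr$protein) > 0, NA)]
  if (length(trs) == 0) stop("gene '", gene$gene_id, "' has no translatable transcript")
  lens <- vapply(trs, function(tr) nchar(tr$protein), 0L)
  ids <- vapply(trs, function(tr) tr$transcript_id, "")
  best <- order(-lens, ids)[1]
  list(transcript = trs[[best]], protein = trs[[best]]$protein)
}

#' Intron positions in protein coordinates
#'
#' For each CDS exon junction of a multi-exon transcript, gives the 0-based
#' amino-acid offset immediately following the intron
#' (`floor(cumulative CDS bp / 3)`) and the phase (`cumulative CDS bp mod 3`).
#' These are the positions at which intron loss is diagnosed in
#' protein-to-genome alignments.
#'
#' @param transcript a transcript entry of a `gene_model` (>= 2 CDS exons)
#' @return data.frame with columns `index`, `aa_offset`, `phase`
#' @export
protein_intron_positions <- function(transcript) {
  ex <- transcript$cds_exons
  if (length(ex) < 2L) stop("transcript '", transcript$transcript_id,
                            "' is single-exon; no intron positions")
  cum <- cumsum(GenomicRanges::width(ex))
  cum <- cum[-length(cum)]
  data.frame(index = seq_along(cum),
             aa_offset = cum %/% 3L,
             phase = cum %% 3L)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set with", length(x), "genes\n")
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, sprintf("%s:%d-%d(%s)", x$seq_id, x$start, x$end, x$strand),
      "with", length(x$transcripts), "transcript(s)\n")
  invisible(x)
}

## genomic span of a gene as GRanges (used for self-locus exclusion)
gene_span <- function(g) {
  GenomicRanges::GRanges(g$seq_id, IRanges::IRanges(g$start, g$end), strand = g$strand)
}
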