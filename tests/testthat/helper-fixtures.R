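## Shared fixture builders. Everything is generated in code at test time;
## the standard implanted fixture is cached per session because several
## files consume it.

.fixture_cache <- new.env(parent = emptyenv())

standard_fixture <- function(seed = 101L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    spec <- fixture_spec(seed = seed, n_genes = 20L, n_retrocopies = 15L,
                         substitution_rate = 0.05, n_intron_retaining = 5L,
                         n_single_exon_fragments = 3L)
    .fixture_cache[[key]] <- implant_retrocopies(generate_genome(spec))
  }
  .fixture_cache[[key]]
}

## an in-memory gene model built from explicit exon lengths (in codons);
## intron lengths default to 100 bp; no genome attached
synthetic_gene <- function(gene_id, exon_aa, strand = "+", start = 1000L,
                           description = "", transcript_ids = NULL,
                           intron_len = 100L) {
  if (!is.list(exon_aa)) exon_aa <- list(exon_aa)
  if (is.null(transcript_ids))
    transcript_ids <- paste0(gene_id, ".T", seq_along(exon_aa))
  transcripts <- list()
  gene_end <- start
  for (j in seq_along(exon_aa)) {
    aa <- exon_aa[[j]]
    widths <- 3L * aa
    starts <- start + c(0L, cumsum(widths + intron_len))[seq_along(widths)]
    ends <- starts + widths - 1L
    exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends),
                                    strand = strand)
    if (strand == "-") exons <- rev(exons)
    prot <- paste(rep("A", sum(aa)), collapse = "")
    transcripts[[transcript_ids[j]]] <- list(
      transcript_id = transcript_ids[j], cds_exons = exons,
      strand = strand, protein = prot)
    gene_end <- max(gene_end, max(ends))
  }
  structure(list(gene_id = gene_id, seq_id = "chr1", strand = strand,
                 start = start, end = gene_end, biotype = "protein_coding",
                 description = description, transcripts = transcripts),
            class = "gene_model")
}

as_gene_set <- function(...) {
  genes <- list(...)
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(genes, class = "gene_set")
}

## a protein-to-genome chain built from plain numbers
toy_chain <- function(query_id = "G001.T1", query_len, blocks, matches,
                      score = matches, t_name = "chr1", t_size = 100000L,
                      strand = "+", protein_query = TRUE) {
  alignment_chain(query_id, query_len, t_name, t_size, strand,
                  blocks, matches, score, protein_query)
}

## write a toy GFF3 + FASTA pair for loader tests; exons given as
## transcribed-strand bp lengths; returns list(gff3=, fasta=, protein=)
write_toy_gene_files <- function(dir, exon_bp = c(99L, 150L, 51L),
                                 intron_bp = 80L, strand = "+") {
  total <- sum(exon_bp)
  stopifnot(total %% 3 == 0)
  n_aa <- total %/% 3
  set.seed(7)
  aa <- c("M", sample(setdiff(unique(Biostrings::GENETIC_CODE), "*"),
                      n_aa - 1, replace = TRUE))
  codons <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  cds <- paste(vapply(aa, function(a) codons[[a]][1], ""), collapse = "")
  pieces <- character(0); pos <- 0L
  lead <- paste(rep("A", 200), collapse = "")
  pieces <- c(pieces, lead); pos <- 200L
  exon_rows <- list(); off <- 0L
  body <- character(0)
  for (k in seq_along(exon_bp)) {
    e <- substring(cds, off + 1L, off + exon_bp[k]); off <- off + exon_bp[k]
    body <- c(body, e)
    if (k < length(exon_bp))
      body <- c(body, paste0("GT", paste(rep("C", intron_bp - 4L), collapse = ""), "AG"))
  }
  body <- paste(c(body, "TAA"), collapse = "")
  if (strand == "-")
    body <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
  gene_start <- pos + 1L
  pieces <- c(pieces, body); pos <- pos + nchar(body)
  gene_end <- pos
  pieces <- c(pieces, paste(rep("T", 100), collapse = ""))
  genome <- paste(pieces, collapse = "")
  ## exon coordinates
  ts_starts <- integer(0); o <- 0L
  for (k in seq_along(exon_bp)) {
    ts_starts <- c(ts_starts, o + 1L)
    o <- o + exon_bp[k] + if (k < length(exon_bp)) intron_bp else 0L
  }
  ts_ends <- ts_starts + exon_bp - 1L
  if (strand == "+") {
    starts <- gene_start + ts_starts - 1L; ends <- gene_start + ts_ends - 1L
  } else {
    starts <- gene_end - ts_ends + 1L; ends <- gene_end - ts_starts + 1L
  }
  gff <- c("##gff-version 3",
           paste("chr1", "toy", "gene", gene_start, gene_end, ".", strand, ".",
                 "ID=G001", sep = "\t"),
           paste("chr1", "toy", "mRNA", gene_start, gene_end, ".", strand, ".",
                 "ID=G001.T1;Parent=G001", sep = "\t"),
           vapply(order(starts), function(k)
             paste("chr1", "toy", "CDS", starts[k], ends[k], ".", strand, "0",
                   "Parent=G001.T1", sep = "\t"), ""))
  gff3 <- file.path(dir, "toy.gff3"); fasta <- file.path(dir, "toy.fa")
  writeLines(gff, gff3)
  writeLines(c(">chr1", genome), fasta)
  list(gff3 = gff3, fasta = fasta, protein = paste(aa, collapse = ""),
       exon_starts = starts, exon_ends = ends)
}
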