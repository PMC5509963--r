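## Seeded synthetic fixtures: toy genomes carrying multi-exon genes with
## GT..AG introns and valid ORFs, implanted processed retrocopies of known
## provenance (controllable substitution load, truncation, frameshift and
## stop-codon injection), negative controls (intron-retaining duplicates,
## single-exon fragments), truth-derived protein-to-genome chains, simulated
## reads/ESTs/peaks/TSS, and two-species genome pairs with a consistent MAF.
## Everything is deterministic under the spec seed; each generator draws
## from its own labelled RNG substream so adding one does not perturb
## another. CDS exon lengths are multiples of 3 (phase-0 junctions), which
## keeps the truth alignment blocks exact in protein coordinates.

#' Specification of a synthetic fixture
#'
#' @param seed RNG seed fixing all outputs
#' @param n_genes number of multi-exon genes
#' @param n_exons_range range of CDS exon counts per gene
#' @param exon_aa_range range of exon lengths in codons (bp = 3x)
#' @param intron_len_range intron length range, bp
#' @param n_retrocopies processed implants
#' @param substitution_rate per-bp substitution probability on implants
#' @param truncation_fraction fraction of the protein removed from the 3'
#'   end of each implant (scalar or per-implant vector)
#' @param inject_frameshifts,inject_stops counts of injected 1-bp
#'   insertions / stop-codon substitutions per implant (scalar or vector)
#' @param n_intron_retaining intron-retaining full-gene duplicates
#'   (negative controls)
#' @param n_single_exon_fragments single-exon fragment insertions
#'   (negative controls)
#' @param chrom chromosome name
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(seed = 1L, n_genes = 20L, n_exons_range = c(2L, 8L),
                         exon_aa_range = c(25L, 90L),
                         intron_len_range = c(60L, 400L),
                         n_retrocopies = 15L, substitution_rate = 0.05,
                         truncation_fraction = 0, inject_frameshifts = 0L,
                         inject_stops = 0L, n_intron_retaining = 5L,
                         n_single_exon_fragments = 3L, chrom = "chr1") {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            all(truncation_fraction >= 0), all(truncation_fraction < 1))
  structure(as.list(environment()), class = "fixture_spec")
}

aa_alphabet <- function() {
  setdiff(unique(Biostrings::GENETIC_CODE), "*")
}

codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

reverse_translate <- function(protein, codon_table) {
  paste(vapply(strsplit(protein, "")[[1]], function(a) {
    cods <- codon_table[[a]]
    cods[sample.int(length(cods), 1)]
  }, ""), collapse = "")
}

#' Generate a toy genome with multi-exon genes
#'
#' Genes have 2-8 CDS exons (phase-0 junctions), GT..AG introns and valid
#' ORFs (ATG start, no internal stop, stop codon immediately after the
#' CDS); roughly a quarter are on the minus strand. Intergenic background
#' is uniform random sequence.
#'
#' @param spec a [fixture_spec()]
#' @return a `fixture` list with elements `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (a `gene_set`), `spec`, and an
#'   empty `truth` list
#' @export
generate_genome <- function(spec) {
  ct <- codons_for()
  pieces <- character(0); pos <- 0L
  genes <- list()
  with_substream(spec$seed, "genome", {
    for (i in seq_len(spec$n_genes)) {
      spacer <- random_dna(sample(500:1500, 1))
      pieces <- c(pieces, spacer); pos <- pos + nchar(spacer)
      n_ex <- sample(seq(spec$n_exons_range[1], spec$n_exons_range[2]), 1)
      ex_aa <- sample(seq(spec$exon_aa_range[1], spec$exon_aa_range[2]),
                      n_ex, replace = TRUE)
      prot <- paste(c("M", sample(aa_alphabet(), sum(ex_aa) - 1L,
                                  replace = TRUE)), collapse = "")
      cds <- reverse_translate(prot, ct)
      strand <- if (i %% 4 == 0) "-" else "+"
      ## transcribed-strand gene body: exons interleaved with GT..AG introns,
      ## stop codon appended after the last exon
      cum <- c(0L, cumsum(ex_aa))
      ex_seq <- vapply(seq_len(n_ex), function(k)
        substring(cds, 3L * cum[k] + 1L, 3L * cum[k + 1L]), "")
      introns <- vapply(seq_len(n_ex - 1L), function(k)
        paste0("GT", random_dna(sample(
          seq(spec$intron_len_range[1], spec$intron_len_range[2]), 1) - 4L),
          "AG"), "")
      body <- paste0(paste0(ex_seq, c(introns, ""), collapse = ""), "TAA")
      piece <- if (strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
      else body
      gene_start <- pos + 1L
      pieces <- c(pieces, piece); pos <- pos + nchar(piece)
      gene_end <- pos
      ## exon coordinates: offsets within the transcribed-strand body
      ts_starts <- integer(n_ex); off <- 0L
      for (k in seq_len(n_ex)) {
        ts_starts[k] <- off + 1L
        off <- off + nchar(ex_seq[k]) + if (k < n_ex) nchar(introns[k]) else 0L
      }
      ts_ends <- ts_starts + 3L * ex_aa - 1L
      if (strand == "+") {
        starts <- gene_start + ts_starts - 1L
        ends <- gene_start + ts_ends - 1L
      } else {
        starts <- gene_end - ts_ends + 1L
        ends <- gene_end - ts_starts + 1L
      }
      gid <- sprintf("G%03d", i); tid <- paste0(gid, ".T1")
      exons <- GenomicRanges::GRanges(spec$chrom,
                                      IRanges::IRanges(starts, ends),
                                      strand = strand)
      genes[[gid]] <- structure(list(
        gene_id = gid, seq_id = spec$chrom, strand = strand,
        start = gene_start, end = gene_end, biotype = "protein_coding",
        description = sprintf("synthetic protein %d", i),
        transcripts = setNames(list(list(
          transcript_id = tid, cds_exons = exons, strand = strand,
          protein = prot)), tid)), class = "gene_model")
    }
    pieces <- c(pieces, random_dna(800))
  })
  genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                              spec$chrom))
  structure(list(genome = genome,
                 genes = structure(genes, class = "gene_set", genome = genome),
                 spec = spec, truth = list()),
            class = "fixture")
}

mutate_bases <- function(seq_chars, positions) {
  for (p in positions) {
    seq_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[p]), 1)
  }
  seq_chars
}

#' Implant retrocopies and negative controls into a fixture genome
#'
#' Processed implants are spliced CDS copies (all introns removed) of a
#' parental gene, inserted on a random strand into fresh intergenic
#' sequence appended beyond the gene array, with per-spec substitutions,
#' 3'-end truncation, 1-bp frameshift insertions at codon boundaries and
#' stop-codon substitutions. Negative controls are unspliced full-gene
#' duplicates (intron-retaining) and single-first-exon fragments. Each
#' implant yields a truth record from which the exact alignment chain,
#' expected call and expected ORF state are derived by construction.
#'
#' @param fixture a `fixture` from [generate_genome()]
#' @param thresholds a [retro_thresholds()] used to derive `expected_call`
#' @return the fixture with extended genome and populated `truth`
#' @export
implant_retrocopies <- function(fixture, thresholds = retro_thresholds()) {
  spec <- fixture$spec
  genes <- fixture$genes
  ## processed implants are drawn from parents with at least two introns;
  ## a copy of a one-intron gene can never show the two-intron loss that
  ## defines a detectable retrocopy
  gids <- names(genes)[vapply(genes, function(g)
    length(g$transcripts[[1]]$cds_exons) >= 3L, NA)]
  if (length(gids) == 0) gids <- names(genes)
  chrom_seq <- as.character(fixture$genome[[spec$chrom]])
  truth <- list()
  rec_frac <- rep_len(spec$truncation_fraction, spec$n_retrocopies)
  rec_fs <- rep_len(spec$inject_frameshifts, spec$n_retrocopies)
  rec_stop <- rep_len(spec$inject_stops, spec$n_retrocopies)

  with_substream(spec$seed, "implants", {
    for (i in seq_len(spec$n_retrocopies)) {
      gid <- gids[(i - 1L) %% length(gids) + 1L]
      tr <- genes[[gid]]$transcripts[[1]]
      P <- nchar(tr$protein)
      cds <- spliced_cds(tr, fixture$genome)
      keep_len <- max(50L, P - floor(rec_frac[i] * P))
      keep_len <- min(keep_len, P)
      codons <- substring(cds, 3L * seq_len(keep_len) - 2L, 3L * seq_len(keep_len))
      ## stop-codon injections on interior codons
      protected <- integer(0)
      n_stop <- rec_stop[i]
      if (n_stop > 0) {
        at <- sample(2:(keep_len - 1L), n_stop)
        codons[at] <- "TAA"
        protected <- at
      }
      ## substitutions on unprotected codons
      n_sub <- 0L
      if (spec$substitution_rate > 0) {
        free <- setdiff(seq_len(keep_len), protected)
        bp <- unlist(lapply(free, function(k) (3L * (k - 1L) + 1L):(3L * k)))
        hit <- bp[runif(length(bp)) < spec$substitution_rate]
        n_sub <- length(hit)
        if (n_sub > 0) {
          chars <- strsplit(paste(codons, collapse = ""), "")[[1]]
          chars <- mutate_bases(chars, hit)
          s <- paste(chars, collapse = "")
          codons <- substring(s, 3L * seq_len(keep_len) - 2L, 3L * seq_len(keep_len))
        }
      }
      ## frameshift injections: 1-bp insertions at interior codon boundaries
      n_fs <- rec_fs[i]
      fs_after <- if (n_fs > 0)
        sort(sample(5:(keep_len - 5L), n_fs)) else integer(0)
      ## assemble implant and its block structure (protein coordinates)
      seg_bounds <- c(0L, fs_after, keep_len)
      segments <- data.frame(qstart = integer(0), offset = integer(0),
                             len = integer(0))
      impl <- character(0); off <- 0L
      for (m in seq_len(length(seg_bounds) - 1L)) {
        aa <- (seg_bounds[m] + 1L):seg_bounds[m + 1L]
        seg_seq <- paste(codons[aa], collapse = "")
        segments <- rbind(segments, data.frame(
          qstart = seg_bounds[m] + 1L, offset = off + 1L, len = length(aa)))
        impl <- c(impl, seg_seq); off <- off + nchar(seg_seq)
        if (m < length(seg_bounds) - 1L) { impl <- c(impl, "C"); off <- off + 1L }
      }
      impl_seq <- paste(impl, collapse = "")
      ## truth statistics by construction
      parent_aa <- strsplit(tr$protein, "")[[1]][seq_len(keep_len)]
      impl_aa <- Biostrings::GENETIC_CODE[codons]
      matches <- sum(impl_aa == parent_aa)
      stops <- sum(impl_aa == "*")
      introns <- protein_intron_positions(tr)
      spanned <- sum(introns$aa_offset >= 1L & introns$aa_offset <= keep_len - 1L)
      identity <- matches / keep_len
      coverage <- keep_len / P
      expected_call <- 3L * keep_len >= thresholds$min_aln_bp &&
        identity >= thresholds$min_identity &&
        coverage >= thresholds$min_coverage &&
        spanned >= thresholds$min_lost_introns
      strand <- sample(c("+", "-"), 1)
      piece <- if (strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(impl_seq)))
      else impl_seq
      spacer <- random_dna(sample(300:800, 1))
      start <- nchar(chrom_seq) + nchar(spacer) + 1L
      chrom_seq <- paste0(chrom_seq, spacer, piece)
      truth[[length(truth) + 1L]] <- list(
        type = "processed", implant_id = sprintf("IMP_%03d", i),
        source_gene = gid, source_transcript = tr$transcript_id,
        chrom = spec$chrom, start = start, end = nchar(chrom_seq),
        strand = strand, protein_len = P, keep_len = keep_len,
        segments = segments, matches = matches, n_sub = n_sub,
        n_frameshift = n_fs, n_stop = as.integer(stops),
        introns_removed = spanned,
        expected_call = expected_call,
        expected_orf_conserved = n_fs == 0L && stops == 0L)
    }
    ## negative controls: intron-retaining full-gene duplicates
    for (i in seq_len(spec$n_intron_retaining)) {
      gid <- gids[(i - 1L) %% length(gids) + 1L]
      g <- genes[[gid]]
      body <- substring(as.character(fixture$genome[[spec$chrom]]),
                        g$start, g$end)
      spacer <- random_dna(sample(300:800, 1))
      start <- nchar(chrom_seq) + nchar(spacer) + 1L
      chrom_seq <- paste0(chrom_seq, spacer, body)
      truth[[length(truth) + 1L]] <- list(
        type = "intron_retaining", implant_id = sprintf("DUP_%03d", i),
        source_gene = gid, source_transcript = g$transcripts[[1]]$transcript_id,
        chrom = spec$chrom, start = start, end = nchar(chrom_seq),
        strand = g$strand, expected_call = FALSE,
        expected_orf_conserved = NA)
    }
    ## negative controls: single-exon fragments
    for (i in seq_len(spec$n_single_exon_fragments)) {
      gid <- gids[(i - 1L) %% length(gids) + 1L]
      tr <- genes[[gid]]$transcripts[[1]]
      cds <- spliced_cds(tr, fixture$genome)
      e1_aa <- GenomicRanges::width(tr$cds_exons)[1] %/% 3L
      frag <- substring(cds, 1L, 3L * e1_aa)
      spacer <- random_dna(sample(300:800, 1))
      start <- nchar(chrom_seq) + nchar(spacer) + 1L
      chrom_seq <- paste0(chrom_seq, spacer, frag)
      truth[[length(truth) + 1L]] <- list(
        type = "single_exon_fragment", implant_id = sprintf("FRG_%03d", i),
        source_gene = gid, source_transcript = tr$transcript_id,
        chrom = spec$chrom, start = start, end = nchar(chrom_seq),
        strand = "+", keep_len = e1_aa, expected_call = FALSE,
        expected_orf_conserved = NA)
    }
    chrom_seq <- paste0(chrom_seq, random_dna(500))
  })
  genome <- Biostrings::DNAStringSet(setNames(chrom_seq, spec$chrom))
  fixture$genome <- genome
  attr(fixture$genes, "genome") <- genome
  fixture$truth <- truth
  fixture
}

## spliced CDS (transcribed strand, stop excluded) of a transcript
spliced_cds <- function(tr, genome) {
  ex <- tr$cds_exons
  parts <- vapply(seq_along(ex), function(k) {
    s <- Biostrings::subseq(genome[[as.character(GenomicRanges::seqnames(ex)[k])]],
                            GenomicRanges::start(ex)[k], GenomicRanges::end(ex)[k])
    if (tr$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, "")
  paste(parts, collapse = "")
}

#' Truth summary table of a fixture
#'
#' @param fixture an implanted `fixture`
#' @return data.frame with one row per implant
#' @export
fixture_truth_table <- function(fixture) {
  do.call(rbind, lapply(fixture$truth, function(r) data.frame(
    implant_id = r$implant_id, type = r$type, source_gene = r$source_gene,
    chrom = r$chrom, start = r$start, end = r$end, strand = r$strand,
    expected_call = r$expected_call,
    expected_orf_conserved = r$expected_orf_conserved %||% NA,
    stringsAsFactors = FALSE)))
}

#' Exact protein-to-genome chains derived from the fixture truth
#'
#' Builds the alignment every implant would produce against its parental
#' protein: single-block chains for clean processed copies, split blocks at
#' injected insertions, exon-block chains (with intron-sized target gaps)
#' for intron-retaining duplicates and fragments. Each parent's perfect
#' self-alignment to its own locus is included, exercising the caller's
#' self-locus exclusion.
#'
#' @param fixture an implanted `fixture`
#' @param include_self include parental self-locus chains (default TRUE)
#' @return list of `alignment_chain`
#' @export
truth_alignments <- function(fixture, include_self = TRUE) {
  t_size <- Biostrings::width(fixture$genome)[1]
  chrom <- fixture$spec$chrom
  chains <- list()
  for (r in fixture$truth) {
    tr <- fixture$genes[[r$source_gene]]$transcripts[[r$source_transcript]]
    P <- nchar(tr$protein)
    if (r$type == "processed") {
      ## strand-local start of the implant body
      local0 <- if (r$strand == "-") t_size - r$end else r$start - 1L
      blocks <- data.frame(qstart = r$segments$qstart,
                           tstart = local0 + r$segments$offset,
                           len = r$segments$len)
      chains[[length(chains) + 1L]] <- alignment_chain(
        r$source_transcript, P, chrom, t_size, r$strand, blocks,
        matches = r$matches, score = r$matches, protein_query = TRUE)
    } else if (r$type == "intron_retaining") {
      chains[[length(chains) + 1L]] <- exon_block_chain(
        tr, P, chrom, t_size, r$start, r$end, r$strand)
    } else if (r$type == "single_exon_fragment") {
      blocks <- data.frame(qstart = 1L, tstart = r$start, len = r$keep_len)
      chains[[length(chains) + 1L]] <- alignment_chain(
        r$source_transcript, P, chrom, t_size, "+", blocks,
        matches = r$keep_len, score = r$keep_len, protein_query = TRUE)
    }
  }
  if (include_self) {
    parents <- unique(vapply(fixture$truth, `[[`, "", "source_gene"))
    for (gid in parents) {
      g <- fixture$genes[[gid]]
      tr <- g$transcripts[[1]]
      chains[[length(chains) + 1L]] <- exon_block_chain(
        tr, nchar(tr$protein), chrom, t_size, g$start, g$end, g$strand)
    }
  }
  chains
}

## perfect chain of a protein to a genomic gene copy, one block per exon
exon_block_chain <- function(tr, P, chrom, t_size, g_start, g_end, strand) {
  ex <- tr$cds_exons
  aa <- GenomicRanges::width(ex) %/% 3L
  qstarts <- c(1L, 1L + cumsum(aa)[-length(aa)])
  ## exon k's genomic coordinates inside the duplicate are shifted by the
  ## offset between the duplicate start and the source gene start; for the
  ## source gene itself the shift is zero
  src_start <- min(GenomicRanges::start(ex))
  src_end <- max(GenomicRanges::end(ex))
  if (strand == "-") {
    ## transcription order = descending forward coords; strand-local start
    ## of exon k = t_size - forward_end + 1
    fwd_end <- g_end - (max(GenomicRanges::end(ex)) - GenomicRanges::end(ex))
    tstarts <- t_size - fwd_end + 1L
  } else {
    tstarts <- g_start + (GenomicRanges::start(ex) - src_start)
  }
  alignment_chain(tr$transcript_id, P, chrom, t_size, strand,
                  data.frame(qstart = qstarts, tstart = tstarts, len = aa),
                  matches = P, score = P, protein_query = TRUE)
}

#' Write a fixture to disk
#'
#' Writes `genome.fa`, `genes.gff3`, `alignments.psl` and `truth.tsv`.
#'
#' @param fixture an implanted `fixture`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(fixture$genome, file.path(dir, "genome.fa"))
  write_gene_models(fixture$genes, file.path(dir, "genes.gff3"))
  write_psl(truth_alignments(fixture), file.path(dir, "alignments.psl"))
  write.table(fixture_truth_table(fixture), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate expression evidence over fixture implants
#'
#' Plants uniquely-mapped (NH:i:1) and multi-mapping (NH:i:5) reads on
#' chosen implants, writes them as SAM, designs ESTs with controlled
#' identity to the retrocopy versus the parental locus, and places Pol II
#' peaks / CAGE TSS at chosen offsets from implant 5' ends.
#'
#' @param fixture an implanted `fixture`
#' @param unique_reads named integer vector: implant_id -> unique reads
#' @param multi_reads named integer vector: implant_id -> multi-mapped reads
#' @param library_total total mapped reads in the simulated library
#' @param est_design data.frame with columns implant_id, est_len,
#'   retro_mismatches, parent_mismatches (NULL parent row omitted when
#'   parent_mismatches is NA)
#' @param peak_offsets,tss_offsets named integer vectors: implant_id ->
#'   offset of the feature start upstream (positive) of the implant 5' end
#' @param read_len planted read length
#' @return list with `sam_lines`, `library_total`, `est_chains` and GRanges
#'   `polII`, `tss`
#' @export
simulate_expression <- function(fixture, unique_reads = NULL,
                                multi_reads = NULL, library_total = 1e6,
                                est_design = NULL, peak_offsets = NULL,
                                tss_offsets = NULL, read_len = 50L) {
  spec <- fixture$spec
  t_size <- Biostrings::width(fixture$genome)[1]
  chrom_seq <- as.character(fixture$genome[[spec$chrom]])
  rec <- setNames(fixture$truth,
                  vapply(fixture$truth, `[[`, "", "implant_id"))
  sam <- c(paste0("@HD\tVN:1.6\tSO:coordinate"),
           paste0("@SQ\tSN:", spec$chrom, "\tLN:", t_size))
  reads <- list()
  with_substream(spec$seed, "expression", {
    add_reads <- function(ids_counts, nh) {
      for (id in names(ids_counts)) {
        r <- rec[[id]]
        n <- ids_counts[[id]]
        if (n == 0) next
        starts <- sort(sample(r$start:(r$end - read_len + 1L), n, replace = TRUE))
        for (k in seq_len(n)) {
          seq <- substring(chrom_seq, starts[k], starts[k] + read_len - 1L)
          reads[[length(reads) + 1L]] <<- list(pos = starts[k], line = paste(
            sprintf("%s_%s_%d_%d", id, if (nh == 1L) "u" else "m", k, nh),
            0, spec$chrom, starts[k], if (nh == 1L) 60 else 0,
            paste0(read_len, "M"), "*", 0, 0, seq,
            strrep("I", read_len), paste0("NH:i:", nh), sep = "\t"))
        }
      }
    }
    if (!is.null(unique_reads)) add_reads(unique_reads, 1L)
    if (!is.null(multi_reads)) add_reads(multi_reads, 5L)
    est_chains <- list()
    if (!is.null(est_design)) for (i in seq_len(nrow(est_design))) {
      d <- est_design[i, ]
      r <- rec[[d$implant_id]]
      g <- fixture$genes[[r$source_gene]]
      len <- d$est_len
      est_id <- paste0("EST_", d$implant_id)
      ## hit on the retrocopy
      est_chains[[length(est_chains) + 1L]] <- alignment_chain(
        est_id, len, spec$chrom, t_size, "+",
        data.frame(qstart = 1L, tstart = r$start, len = len),
        matches = len - d$retro_mismatches,
        score = len - 2L * d$retro_mismatches)
      ## competing hit on the parental locus
      if (!is.na(d$parent_mismatches)) {
        est_chains[[length(est_chains) + 1L]] <- alignment_chain(
          est_id, len, spec$chrom, t_size, "+",
          data.frame(qstart = 1L, tstart = g$start, len = len),
          matches = len - d$parent_mismatches,
          score = len - 2L * d$parent_mismatches)
      }
    }
    feature_granges <- function(offsets, width) {
      if (is.null(offsets)) return(NULL)
      gr <- lapply(names(offsets), function(id) {
        r <- rec[[id]]
        five <- if (r$strand == "-") r$end else r$start
        s <- if (r$strand == "-") five + offsets[[id]] - width + 1L else
          five - offsets[[id]]
        GenomicRanges::GRanges(spec$chrom, IRanges::IRanges(s, s + width - 1L))
      })
      do.call(c, gr)
    }
    polII <- feature_granges(peak_offsets, 200L)
    tss <- feature_granges(tss_offsets, 1L)
    ord <- order(vapply(reads, `[[`, 0L, "pos"))
    list(sam_lines = c(sam, vapply(reads[ord], `[[`, "", "line")),
         library_total = library_total, est_chains = est_chains,
         polII = polII, tss = tss)
  })
}

#' Generate a two-species genome pair with a consistent MAF
#'
#' Species B is a diverged copy of species A (substitutions only, so
#' coordinates are preserved). Shared implants stay alignable; implants
#' listed in `a_only` are scrambled in species B (no orthologous copy). One
#' gapless MAF block is written per processed implant, covering the implant
#' with a small flank.
#'
#' @param spec a [fixture_spec()]
#' @param divergence per-bp substitution rate between the species
#' @param a_only implant ids present only in species A
#' @param flank MAF block flank, bp
#' @return list with `fixture_a`, `genome_b`, `blocks` (wga_block list),
#'   `calls_by_species` (truth-derived call tables for both species) and
#'   `maf_lines`
#' @export
generate_species_pair <- function(spec, divergence = 0.02,
                                  a_only = character(0), flank = 100L) {
  fx <- implant_retrocopies(generate_genome(spec))
  chrom_seq <- as.character(fx$genome[[spec$chrom]])
  t_size <- nchar(chrom_seq)
  with_substream(spec$seed, "species-pair", {
    chars <- strsplit(chrom_seq, "")[[1]]
    hit <- which(runif(length(chars)) < divergence)
    chars_b <- mutate_bases(chars, hit)
    for (r in fx$truth) {
      if (r$implant_id %in% a_only && r$type == "processed") {
        ## erase the orthologous copy in B
        chars_b[r$start:r$end] <- sample(c("A", "C", "G", "T"),
                                         r$end - r$start + 1L, replace = TRUE)
      }
    }
    seq_b <- paste(chars_b, collapse = "")
    genome_b <- Biostrings::DNAStringSet(setNames(seq_b, spec$chrom))
    processed <- Filter(function(r) r$type == "processed", fx$truth)
    maf <- c("##maf version=1")
    blocks <- list()
    for (r in processed) {
      s <- max(1L, r$start - flank); e <- min(t_size, r$end + flank)
      ta <- substring(chrom_seq, s, e); tb <- substring(seq_b, s, e)
      maf <- c(maf, "a score=0",
               paste("s", paste0("spA.", spec$chrom), s - 1L, e - s + 1L, "+",
                     t_size, ta),
               paste("s", paste0("spB.", spec$chrom), s - 1L, e - s + 1L, "+",
                     t_size, tb),
               "")
      rows <- data.frame(species = c("spA", "spB"), chrom = spec$chrom,
                         start0 = s - 1L, size = e - s + 1L, strand = "+",
                         src_size = t_size, text = c(ta, tb),
                         stringsAsFactors = FALSE)
      blocks[[length(blocks) + 1L]] <- structure(
        list(block_id = length(blocks) + 1L, rows = rows), class = "wga_block")
    }
    mk_calls <- function(keep) {
      do.call(rbind, lapply(processed[keep], function(r) data.frame(
        retrocopy_id = r$implant_id, chrom = r$chrom, start = r$start,
        end = r$end, strand = r$strand, stringsAsFactors = FALSE)))
    }
    ids <- vapply(processed, `[[`, "", "implant_id")
    list(fixture_a = fx, genome_b = genome_b, blocks = blocks,
         maf_lines = maf,
         calls_by_species = list(spA = mk_calls(rep(TRUE, length(processed))),
                                 spB = mk_calls(!(ids %in% a_only))))
  })
}
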