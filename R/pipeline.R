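## End-to-end orchestration: call -> classify -> ORF -> expression ->
## orthology, driven by a single config (YAML file or list). Every numeric
## threshold and window is overridable; defaults are the published values.

#' Run the full annotation pipeline
#'
#' Executes retrocopy calling, status classification, ORF assessment,
#' expression-evidence annotation and (optionally) cross-species orthology,
#' writing the combined per-retrocopy table, a BED12 and a FASTA of
#' retrocopy sequences.
#'
#' Config entries: `gff3`, `genome_fasta`, `psl` (protein-to-genome
#' alignments; `last_tab` may be given instead), `pseudogenes_bed`
#' (optional), `clade` ("mammal"/"other"), `species_prefix`, `out_prefix`;
#' optional `thresholds` and `windows` overrides (named lists); optional
#' `expression` block (`counts_tsv`, or `bam`+`library_sizes`; `est_psl`;
#' `polii_bed`; `tss_bed`); optional `orthology` block (`maf`, `calls`
#' as species=tsv named list, `species` naming this genome in the MAF).
#'
#' @param config a named list or path to a YAML file
#' @return the annotated `retrocopy_calls` table, invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  needed <- c("gff3", "genome_fasta", "out_prefix")
  missing_keys <- setdiff(needed, names(config))
  if (length(missing_keys))
    stop("config is missing: ", paste(missing_keys, collapse = ", "))
  if (is.null(config$psl) && is.null(config$last_tab))
    stop("config needs 'psl' or 'last_tab' alignments")
  ## all inputs must exist before any work
  paths <- c(config$gff3, config$genome_fasta, config$psl, config$last_tab,
             config$pseudogenes_bed, config$expression$counts_tsv,
             config$expression$est_psl, config$expression$polii_bed,
             config$expression$tss_bed, config$orthology$maf,
             unlist(config$orthology$calls))
  absent <- paths[!file.exists(paths)]
  if (length(absent)) stop("missing input file(s): ",
                           paste(absent, collapse = ", "))

  thr <- do.call(retro_thresholds, config$thresholds %||% list())
  win <- do.call(evidence_windows, config$windows %||% list())
  clade <- config$clade %||% "other"
  prefix <- config$species_prefix %||% "RC"

  genes <- load_gene_models(config$gff3, config$genome_fasta)
  chains <- if (!is.null(config$psl)) read_psl(config$psl) else
    read_last_tab(config$last_tab, protein_query = TRUE)
  chains <- chain_colinear(chains, config$chain_gap %||% 1000L)
  message("pipeline: ", length(genes), " genes, ", length(chains),
          " alignment chains")
  pseudo <- if (!is.null(config$pseudogenes_bed))
    rtracklayer::import(config$pseudogenes_bed, format = "bed") else NULL
  calls <- call_retrocopies(chains, genes, pseudo, thr, clade, prefix)
  message("pipeline: ", nrow(calls), " retrocopies called")
  calls <- annotate_orf(calls, attr(genes, "genome"))

  ex <- config$expression
  if (!is.null(ex$counts_tsv)) {
    calls <- annotate_expression_table(calls, ex$counts_tsv)
  }
  est_chains <- if (!is.null(ex$est_psl)) read_psl(ex$est_psl) else NULL
  polii <- if (!is.null(ex$polii_bed))
    rtracklayer::import(ex$polii_bed, format = "bed") else NULL
  tss <- if (!is.null(ex$tss_bed))
    rtracklayer::import(ex$tss_bed, format = "bed") else NULL
  if (!is.null(ex$bam)) {
    calls <- annotate_expression(calls, bam_files = unlist(ex$bam),
                                 library_sizes = unlist(ex$library_sizes),
                                 est_chains = est_chains,
                                 polII_peaks = polii, tss_sites = tss,
                                 windows = win)
  } else if (!is.null(est_chains) || !is.null(polii) || !is.null(tss)) {
    keep_rpm <- calls$max_rpm %||% NULL
    keep_rna <- calls$rnaseq_expressed %||% NULL
    calls <- annotate_expression(calls, est_chains = est_chains,
                                 polII_peaks = polii, tss_sites = tss,
                                 windows = win)
    if (!is.null(keep_rpm)) {
      calls$max_rpm <- keep_rpm
      calls$rnaseq_expressed <- keep_rna
    }
  }

  write_calls(calls, config$out_prefix)
  write_call_fasta(calls, attr(genes, "genome"),
                   paste0(config$out_prefix, ".fa"))

  if (!is.null(config$orthology)) {
    ortho <- config$orthology
    blocks <- read_maf(ortho$maf)
    calls_by_species <- lapply(ortho$calls, function(p)
      read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
    calls_by_species[[ortho$species %||% "this"]] <- as.data.frame(calls)
    groups <- ortholog_groups(calls_by_species, blocks,
                              min_frac = ortho$min_frac %||% 0.50)
    write.table(groups, paste0(config$out_prefix, ".orthologs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message("pipeline: ", length(unique(groups$group_id)),
            " ortholog groups")
  }
  invisible(calls)
}

#' Write retrocopy sequences as FASTA
#'
#' Strand-corrected locus sequences, one record per call.
#'
#' @param calls a `retrocopy_calls` data.frame
#' @param genome a [Biostrings::DNAStringSet]
#' @param path output FASTA path
#' @export
write_call_fasta <- function(calls, genome, path) {
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(calls)), function(i) {
    s <- Biostrings::subseq(genome[[calls$chrom[i]]], calls$start[i],
                            calls$end[i])
    if (calls$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, ""))
  names(seqs) <- calls$retrocopy_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
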