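## Expression evidence: uniquely-mapped RNA-Seq reads (RPM), best-hit EST
## validation, RNA Pol II peak and CAGE TSS association near the retrocopy
## 5' end. Each source yields a boolean badge; sources never supplied are
## "not assessed" (NA), distinct from a negative.

#' Evidence window defaults
#'
#' Pol II peaks are searched up to 1000 bp and CAGE TSS up to 500 bp
#' upstream of the annotated retrocopy 5' end, and down to 30% of the
#' retrocopy body.
#'
#' @param polII_upstream upstream window for Pol II peaks, bp
#' @param tss_upstream upstream window for CAGE TSS, bp
#' @param body_fraction fraction of the retrocopy body included
#' @return an `evidence_windows` list
#' @export
evidence_windows <- function(polII_upstream = 1000L, tss_upstream = 500L,
                             body_fraction = 0.30) {
  stopifnot(polII_upstream > 0, tss_upstream > 0,
            body_fraction > 0, body_fraction <= 1)
  structure(list(polII_upstream = polII_upstream,
                 tss_upstream = tss_upstream,
                 body_fraction = body_fraction), class = "evidence_windows")
}

#' Count uniquely-mapped reads overlapping a locus
#'
#' Retrocopy/parent sequence similarity makes multi-mapping reads
#' uninformative, so only uniquely mapped reads count: NH tag equal to 1
#' when present, else mapping quality at least `min_mapq`. Secondary and
#' supplementary records are excluded. A read counts if its alignment
#' overlaps the locus by at least one base.
#'
#' @param bam_file coordinate-sorted, indexed BAM path
#' @param locus a length-1 GRanges
#' @param min_mapq MAPQ cut-off used when the NH tag is absent
#' @return integer read count
#' @export
count_unique_reads <- function(bam_file, locus, min_mapq = 30L) {
  if (!file.exists(paste0(bam_file, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_file)))
    stop("BAM file is not indexed: ", bam_file)
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::granges(locus),
    what = c("qname", "flag", "mapq"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam_file, param = param)[[1]]
  nh <- res$tag$NH
  mapq <- res$mapq
  if (is.null(nh)) nh <- rep(NA_integer_, length(mapq))
  unique_read <- ifelse(!is.na(nh), nh == 1L, !is.na(mapq) & mapq >= min_mapq)
  sum(unique_read)
}

#' Reads-per-million from a unique-read count
#'
#' @param unique_count uniquely-mapped reads on the feature
#' @param total_mapped_reads mapped reads in the library
#' @return RPM value; the expression badge is `rpm >= 1` (inclusive)
#' @export
compute_rpm <- function(unique_count, total_mapped_reads) {
  if (any(total_mapped_reads <= 0)) stop("library size must be positive")
  unique_count / total_mapped_reads * 1e6
}

#' Validate a retrocopy's expression with one EST
#'
#' Considers every genome-wide hit of the EST. The retrocopy-overlapping
#' hit must be at least `min_len` nt long with identity at least `min_ident`,
#' and must be strictly better — higher score *and* higher identity — than
#' the EST's alignment to any other locus, including the parental gene.
#' Ties reject.
#'
#' @param est_hits list of `alignment_chain`: all hits of one EST
#' @param retro_locus a length-1 GRanges
#' @param min_len minimum aligned length, nt
#' @param min_ident minimum identity
#' @return list with `accepted` and `reason`
#' @export
validate_est <- function(est_hits, retro_locus, min_len = 100L,
                         min_ident = 0.90) {
  if (length(est_hits) == 0)
    return(list(accepted = FALSE, reason = "no hits"))
  hit_gr <- GenomicRanges::GRanges(
    vapply(est_hits, `[[`, "", "t_name"),
    IRanges::IRanges(vapply(est_hits, function(x) x$t_start, 0L),
                     vapply(est_hits, function(x) x$t_end, 0L)))
  on_retro <- IRanges::overlapsAny(hit_gr, GenomicRanges::granges(retro_locus),
                                   ignore.strand = TRUE)
  if (!any(on_retro))
    return(list(accepted = FALSE, reason = "no hit on retrocopy"))
  st <- lapply(est_hits, compute_stats)
  ident <- vapply(st, `[[`, 0, "identity")
  len <- vapply(st, `[[`, 0L, "aln_len_bp")
  score <- vapply(est_hits, `[[`, 0, "score")
  ## best retrocopy hit by score
  ri <- which(on_retro)[order(-score[on_retro], -ident[on_retro])[1]]
  if (len[ri] < min_len)
    return(list(accepted = FALSE, reason = "alignment shorter than minimum"))
  if (ident[ri] < min_ident)
    return(list(accepted = FALSE, reason = "identity below minimum"))
  others <- which(!on_retro)
  if (length(others)) {
    if (any(score[others] >= score[ri]))
      return(list(accepted = FALSE, reason = "another locus scores as well or better"))
    if (any(ident[others] >= ident[ri]))
      return(list(accepted = FALSE, reason = "another locus matches as well or better"))
  }
  list(accepted = TRUE, reason = "best genome-wide hit")
}

#' Associate peaks or TSS features with a retrocopy promoter window
#'
#' The strand-aware window runs from `upstream_bp` upstream of the
#' retrocopy 5' end into the body for `body_fraction` of the locus length.
#' A single overlapping base associates the feature. Windows are clipped at
#' position 1 (and at the contig end if `seqlengths` are set on the
#' features).
#'
#' @param locus a length-1 GRanges with strand
#' @param features GRanges of peaks or TSS positions
#' @param upstream_bp upstream extent of the window
#' @param body_fraction fraction of the locus length included downstream of
#'   the 5' end
#' @return list with `associated` and `matches` (indices into `features`)
#' @export
associate_signal <- function(locus, features, upstream_bp, body_fraction) {
  w <- GenomicRanges::width(locus)
  body <- floor(body_fraction * w)
  if (as.character(GenomicRanges::strand(locus)) == "-") {
    win_start <- GenomicRanges::end(locus) - body + 1L
    win_end <- GenomicRanges::end(locus) + upstream_bp
  } else {
    win_start <- GenomicRanges::start(locus) - upstream_bp
    win_end <- GenomicRanges::start(locus) + body - 1L
  }
  win_start <- max(1L, win_start)
  sl <- GenomeInfoDb::seqlengths(features)
  chr <- as.character(GenomicRanges::seqnames(locus))
  if (!is.na(sl[chr] %||% NA)) win_end <- min(win_end, sl[chr])
  win <- GenomicRanges::GRanges(chr, IRanges::IRanges(win_start, win_end))
  hits <- which(IRanges::overlapsAny(features, win, ignore.strand = TRUE))
  list(associated = length(hits) > 0, matches = hits)
}

#' Merge per-source expression evidence into one bundle
#'
#' Sources not supplied (NULL) are recorded as NA ("not assessed"), the
#' grey-badge state, distinct from FALSE (negative). RNA-Seq is expressed
#' when any library reaches 1 RPM.
#'
#' @param rpm_by_library named numeric vector of per-library RPM, or NULL
#' @param est_ids accessions of accepted ESTs, or NULL if ESTs were not
#'   assessed (an empty character vector means assessed and negative)
#' @param polII logical or NULL
#' @param tss logical or NULL
#' @param rpm_threshold expression cut-off, default 1 RPM (inclusive)
#' @return an `evidence_bundle` list
#' @export
merge_evidence <- function(rpm_by_library = NULL, est_ids = NULL,
                           polII = NULL, tss = NULL, rpm_threshold = 1.0) {
  structure(list(
    rpm_by_library = rpm_by_library,
    rnaseq_expressed = if (is.null(rpm_by_library)) NA else
      any(rpm_by_library >= rpm_threshold),
    est_ids = est_ids,
    est_expressed = if (is.null(est_ids)) NA else length(est_ids) > 0,
    polII = if (is.null(polII)) NA else isTRUE(polII),
    tss = if (is.null(tss)) NA else isTRUE(tss)),
    class = "evidence_bundle")
}

#' Attach expression evidence to a calls table
#'
#' Convenience wrapper running all four evidence sources for every call.
#' Any source may be omitted (NULL) and is then reported NA.
#'
#' @param calls a `retrocopy_calls` data.frame
#' @param bam_files named character vector of library BAM paths, or NULL
#' @param library_sizes total mapped reads per library (same names)
#' @param est_chains list of `alignment_chain` EST hits (all loci), or NULL
#' @param polII_peaks,tss_sites GRanges or NULL
#' @param windows an [evidence_windows()] list
#' @param min_mapq MAPQ cut-off for uniqueness without NH tags
#' @return calls with columns `max_rpm`, `rnaseq_expressed`,
#'   `est_expressed`, `polII`, `tss` added
#' @export
annotate_expression <- function(calls, bam_files = NULL, library_sizes = NULL,
                                est_chains = NULL, polII_peaks = NULL,
                                tss_sites = NULL,
                                windows = evidence_windows(),
                                min_mapq = 30L) {
  n <- nrow(calls)
  loci <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$start, calls$end),
                                 strand = calls$strand)
  max_rpm <- rep(NA_real_, n); rnaseq <- rep(NA, n)
  est <- rep(NA, n); pol <- rep(NA, n); tss <- rep(NA, n)

  if (!is.null(bam_files)) {
    stopifnot(!is.null(library_sizes),
              all(names(bam_files) %in% names(library_sizes)))
    for (i in seq_len(n)) {
      rpms <- vapply(names(bam_files), function(lib)
        compute_rpm(count_unique_reads(bam_files[[lib]], loci[i], min_mapq),
                    library_sizes[[lib]]), 0)
      max_rpm[i] <- max(rpms)
      rnaseq[i] <- any(rpms >= 1.0)
    }
  }
  if (!is.null(est_chains)) {
    by_est <- split(est_chains,
                    vapply(est_chains, `[[`, "", "query_id"))
    for (i in seq_len(n)) {
      acc <- vapply(by_est, function(hits)
        validate_est(hits, loci[i])$accepted, NA)
      est[i] <- any(acc)
    }
  }
  if (!is.null(polII_peaks))
    for (i in seq_len(n))
      pol[i] <- associate_signal(loci[i], polII_peaks,
                                 windows$polII_upstream,
                                 windows$body_fraction)$associated
  if (!is.null(tss_sites))
    for (i in seq_len(n))
      tss[i] <- associate_signal(loci[i], tss_sites,
                                 windows$tss_upstream,
                                 windows$body_fraction)$associated
  calls$max_rpm <- max_rpm
  calls$rnaseq_expressed <- rnaseq
  calls$est_expressed <- est
  calls$polII <- pol
  calls$tss <- tss
  calls
}

#' Unique-read counts from a precomputed count table
#'
#' Alternative to BAM input: a TSV with columns retrocopy_id, library,
#' unique_count, library_total.
#'
#' @param calls a `retrocopy_calls` data.frame
#' @param counts_file TSV path
#' @return calls with `max_rpm` and `rnaseq_expressed` columns
#' @export
annotate_expression_table <- function(calls, counts_file) {
  tab <- read.table(counts_file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("retrocopy_id", "library", "unique_count",
                  "library_total") %in% names(tab)))
  tab$rpm <- compute_rpm(tab$unique_count, tab$library_total)
  agg <- tapply(tab$rpm, tab$retrocopy_id, max)
  calls$max_rpm <- as.numeric(agg[calls$retrocopy_id])
  calls$rnaseq_expressed <- !is.na(calls$max_rpm) & calls$max_rpm >= 1.0
  calls
}
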