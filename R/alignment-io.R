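## Alignment chains: gapped query-to-target alignments with per-block
## coordinates. Block coordinates are stored in the alignment's native
## orientation ("strand-local" target coordinates when the target strand is
## "-", as in PSL translated alignments), so blocks always increase in both
## query and target units; the forward-strand target interval is kept
## alongside. Query units are amino acids for protein queries (one unit = 3
## target bp) and nucleotides otherwise.

#' Construct an alignment chain
#'
#' @param query_id query sequence name
#' @param query_len full query length in query units (aa or nt)
#' @param t_name target sequence name
#' @param t_size target sequence length (bp, or aa for protein targets)
#' @param strand target strand, "+" or "-"
#' @param blocks data.frame with columns `qstart`, `tstart` (1-based starts,
#'   strand-local target coordinates) and `len` (query units)
#' @param matches identical aligned positions, in query units
#' @param score alignment score
#' @param protein_query TRUE if the query is a protein aligned to DNA
#' @return an `alignment_chain` object
#' @export
alignment_chain <- function(query_id, query_len, t_name, t_size, strand,
                            blocks, matches, score = matches,
                            protein_query = FALSE) {
  stopifnot(is.data.frame(blocks), nrow(blocks) >= 1,
            all(c("qstart", "tstart", "len") %in% names(blocks)))
  blocks <- blocks[order(blocks$qstart), c("qstart", "tstart", "len")]
  blocks[] <- lapply(blocks, as.integer)
  rownames(blocks) <- NULL
  if (any(diff(blocks$qstart) <= 0) || any(diff(blocks$tstart) <= 0))
    stop("blocks must be strictly increasing in query and target")
  u <- if (protein_query) 3L else 1L
  local_end <- blocks$tstart[nrow(blocks)] + u * blocks$len[nrow(blocks)] - 1L
  local_start <- blocks$tstart[1]
  ## protein chains keep target coordinates strand-local (PSL translated
  ## convention); nucleotide chains keep the target forward and the query
  ## strand-local, so the forward target span is the local span
  if (protein_query && strand == "-") {
    t_start <- t_size - local_end + 1L
    t_end <- t_size - local_start + 1L
  } else {
    t_start <- local_start
    t_end <- local_end
  }
  structure(list(query_id = query_id, query_len = as.integer(query_len),
                 t_name = t_name, t_size = as.integer(t_size),
                 strand = strand, t_start = as.integer(t_start),
                 t_end = as.integer(t_end), blocks = blocks,
                 matches = as.numeric(matches), score = as.numeric(score),
                 protein_query = isTRUE(protein_query)),
            class = "alignment_chain")
}

#' @export
print.alignment_chain <- function(x, ...) {
  cat(sprintf("alignment_chain %s (%d %s) -> %s:%d-%d(%s), %d block(s), matches=%g score=%g\n",
              x$query_id, x$query_len, if (x$protein_query) "aa" else "nt",
              x$t_name, x$t_start, x$t_end, x$strand, nrow(x$blocks),
              x$matches, x$score))
  invisible(x)
}

chain_target_granges <- function(chain) {
  GenomicRanges::GRanges(chain$t_name,
                         IRanges::IRanges(chain$t_start, chain$t_end),
                         strand = chain$strand)
}

#' Read PSL alignments
#'
#' Parses 21-column PSL (BLAT interchange format), with or without the
#' 5-line header. A two-character strand field marks a translated/protein
#' alignment: block sizes are amino acids and target starts count on the
#' target strand given by the second character. Single-character strands
#' are nucleotide queries with PSL's native semantics (query starts counted
#' on the query strand, target starts always forward); the chain's
#' `t_start`/`t_end` are always on the forward strand.
#'
#' @param path PSL file path
#' @return list of [alignment_chain()] objects
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ## skip optional header (psLayout banner up to the dashed line)
  dash <- grep("^-{10,}", lines)
  if (length(dash)) lines <- lines[-seq_len(dash[1])]
  lines <- lines[!grepl("^(psLayout|match|\\s*$)", lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21)
      stop("PSL parse error at line ", i, ": expected 21 columns, got ", length(f))
    strand_field <- f[9]
    protein_query <- nchar(strand_field) == 2L
    t_strand <- substring(strand_field, nchar(strand_field))
    q_strand <- substring(strand_field, 1, 1)
    q_size <- as.integer(f[11]); t_size <- as.integer(f[15])
    n_blk <- as.integer(f[18])
    sizes <- as.integer(strsplit(f[19], ",")[[1]])
    qs <- as.integer(strsplit(f[20], ",")[[1]])
    ts <- as.integer(strsplit(f[21], ",")[[1]])
    stopifnot(length(sizes) == n_blk, length(qs) == n_blk, length(ts) == n_blk)
    blocks <- data.frame(qstart = qs + 1L, tstart = ts + 1L, len = sizes)
    out[[i]] <- alignment_chain(
      query_id = f[10], query_len = q_size, t_name = f[14], t_size = t_size,
      strand = if (protein_query) t_strand else q_strand,
      blocks = blocks, matches = as.numeric(f[1]),
      score = as.numeric(f[1]) - as.numeric(f[2]),
      protein_query = protein_query)
  }
  out
}

#' Write alignment chains as PSL
#'
#' Inverse of [read_psl()]; `read_psl(write_psl(x))` reproduces the chains.
#'
#' @param chains list of `alignment_chain`
#' @param path output path
#' @export
write_psl <- function(chains, path) {
  rows <- vapply(chains, function(ch) {
    u <- if (ch$protein_query) 3L else 1L
    b <- ch$blocks
    aligned <- sum(b$len)
    mis <- max(0, round(aligned - ch$matches))
    qs0 <- b$qstart - 1L
    strand_field <- if (ch$protein_query) paste0("+", ch$strand) else ch$strand
    ## qStart/qEnd are forward-query even when block starts are strand-local
    if (!ch$protein_query && ch$strand == "-") {
      q_start <- ch$query_len - (max(b$qstart + b$len) - 1L)
      q_end <- ch$query_len - (min(b$qstart) - 1L)
    } else {
      q_start <- min(b$qstart) - 1L
      q_end <- max(b$qstart + b$len) - 1L
    }
    paste(c(ch$matches, mis, 0, 0, 0, 0,
            max(0L, nrow(b) - 1L), sum(pmax(0L, diff(b$tstart) - u * head(b$len, -1))),
            strand_field, ch$query_id, ch$query_len, q_start, q_end,
            ch$t_name, ch$t_size, ch$t_start - 1L, ch$t_end,
            nrow(b), paste0(paste(b$len, collapse = ","), ","),
            paste0(paste(qs0, collapse = ","), ","),
            paste0(paste(b$tstart - 1L, collapse = ","), ",")),
          collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Read LAST tabular alignments
#'
#' Parses `lastal -f TAB` output: score, target (seq1) and query (seq2)
#' coordinate fields, and a block string of gapless sizes and `t:q` gap
#' pairs. Coordinates on a "-" strand count from the reverse-complement
#' start, matching the chain's strand-local convention. Plain TAB carries no
#' mismatch count; an optional trailing `matches=N` field is honored, else
#' matches defaults to the aligned length.
#'
#' @param path file of TAB lines (comment lines starting `#` ignored)
#' @param protein_query TRUE when seq2 is a protein aligned against DNA
#' @return list of [alignment_chain()]
#' @export
read_last_tab <- function(path, protein_query = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  u <- if (protein_query) 3L else 1L
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("LAST TAB parse error at line ", i, ": fewer than 12 fields")
    score <- as.numeric(f[1])
    t_name <- f[2]; t_start0 <- as.integer(f[3]); t_size <- as.integer(f[6])
    q_name <- f[7]; q_start0 <- as.integer(f[8]); q_size <- as.integer(f[11])
    t_strand <- f[5]
    toks <- strsplit(f[12], ",", fixed = TRUE)[[1]]
    qpos <- q_start0 + 1L; tpos <- t_start0 + 1L
    qs <- integer(0); ts <- integer(0); lens <- integer(0)
    for (tok in toks) {
      if (grepl(":", tok, fixed = TRUE)) {
        gp <- suppressWarnings(as.integer(strsplit(tok, ":", fixed = TRUE)[[1]]))
        if (length(gp) != 2 || any(is.na(gp)))
          stop("LAST TAB parse error at line ", i, ": bad gap token '", tok, "'")
        tpos <- tpos + gp[1]
        qpos <- qpos + gp[2]
      } else {
        n <- suppressWarnings(as.integer(tok))
        if (is.na(n)) stop("LAST TAB parse error at line ", i, ": bad block token '", tok, "'")
        qs <- c(qs, qpos); ts <- c(ts, tpos); lens <- c(lens, n)
        qpos <- qpos + n
        tpos <- tpos + u * n
      }
    }
    matches <- sum(lens)
    mt <- grep("^matches=", f, value = TRUE)
    if (length(mt)) matches <- as.numeric(sub("^matches=", "", mt[1]))
    alignment_chain(q_name, q_size, t_name, t_size, t_strand,
                    data.frame(qstart = qs, tstart = ts, len = lens),
                    matches = matches, score = score,
                    protein_query = protein_query)
  })
}

#' Alignment statistics used by all filters
#'
#' @param chain an `alignment_chain`
#' @return list with `aln_len_bp` (aligned length on the target in bp),
#'   `identity` (matches over aligned query positions) and `coverage`
#'   (aligned query positions over full query length)
#' @export
compute_stats <- function(chain) {
  aligned <- sum(chain$blocks$len)
  if (aligned == 0) stop("zero aligned length")
  u <- if (chain$protein_query) 3L else 1L
  list(aln_len_bp = as.integer(aligned * u),
       identity = chain$matches / aligned,
       coverage = aligned / chain$query_len)
}

#' Chain co-linear local alignments
#'
#' Hard-masked genomes fragment a single retrocopy into several local hits.
#' Hits of the same query to the same target strand are merged into one
#' chain when they are co-linear (query and target order both preserved,
#' no overlap) and the genomic gap between them is at most `max_gap` bp.
#' Matches and scores are summed.
#'
#' @param chains list of `alignment_chain`
#' @param max_gap maximum genomic gap in bp between merged hits
#' @return list of `alignment_chain` (merged where applicable)
#' @export
chain_colinear <- function(chains, max_gap = 1000L) {
  if (length(chains) <= 1) return(chains)
  key <- vapply(chains, function(ch)
    paste(ch$query_id, ch$t_name, ch$strand, ch$protein_query, sep = "\r"), "")
  out <- list()
  for (k in unique(key)) {
    grp <- chains[key == k]
    ord <- order(vapply(grp, function(ch) ch$blocks$tstart[1], 0))
    grp <- grp[ord]
    cur <- grp[[1]]
    u <- if (cur$protein_query) 3L else 1L
    if (length(grp) > 1) for (ch in grp[-1]) {
      cur_q_end <- max(cur$blocks$qstart + cur$blocks$len) - 1L
      cur_t_end <- max(cur$blocks$tstart + u * cur$blocks$len) - 1L
      gap <- ch$blocks$tstart[1] - cur_t_end - 1L
      if (ch$blocks$qstart[1] > cur_q_end && gap >= 0 && gap <= max_gap) {
        cur <- alignment_chain(cur$query_id, cur$query_len, cur$t_name,
                               cur$t_size, cur$strand,
                               rbind(cur$blocks, ch$blocks),
                               matches = cur$matches + ch$matches,
                               score = cur$score + ch$score,
                               protein_query = cur$protein_query)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- ch
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  out
}
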