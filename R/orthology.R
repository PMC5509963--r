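## Cross-species ortholog groups: retrocopies from two or more species are
## linked when they overlap reciprocally (>= 50% both ways) within
## whole-genome-alignment blocks, measured in alignment-column space
## (gap-aware); connected components of the link graph are the groups.

#' Read whole-genome-alignment blocks from MAF
#'
#' Parses `a`/`s` paragraph records. Sequence sources are expected as
#' `species.chrom`; start coordinates are 0-based on the given strand, per
#' the MAF convention.
#'
#' @param path MAF file path
#' @return list of `wga_block` objects, each with a `rows` data.frame
#'   (species, chrom, start0, size, strand, src_size, text)
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list(); rows <- NULL
  flush <- function() {
    if (!is.null(rows) && nrow(rows) > 0) {
      stopifnot(length(unique(nchar(rows$text))) == 1)
      blocks[[length(blocks) + 1L]] <<- structure(
        list(block_id = length(blocks) + 1L, rows = rows), class = "wga_block")
    }
    rows <<- NULL
  }
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) { flush(); rows <- data.frame() }
    else if (grepl("^s ", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7) stop("malformed MAF s-line: ", ln)
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substring(src, 1, dot - 1) else src
      chrom <- if (dot > 0) substring(src, dot + 1) else src
      rows <- rbind(rows, data.frame(
        species = species, chrom = chrom, start0 = as.integer(f[3]),
        size = as.integer(f[4]), strand = f[5], src_size = as.integer(f[6]),
        text = f[7], stringsAsFactors = FALSE))
    } else if (!grepl("^#", ln) && !nzchar(trimws(ln))) flush()
  }
  flush()
  blocks
}

## forward-strand genomic interval of a MAF row
maf_row_interval <- function(row) {
  if (row$strand == "-") {
    c(row$src_size - row$start0 - row$size + 1L, row$src_size - row$start0)
  } else c(row$start0 + 1L, row$start0 + row$size)
}

#' Project a retrocopy locus to alignment columns of a block
#'
#' Maps the genomic bases of the retrocopy that fall inside the block's
#' segment for one species to alignment-column indices, skipping columns
#' where that species' row has a gap.
#'
#' @param retro_locus a length-1 GRanges
#' @param block a `wga_block`
#' @param species species name as used in the MAF sources
#' @return integer vector of column indices (possibly empty)
#' @export
project_to_columns <- function(retro_locus, block, species) {
  chr <- as.character(GenomicRanges::seqnames(retro_locus))
  ri <- which(block$rows$species == species & block$rows$chrom == chr)
  if (length(ri) == 0) return(integer(0))
  row <- block$rows[ri[1], ]
  chars <- strsplit(row$text, "")[[1]]
  non_gap <- chars != "-"
  local <- cumsum(non_gap) + row$start0        # 1-based strand-local position
  gpos <- if (row$strand == "-") row$src_size - local + 1L else local
  lo <- GenomicRanges::start(retro_locus); hi <- GenomicRanges::end(retro_locus)
  which(non_gap & gpos >= lo & gpos <= hi)
}

#' Reciprocal overlap of two column sets
#'
#' @param cols_a,cols_b integer vectors of (globally identified) alignment
#'   columns; must be non-empty
#' @param min_frac edge threshold, default 0.50 (inclusive)
#' @return list with `frac_a`, `frac_b` and `edge`
#' @export
reciprocal_overlap <- function(cols_a, cols_b, min_frac = 0.50) {
  if (length(cols_a) == 0 || length(cols_b) == 0)
    stop("empty column set")
  inter <- length(intersect(cols_a, cols_b))
  frac_a <- inter / length(unique(cols_a))
  frac_b <- inter / length(unique(cols_b))
  list(frac_a = frac_a, frac_b = frac_b,
       edge = min(frac_a, frac_b) >= min_frac)
}

#' Connected components of the ortholog-link graph
#'
#' Groups are single-linkage connected components; singletons are dropped.
#' Group ids are assigned deterministically by the lexicographically
#' smallest member id.
#'
#' @param edges data.frame with character columns `a` and `b` (member ids
#'   of linked retrocopies, e.g. "species:retrocopy_id")
#' @return data.frame with columns `group_id`, `member`
#' @export
build_groups <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0)
    return(data.frame(group_id = character(0), member = character(0),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[vapply(members, length, 0L) >= 2]
  members <- lapply(members, sort)
  ord <- order(vapply(members, `[[`, "", 1))
  members <- members[ord]
  do.call(rbind, lapply(seq_along(members), function(i)
    data.frame(group_id = sprintf("OG_%04d", i), member = members[[i]],
               stringsAsFactors = FALSE)))
}

#' Build cross-species ortholog groups of retrocopies
#'
#' For every species, each retrocopy is projected into the blocks it
#' overlaps; its columns accumulate across blocks (columns are globally
#' identified by block). Retrocopies of different species are linked when
#' their column sets overlap reciprocally by at least `min_frac`, and
#' groups are the connected components.
#'
#' @param calls_by_species named list (species -> `retrocopy_calls`)
#' @param blocks list of `wga_block` from [read_maf()]
#' @param min_frac reciprocal-overlap threshold
#' @param space "column" measures overlap in alignment columns (gap-aware);
#'   "bp" uses each retrocopy's full genomic length as its denominator
#' @return data.frame with columns `group_id`, `species`, `retrocopy_id`
#' @export
ortholog_groups <- function(calls_by_species, blocks, min_frac = 0.50,
                            space = c("column", "bp")) {
  space <- match.arg(space)
  cols <- list()   # member id -> global column ids
  denom <- list()  # member id -> denominator (bp mode)
  for (sp in names(calls_by_species)) {
    calls <- calls_by_species[[sp]]
    for (i in seq_len(nrow(calls))) {
      locus <- GenomicRanges::GRanges(calls$chrom[i],
                                      IRanges::IRanges(calls$start[i],
                                                       calls$end[i]))
      id <- paste0(sp, ":", calls$retrocopy_id[i])
      acc <- integer(0)
      for (b in seq_along(blocks)) {
        pc <- project_to_columns(locus, blocks[[b]], sp)
        if (length(pc))
          acc <- c(acc, b * 10000000L + pc)
      }
      if (length(acc)) {
        cols[[id]] <- acc
        denom[[id]] <- calls$end[i] - calls$start[i] + 1L
      }
    }
  }
  ids <- names(cols)
  sp_of <- sub(":.*$", "", ids)
  edges <- list()
  if (length(ids) > 1) for (i in seq_len(length(ids) - 1))
    for (j in seq(i + 1, length(ids))) {
      if (sp_of[i] == sp_of[j]) next
      inter <- length(intersect(cols[[ids[i]]], cols[[ids[j]]]))
      if (inter == 0) next
      da <- if (space == "bp") denom[[ids[i]]] else length(cols[[ids[i]]])
      db <- if (space == "bp") denom[[ids[j]]] else length(cols[[ids[j]]])
      if (min(inter / da, inter / db) >= min_frac)
        edges[[length(edges) + 1L]] <- data.frame(a = ids[i], b = ids[j],
                                                  stringsAsFactors = FALSE)
    }
  groups <- build_groups(if (length(edges)) do.call(rbind, edges) else NULL)
  if (nrow(groups) == 0)
    return(data.frame(group_id = character(0), species = character(0),
                      retrocopy_id = character(0), stringsAsFactors = FALSE))
  data.frame(group_id = groups$group_id,
             species = sub(":.*$", "", groups$member),
             retrocopy_id = sub("^[^:]*:", "", groups$member),
             stringsAsFactors = FALSE)
}
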