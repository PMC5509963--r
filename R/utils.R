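#' @importFrom methods is as
#' @importFrom stats setNames runif
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a genomic interval as a GRanges
#'
#' Thin constructor used throughout the package. Coordinates are 1-based
#' closed (the Bioconductor convention); BED/PSL input is converted on read.
#'
#' @param seq_id sequence (chromosome/contig) name
#' @param start 1-based inclusive start
#' @param end 1-based inclusive end
#' @param strand "+" or "-"
#' @return a length-1 [GenomicRanges::GRanges]
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  stopifnot(start >= 1, end >= start)
  GenomicRanges::GRanges(seq_id, IRanges::IRanges(start, end), strand = strand)
}

## deterministic RNG substream: hash a label into an integer seed offset so
## adding one generator never perturbs the draws of another
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 99991L)) %% .Machine$integer.max
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
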