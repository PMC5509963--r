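test_that("a single-block PSL line parses to one chain", {
  dir <- withr::local_tempdir()
  psl <- file.path(dir, "one.psl")
  writeLines(paste(c(150, 0, 0, 0, 0, 0, 0, 0, "+", "est1", 200, 0, 150,
                     "chr1", 10000, 500, 650, 1, "150,", "0,", "500,"),
                   collapse = "\t"), psl)
  chains <- read_psl(psl)
  expect_length(chains, 1)
  ch <- chains[[1]]
  expect_equal(nrow(ch$blocks), 1)
  expect_equal(ch$matches, 150)
  expect_equal(ch$t_start, 501)
  expect_equal(ch$t_end, 650)
  expect_false(ch$protein_query)
})

test_that("empty PSL file yields an empty list", {
  dir <- withr::local_tempdir()
  psl <- file.path(dir, "empty.psl")
  writeLines(character(0), psl)
  expect_length(read_psl(psl), 0)
})

test_that("wrong column count is a parse error with the line number", {
  dir <- withr::local_tempdir()
  psl <- file.path(dir, "bad.psl")
  writeLines("only\tfour\tcolumns\there", psl)
  expect_error(read_psl(psl), "line 1.*21 columns|21 columns.*line 1")
})

test_that("PSL round-trips for plus/minus protein and nucleotide chains", {
  chains <- list(
    toy_chain("p1", 100L, data.frame(qstart = 1L, tstart = 501L, len = 80L),
              matches = 75, strand = "+"),
    toy_chain("p2", 120L, data.frame(qstart = c(1L, 61L),
                                     tstart = c(301L, 1002L),
                                     len = c(60L, 50L)),
              matches = 100, strand = "-"),
    toy_chain("e1", 300L, data.frame(qstart = c(1L, 120L),
                                     tstart = c(2001L, 2500L),
                                     len = c(100L, 150L)),
              matches = 230, strand = "-", protein_query = FALSE),
    toy_chain("e2", 150L, data.frame(qstart = 1L, tstart = 9000L, len = 150L),
              matches = 150, strand = "+", protein_query = FALSE))
  dir <- withr::local_tempdir()
  psl <- file.path(dir, "rt.psl")
  write_psl(chains, psl)
  back <- read_psl(psl)
  expect_length(back, length(chains))
  for (i in seq_along(chains)) {
    expect_identical(back[[i]]$blocks, chains[[i]]$blocks)
    expect_equal(back[[i]]$t_start, chains[[i]]$t_start)
    expect_equal(back[[i]]$t_end, chains[[i]]$t_end)
    expect_equal(back[[i]]$matches, chains[[i]]$matches)
    expect_identical(back[[i]]$strand, chains[[i]]$strand)
    expect_identical(back[[i]]$protein_query, chains[[i]]$protein_query)
  }
})

test_that("LAST TAB and PSL encodings of one alignment yield equal chains", {
  ## protein query, two blocks separated by a 500 bp target gap
  chain <- toy_chain("G001.T1", 100L,
                     data.frame(qstart = c(1L, 41L), tstart = c(1001L, 1621L),
                                len = c(40L, 60L)),
                     matches = 95, score = 95, t_size = 50000L)
  dir <- withr::local_tempdir()
  psl <- file.path(dir, "x.psl"); write_psl(list(chain), psl)
  from_psl <- read_psl(psl)[[1]]
  tab <- file.path(dir, "x.tab")
  ## seq1 = target, seq2 = query; gap token t:q; trailing matches= field
  writeLines(paste(c(95, "chr1", 1000, 800, "+", 50000,
                     "G001.T1", 0, 100, "+", 100,
                     "40,500:0,60", "matches=95"), collapse = "\t"), tab)
  from_tab <- read_last_tab(tab, protein_query = TRUE)[[1]]
  expect_identical(from_tab$blocks, from_psl$blocks)
  expect_equal(from_tab$matches, from_psl$matches)
  expect_equal(from_tab$t_start, from_psl$t_start)
  expect_identical(from_tab$strand, from_psl$strand)
})

test_that("malformed LAST block strings are parse errors", {
  dir <- withr::local_tempdir()
  tab <- file.path(dir, "bad.tab")
  writeLines(paste(c(95, "chr1", 1000, 800, "+", 50000,
                     "q", 0, 100, "+", 100, "40,xx,60"), collapse = "\t"), tab)
  expect_error(read_last_tab(tab), "bad block token")
})

test_that("alignment statistics follow the stated arithmetic", {
  ch <- toy_chain("p", 100L, data.frame(qstart = 1L, tstart = 1L, len = 50L),
                  matches = 40)
  st <- compute_stats(ch)
  expect_equal(st$aln_len_bp, 150)
  expect_equal(st$identity, 0.80)
  expect_equal(st$coverage, 0.50)
  perfect <- toy_chain("p", 60L, data.frame(qstart = 1L, tstart = 1L, len = 60L),
                       matches = 60)
  st2 <- compute_stats(perfect)
  expect_equal(st2$identity, 1.0)
  expect_equal(st2$coverage, 1.0)
  expect_equal(st2$aln_len_bp, 180)
})

test_that("fixture identities match a per-column recount of the alignment", {
  fx <- standard_fixture()
  chains <- truth_alignments(fx, include_self = FALSE)
  chrom <- as.character(fx$genome[[1]])
  t_size <- nchar(chrom)
  for (ch in chains[1:8]) {
    tr_gene <- NULL
    for (g in fx$genes) if (ch$query_id %in% names(g$transcripts)) tr_gene <- g
    prot <- strsplit(tr_gene$transcripts[[ch$query_id]]$protein, "")[[1]]
    local_seq <- if (ch$strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
    else chrom
    n_match <- 0L; n_cols <- 0L
    for (b in seq_len(nrow(ch$blocks))) {
      for (k in seq_len(ch$blocks$len[b])) {
        codon <- substring(local_seq,
                           ch$blocks$tstart[b] + 3 * (k - 1),
                           ch$blocks$tstart[b] + 3 * k - 1)
        aa <- Biostrings::GENETIC_CODE[[codon]]
        n_cols <- n_cols + 1L
        if (identical(aa, prot[ch$blocks$qstart[b] + k - 1])) n_match <- n_match + 1L
      }
    }
    st <- compute_stats(ch)
    expect_equal(st$identity, n_match / n_cols, tolerance = 1e-12)
  }
})

test_that("co-linear fragments merge only within the gap limit in order", {
  frag <- function(q, t, len, id = "p1") {
    toy_chain(id, 200L, data.frame(qstart = q, tstart = t, len = len),
              matches = len)
  }
  ## gap 900 bp between target ends: merged
  merged <- chain_colinear(list(frag(1L, 1001L, 50L), frag(51L, 2051L, 50L)),
                           max_gap = 1000L)
  expect_length(merged, 1)
  expect_equal(nrow(merged[[1]]$blocks), 2)
  expect_equal(merged[[1]]$matches, 100)
  ## gap beyond the limit: kept separate
  apart <- chain_colinear(list(frag(1L, 1001L, 50L), frag(51L, 3000L, 50L)),
                          max_gap = 1000L)
  expect_length(apart, 2)
  ## query order violated: kept separate
  disord <- chain_colinear(list(frag(51L, 1001L, 50L), frag(1L, 2051L, 50L)),
                           max_gap = 1000L)
  expect_length(disord, 2)
  ## different queries never merge
  two <- chain_colinear(list(frag(1L, 1001L, 50L), frag(51L, 2051L, 50L, "p2")))
  expect_length(two, 2)
})
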