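## a 3-exon parent: 100 aa, introns after aa 33 and aa 66
parent_introns <- data.frame(index = 1:2, aa_offset = c(33L, 66L),
                             phase = c(0L, 0L))

test_that("intron loss distinguishes contiguous, gapped and unspanned junctions", {
  thr <- retro_thresholds()
  ## contiguous single block across both introns: both lost
  ch <- toy_chain("p", 100L, data.frame(qstart = 1L, tstart = 1001L, len = 100L),
                  matches = 100)
  loss <- detect_intron_loss(ch, parent_introns, thr)
  expect_equal(loss$spanned, 1:2)
  expect_equal(loss$lost, 1:2)
  expect_length(loss$retained, 0)
  ## 500 bp target gap exactly at intron 1, contiguous at intron 2
  ch2 <- toy_chain("p", 100L,
                   data.frame(qstart = c(1L, 34L), tstart = c(1001L, 1600L),
                              len = c(33L, 67L)), matches = 100)
  loss2 <- detect_intron_loss(ch2, parent_introns, thr)
  expect_equal(loss2$spanned, 1:2)
  expect_equal(loss2$lost, 2L)
  expect_equal(loss2$retained, 1L)
  ## chain covering only exon 1: no junction strictly inside
  ch3 <- toy_chain("p", 100L, data.frame(qstart = 1L, tstart = 1001L, len = 33L),
                   matches = 33)
  loss3 <- detect_intron_loss(ch3, parent_introns, thr)
  expect_length(loss3$spanned, 0)
  ## empty intron list is an error
  expect_error(detect_intron_loss(ch, parent_introns[0, ], thr), "multi-exon")
})

test_that("the retained-intron gap cut-off is applied at the stated boundary", {
  thr <- retro_thresholds(retained_intron_min_gap = 30L)
  gap_chain <- function(gap) {
    toy_chain("p", 100L,
              data.frame(qstart = c(1L, 34L),
                         tstart = c(1001L, 1001L + 99L + gap),
                         len = c(33L, 67L)), matches = 100)
  }
  expect_equal(detect_intron_loss(gap_chain(29L), parent_introns, thr)$lost,
               c(1L, 2L))   # 29 bp gap: too short to be an intron -> lost
  expect_equal(detect_intron_loss(gap_chain(30L), parent_introns, thr)$lost,
               2L)          # 30 bp gap: retained
})

test_that("parental assignment follows score, identity, coverage, then id", {
  mk <- function(len, matches, score, qlen = 100L) {
    toy_chain("p", qlen, data.frame(qstart = 1L, tstart = 1001L, len = len),
              matches = matches, score = score)
  }
  expect_equal(assign_parental(list(mk(80L, 70, 200), mk(80L, 75, 180)),
                               c("GA", "GB")), 1L)
  expect_equal(assign_parental(list(mk(80L, 72, 200), mk(80L, 64, 200)),
                               c("GA", "GB")), 1L)  # identity 0.9 vs 0.8
  expect_equal(assign_parental(list(mk(60L, 54, 200), mk(80L, 72, 200)),
                               c("GA", "GB")), 2L)  # coverage tie-break
  ## fully equal: smaller gene id, independent of order
  expect_equal(assign_parental(list(mk(80L, 72, 200), mk(80L, 72, 200)),
                               c("GB", "GA")), 2L)
  expect_equal(assign_parental(list(mk(80L, 72, 200), mk(80L, 72, 200)),
                               c("GA", "GB")), 1L)
})

test_that("status classification is retrocopy-relative and inclusive at 50%", {
  locus <- genomic_interval("chr1", 1001, 2000)
  pseudo <- function(w) GenomicRanges::GRanges("chr1",
                                               IRanges::IRanges(1001, 1000 + w))
  expect_equal(classify_status(locus, pseudo(510)), "KNOWN_PSEUDOGENE")
  expect_equal(classify_status(locus, pseudo(490)), "NOVEL")
  expect_equal(classify_status(locus, pseudo(500)), "KNOWN_PSEUDOGENE")
  expect_equal(classify_status(locus, NULL), "NOVEL")
  ## overlapping annotations are unioned, not double-counted
  two <- c(pseudo(300), GenomicRanges::GRanges("chr1",
                                               IRanges::IRanges(1201, 1500)))
  expect_equal(classify_status(locus, two), "KNOWN_PSEUDOGENE")
})

test_that("suspicious parents need both the count excess and 'protein unknown'", {
  mk_calls <- function(n, gid) data.frame(parental_gene = rep(gid, n))
  unknown <- synthetic_gene("GU", list(c(40L, 40L)),
                            description = "Protein Unknown")
  known <- synthetic_gene("GK", list(c(40L, 40L)),
                          description = "kinase, well described")
  gs <- as_gene_set(unknown, known)
  expect_equal(flag_suspicious_parents(mk_calls(51, "GU"), gs, "mammal"), "GU")
  expect_length(flag_suspicious_parents(mk_calls(51, "GK"), gs, "mammal"), 0)
  expect_length(flag_suspicious_parents(mk_calls(50, "GU"), gs, "mammal"), 0)
  expect_equal(flag_suspicious_parents(mk_calls(6, "GU"), gs, "other"), "GU")
  expect_length(flag_suspicious_parents(mk_calls(6, "GU"), gs, "mammal"), 0)
  expect_error(flag_suspicious_parents(mk_calls(6, "GU"), gs, "fungal"))
})

test_that("calling recovers implants with correct parents and rejects controls", {
  fx <- standard_fixture()
  chains <- truth_alignments(fx)
  calls <- call_retrocopies(chains, fx$genes, clade = "other",
                            species_prefix = "SYN")
  truth <- fixture_truth_table(fx)
  pos <- truth[truth$expected_call, ]
  expect_equal(nrow(calls), nrow(pos))
  m <- match(calls$start, pos$start)
  expect_false(anyNA(m))
  expect_equal(calls$parental_gene, pos$source_gene[m])
  expect_true(all(calls$introns_lost >= 2))
  neg <- truth[!truth$expected_call, ]
  expect_false(any(calls$start %in% neg$start))
})

test_that("raising any threshold never increases the number of calls", {
  fx <- standard_fixture()
  chains <- truth_alignments(fx)
  base <- nrow(call_retrocopies(chains, fx$genes, clade = "other"))
  for (tweak in list(list(min_aln_bp = 400L), list(min_identity = 0.95),
                     list(min_coverage = 0.99), list(min_lost_introns = 4L))) {
    thr <- do.call(retro_thresholds, tweak)
    expect_lte(nrow(call_retrocopies(chains, fx$genes, thresholds = thr,
                                     clade = "other")), base)
  }
})

test_that("calls are identical under permutation of the input chains", {
  fx <- standard_fixture()
  chains <- truth_alignments(fx)
  a <- call_retrocopies(chains, fx$genes, clade = "other")
  set.seed(3)
  b <- call_retrocopies(sample(chains), fx$genes, clade = "other")
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a parent aligning to its own locus is never called", {
  fx <- standard_fixture()
  self_only <- truth_alignments(fx, include_self = TRUE)
  keep <- vapply(self_only, function(ch) {
    g <- NULL
    for (gg in fx$genes) if (ch$query_id %in% names(gg$transcripts)) g <- gg
    ch$t_start <= g$end && ch$t_end >= g$start
  }, NA)
  calls <- call_retrocopies(self_only[keep], fx$genes, clade = "other")
  expect_equal(nrow(calls), 0)
})

test_that("BED12 output mirrors the call loci", {
  fx <- standard_fixture()
  calls <- call_retrocopies(truth_alignments(fx), fx$genes, clade = "other")
  dir <- withr::local_tempdir()
  write_calls(calls, file.path(dir, "out"))
  bed <- read.table(file.path(dir, "out.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(calls))
  expect_equal(bed$V2, calls$start - 1L)
  expect_equal(bed$V3, calls$end)
  expect_equal(bed$V6, calls$strand)
  tsv <- read.table(file.path(dir, "out.tsv"), sep = "\t", header = TRUE)
  expect_equal(tsv$retrocopy_id, calls$retrocopy_id)
})
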