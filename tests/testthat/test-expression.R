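expr_fixture <- function() {
  if (is.null(.fixture_cache$expr)) {
    spec <- fixture_spec(seed = 301L, n_genes = 6L, n_retrocopies = 5L,
                         substitution_rate = 0.02, n_intron_retaining = 0L,
                         n_single_exon_fragments = 0L)
    .fixture_cache$expr <- implant_retrocopies(generate_genome(spec))
  }
  .fixture_cache$expr
}

make_bam <- function(sam_lines, dir) {
  sam <- file.path(dir, "reads.sam")
  writeLines(sam_lines, sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

test_that("only uniquely mapped reads are counted, matching a linear scan", {
  fx <- expr_fixture()
  em <- simulate_expression(fx,
                            unique_reads = c(IMP_001 = 3L, IMP_002 = 7L),
                            multi_reads = c(IMP_001 = 2L, IMP_003 = 4L))
  dir <- withr::local_tempdir()
  bam <- make_bam(em$sam_lines, dir)
  truth <- fixture_truth_table(fx)
  for (id in c("IMP_001", "IMP_002", "IMP_003")) {
    r <- truth[truth$implant_id == id, ]
    locus <- genomic_interval(r$chrom, r$start, r$end, r$strand)
    got <- count_unique_reads(bam, locus)
    ## independent linear scan over the SAM text
    body <- em$sam_lines[!grepl("^@", em$sam_lines)]
    f <- strsplit(body, "\t")
    oracle <- sum(vapply(f, function(x) {
      pos <- as.integer(x[4]); len <- nchar(x[10])
      nh <- as.integer(sub("NH:i:", "", grep("^NH:i:", x, value = TRUE)))
      nh == 1L && pos <= r$end && (pos + len - 1L) >= r$start
    }, NA))
    expect_equal(got, oracle)
  }
  expect_equal(count_unique_reads(bam, genomic_interval(
    truth$chrom[1], truth$start[1], truth$end[1])), 3)
})

test_that("reads abutting the locus boundary are not counted", {
  fx <- expr_fixture()
  truth <- fixture_truth_table(fx)
  r <- truth[truth$implant_id == "IMP_001", ]
  t_size <- Biostrings::width(fx$genome)[1]
  dir <- withr::local_tempdir()
  chrom_seq <- as.character(fx$genome[[1]])
  read_at <- function(pos) paste("r", 0, r$chrom, pos, 60, "50M", "*", 0, 0,
                                 substring(chrom_seq, pos, pos + 49),
                                 strrep("I", 50), "NH:i:1", sep = "\t")
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", r$chrom, "\tLN:", t_size),
           read_at(r$start - 50L),   # ends 1 bp before the locus
           read_at(r$start - 49L),   # overlaps by exactly 1 bp
           read_at(r$end + 1L))      # starts 1 bp after the locus
  bam <- make_bam(sam, dir)
  expect_equal(count_unique_reads(bam, genomic_interval(r$chrom, r$start,
                                                        r$end)), 1)
})

test_that("an unindexed BAM is an error", {
  expect_error(count_unique_reads(file.path(tempdir(), "nope.bam"),
                                  genomic_interval("chr1", 1, 10)),
               "index")
})

test_that("RPM arithmetic is exact and inclusive at 1.0", {
  expect_equal(compute_rpm(10, 5e6), 2.0)
  expect_equal(compute_rpm(4, 5e6), 0.8)
  expect_equal(compute_rpm(5, 5e6), 1.0)
  expect_true(compute_rpm(5, 5e6) >= 1.0)
  expect_false(compute_rpm(4, 5e6) >= 1.0)
  expect_error(compute_rpm(1, 0), "positive")
  ## linearity; doubling the library halves RPM
  expect_equal(compute_rpm(20, 5e6), 2 * compute_rpm(10, 5e6))
  expect_equal(compute_rpm(10, 1e7), compute_rpm(10, 5e6) / 2)
})

test_that("EST validation enforces length, identity and strict best-hit", {
  retro <- genomic_interval("chr1", 50000, 51000)
  hit <- function(len, mism, tstart, score = len - 2 * mism) {
    alignment_chain("EST1", len, "chr1", 100000L, "+",
                    data.frame(qstart = 1L, tstart = tstart, len = len),
                    matches = len - mism, score = score)
  }
  ## parent hit worse on both axes: accepted
  res <- validate_est(list(hit(120L, 5L, 50100L), hit(120L, 8L, 2000L)), retro)
  expect_true(res$accepted)
  ## too short
  expect_false(validate_est(list(hit(99L, 2L, 50100L)), retro)$accepted)
  ## identity below 90%
  expect_false(validate_est(list(hit(120L, 13L, 50100L)), retro)$accepted)
  ## equal score elsewhere: rejected (strictness)
  tie <- validate_est(list(hit(120L, 5L, 50100L), hit(120L, 5L, 2000L)), retro)
  expect_false(tie$accepted)
  ## parent strictly better: rejected
  worse <- validate_est(list(hit(120L, 8L, 50100L), hit(120L, 2L, 2000L)),
                        retro)
  expect_false(worse$accepted)
  ## no hit on the retrocopy at all
  expect_false(validate_est(list(hit(120L, 2L, 2000L)), retro)$accepted)
})

test_that("window association matches the worked boundary cases", {
  tss_at <- function(pos) GenomicRanges::GRanges("chr1",
                                                 IRanges::IRanges(pos, pos))
  locus <- genomic_interval("chr1", 10001, 12000)   # width 2000, 5' at 10001
  expect_true(associate_signal(locus, tss_at(9601), 500L, 0.30)$associated)
  expect_false(associate_signal(locus, tss_at(9400), 500L, 0.30)$associated)
  ## body window ends at 10001 + 600 - 1
  expect_true(associate_signal(locus, tss_at(10600), 500L, 0.30)$associated)
  expect_false(associate_signal(locus, tss_at(10700), 500L, 0.30)$associated)
  ## minus strand mirrors around the 5' end at the right edge
  minus <- genomic_interval("chr1", 10001, 12000, "-")
  expect_true(associate_signal(minus, tss_at(12400), 500L, 0.30)$associated)
  expect_false(associate_signal(minus, tss_at(12600), 500L, 0.30)$associated)
  expect_true(associate_signal(minus, tss_at(11401), 500L, 0.30)$associated)
  expect_false(associate_signal(minus, tss_at(11300), 500L, 0.30)$associated)
})

test_that("association agrees with a per-base brute-force oracle", {
  set.seed(424)
  for (up in c(1000L, 500L)) {
    for (rep in 1:250) {
      s <- sample(2000:30000, 1)
      w <- sample(300:3000, 1)
      strand <- sample(c("+", "-"), 1)
      locus <- genomic_interval("chr1", s, s + w - 1L, strand)
      fs <- sample(1000:33000, 1)
      fw <- sample(1:400, 1)
      feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(fs, fs + fw - 1L))
      got <- associate_signal(locus, feat, up, 0.30)$associated
      ## brute force: enumerate the window's base positions
      body <- floor(0.30 * w)
      win <- if (strand == "-")
        seq(s + w - 1L - body + 1L, s + w - 1L + up) else
          seq(max(1L, s - up), s + body - 1L)
      oracle <- length(intersect(win, seq(fs, fs + fw - 1L))) > 0
      expect_identical(got, oracle)
    }
  }
})

test_that("evidence bundles keep 'not assessed' distinct from negative", {
  b <- merge_evidence(rpm_by_library = c(lib1 = 2.0))
  expect_true(b$rnaseq_expressed)
  expect_true(is.na(b$est_expressed))
  expect_true(is.na(b$polII))
  neg <- merge_evidence(rpm_by_library = c(l = 0.2), est_ids = character(0),
                        polII = FALSE, tss = FALSE)
  expect_false(neg$rnaseq_expressed)
  expect_false(neg$est_expressed)
  expect_false(neg$polII)
  ## multi-library OR at the inclusive threshold
  expect_true(merge_evidence(rpm_by_library = c(a = 0.2, b = 1.0))$rnaseq_expressed)
  ## recomputation from the same inputs is identical
  expect_identical(b, merge_evidence(rpm_by_library = c(lib1 = 2.0)))
})

test_that("count-table expression annotation reproduces RPM flags", {
  fx <- expr_fixture()
  calls <- call_retrocopies(truth_alignments(fx), fx$genes, clade = "other")
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "counts.tsv")
  tab <- data.frame(retrocopy_id = calls$retrocopy_id[1:3],
                    library = "lib1",
                    unique_count = c(10L, 5L, 4L),
                    library_total = 5e6)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- annotate_expression_table(calls, tsv)
  expect_equal(out$max_rpm[1:3], c(2.0, 1.0, 0.8))
  expect_equal(out$rnaseq_expressed[1:3], c(TRUE, TRUE, FALSE))
  expect_false(any(out$rnaseq_expressed[-(1:3)]))
})
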