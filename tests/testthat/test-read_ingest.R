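test_that("qc_filter keeps reads at or above the threshold", {
  r <- data.frame(read_id = c("a", "b", "c"), length = c(100L, 200L, 300L),
                  mean_quality = c(6.9, 7.0, 11.6))
  out <- qc_filter(r)
  expect_equal(out$reads$read_id, c("b", "c"))
  expect_equal(out$report$n_removed, 1L)

  # threshold 0 is the identity
  expect_equal(qc_filter(r, 0)$reads, r)

  # everything below threshold -> empty kept set with a zero/3 report
  all_low <- qc_filter(r, 20)
  expect_equal(nrow(all_low$reads), 0L)
  expect_equal(all_low$report$n_kept, 0L)

  # idempotence
  expect_equal(qc_filter(out$reads)$reads, out$reads)
})

test_that("FASTQ records carry arithmetic mean Phred quality", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1 extra", "ACGT", "+", "IIII",    # Q40
               "@r2", "ACGTAC", "+", "$$$$$$"), fq) # Q3
  rec <- read_fastq_records(fq)
  expect_equal(rec$read_id, c("r1", "r2"))
  expect_equal(rec$length, c(4L, 6L))
  expect_equal(rec$mean_quality, c(40, 3))
  expect_equal(qc_filter(rec)$reads$read_id, "r1")
})

test_that("N50 follows the strict-majority convention", {
  expect_equal(read_n50(c(100, 200, 700)), 700)
  expect_equal(read_n50(c(500, 500, 1000)), 500)
  expect_equal(read_n50(rep(42, 10)), 42)
  s <- summarize_reads(rep(42, 10))
  expect_equal(s$mean_length, 42)
  expect_equal(s$median_length, 42)
  expect_equal(s$n50, 42)
  expect_error(summarize_reads(numeric(0)), "no reads")
})

test_that("N50 agrees with the brute-force oracle on random multisets", {
  withr::with_seed(99L, {
    for (i in 1:1000) {
      lens <- sample.int(5000L, sample.int(40L, 1L), replace = TRUE)
      expect_identical(read_n50(lens), oracle_n50(lens))
    }
  })
})

test_that("PAF parsing maps fields and walks CIGARs", {
  paf <- tempfile(fileext = ".paf")
  writeLines(c(
    # no CIGAR: single block [0,90), matches from col 10
    "r1\t95\t0\t90\t+\ttx1\t100\t0\t90\t85\t90\t60",
    # 50M10D40M -> blocks [0,50) and [60,100)
    "r2\t90\t0\t90\t+\ttx1\t100\t0\t100\t88\t100\t60\tcg:Z:50M10D40M",
    # 50M10I40M -> insertions consume no target: single [0,90)
    "r3\t100\t0\t100\t+\ttx1\t100\t0\t90\t89\t100\t60\tcg:Z:50M10I40M",
    # secondary: excluded up front
    "r1\t95\t0\t90\t+\ttx2\t100\t0\t90\t80\t90\t0\ttp:A:S"
  ), paf)
  aln <- parse_alignments(paf, dialect = "paf")
  expect_equal(nrow(aln), 3L)
  expect_equal(aln$blocks, c("0-90", "0-50;60-100", "0-90"))
  expect_equal(aln$matches[1L], 85L)
  expect_equal(attr(aln, "report")$n_secondary, 1L)

  # bridging deletions <= N merges split blocks
  bridged <- parse_alignments(paf, dialect = "paf", bridge_deletions = 10L)
  expect_equal(bridged$blocks[2L], "0-100")
})

test_that("unknown targets are dropped and counted against a catalog", {
  cat <- toy_catalog()
  tsv <- tempfile(fileext = ".tsv")
  aln <- rbind(aln_row("r1", "T1", 250L, 0L, 100L),
               aln_row("r2", "NOPE", 250L, 0L, 100L))
  write_alignment_tsv(aln, tsv)
  expect_message(got <- parse_alignments(tsv, catalog = cat), "unknown")
  expect_equal(got$read_id, "r1")
  expect_equal(attr(got, "report")$n_unknown_target, 1L)
})

test_that("alignment-TSV round-trips blocks exactly", {
  withr::with_seed(17L, {
    rows <- lapply(1:50, function(i) {
      m <- random_blocks(500L)
      aln_row(sprintf("r%03d", i), "tx1", 500L, m[1L, 1L],
              m[nrow(m), 2L],
              matches = sum(m[, 2L] - m[, 1L]),
              blocks = paste(sprintf("%d-%d", m[, 1L], m[, 2L]),
                             collapse = ";"))
    })
  })
  aln <- do.call(rbind, rows)
  tsv <- tempfile(fileext = ".tsv")
  write_alignment_tsv(aln, tsv)
  back <- parse_alignments(tsv)
  expect_equal(back$blocks, aln$blocks)
  write_alignment_tsv(back, tsv)
  expect_equal(parse_alignments(tsv)$blocks, aln$blocks)
})

test_that("select_primary is deterministic under the stated tie-breaks", {
  a <- rbind(aln_row("r", "A", 100L, 0L, 90L, matches = 80L),
             aln_row("r", "B", 100L, 0L, 90L, matches = 60L))
  expect_equal(select_primary(a)$transcript_id, "A")

  b <- rbind(aln_row("r", "A", 100L, 0L, 90L, matches = 80L),
             aln_row("r", "B", 100L, 0L, 85L, matches = 80L))
  expect_equal(select_primary(b)$transcript_id, "A")

  c3 <- rbind(aln_row("r", "tx2", 100L, 0L, 90L, matches = 80L),
              aln_row("r", "tx1", 100L, 0L, 90L, matches = 80L))
  expect_equal(select_primary(c3)$transcript_id, "tx1")
})
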