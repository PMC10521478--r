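make_candidates <- function(spec) {
  # spec: list of c(read_id, transcript ids...)
  do.call(rbind, lapply(spec, function(s)
    do.call(rbind, lapply(s[-1L], function(t)
      aln_row(s[1L], t, 100L, 0L, 90L)))))
}

test_that("EM equals direct counts when every read maps uniquely", {
  cand <- make_candidates(lapply(1:20, function(i)
    c(sprintf("r%02d", i), sprintf("tx%d", (i %% 4) + 1L))))
  em <- em_assign(cand, mode = "em")
  po <- em_assign(cand, mode = "primary_only")
  expect_equal(em$counts[sort(names(em$counts))],
               po$counts[sort(names(po$counts))])
  expect_equal(sum(em$counts), 20)
})

test_that("fully symmetric two-transcript instance splits 50/50", {
  cand <- make_candidates(lapply(1:10, function(i)
    c(sprintf("r%02d", i), "A", "B")))
  em <- em_assign(cand, mode = "em")
  expect_equal(unname(em$counts["A"]), 5, tolerance = 1e-6)
  expect_equal(unname(em$counts["B"]), 5, tolerance = 1e-6)
})

test_that("EM matches the independent fixed-point oracle on a mixed toy", {
  spec <- c(lapply(1:6, function(i) c(sprintf("u%d", i), "A")),
            lapply(1:2, function(i) c(sprintf("v%d", i), "B")),
            lapply(1:4, function(i) c(sprintf("w%d", i), "A", "B")))
  cand <- make_candidates(spec)
  em <- em_assign(cand, mode = "em")
  ref <- oracle_em(cand)
  expect_equal(em$counts[names(ref)], ref, tolerance = 1e-6)
  # log-likelihood is non-decreasing along the EM trace
  expect_true(all(diff(em$loglik) >= -1e-12))
})

test_that("EM conserves reads on random compatibility structures", {
  withr::with_seed(31L, {
    for (rep in 1:10) {
      spec <- lapply(seq_len(sample(5:30, 1L)), function(i)
        c(sprintf("r%02d", i),
          sample(paste0("tx", 1:6), sample.int(3L, 1L))))
      cand <- make_candidates(spec)
      em <- em_assign(cand, mode = "em")
      expect_equal(sum(em$counts), em$n_reads, tolerance = 1e-6)
      expect_true(all(diff(em$loglik) >= -1e-12))
    }
  })
})

comp_catalog <- function() {
  path <- write_toy_gtf(c(
    gtf_exon(start1 = 1, end1 = 100, tx = "P1", gene = "GP1"),
    gtf_exon(start1 = 201, end1 = 300, tx = "P2", gene = "GP2"),
    gtf_exon(start1 = 401, end1 = 500, tx = "P3", gene = "GP3"),
    gtf_exon(start1 = 601, end1 = 700, tx = "R1", gene = "GR1",
             biotype = "rRNA")
  ))
  read_transcript_catalog(path)
}

test_that("composition reports transcript share and read share separately", {
  cat <- comp_catalog()
  counts <- c(P1 = 1, P2 = 1, P3 = 1, R1 = 97)
  tab <- biotype_composition(counts, cat)
  expect_equal(tab$composition_pct[tab$biotype == "protein_coding"], 75)
  expect_equal(tab$composition_pct[tab$biotype == "rRNA"], 25)
  expect_equal(tab$read_count_pct[tab$biotype == "protein_coding"], 3)
  expect_equal(tab$read_count_pct[tab$biotype == "rRNA"], 97)
  # all vocabulary rows are present, including empty biotypes
  expect_true("lncRNA" %in% tab$biotype)
  expect_equal(tab$composition_pct[tab$biotype == "lncRNA"], 0)
  expect_equal(sum(tab$composition_pct), 100, tolerance = 1e-9)
  expect_equal(sum(tab$read_count_pct), 100, tolerance = 1e-9)

  solo <- biotype_composition(c(P1 = 5, P2 = 3), cat)
  expect_equal(solo$composition_pct[solo$biotype == "protein_coding"], 100)
  expect_equal(solo$read_count_pct[solo$biotype == "protein_coding"], 100)
})

test_that("intrinsic genes are the all-sample intersection over the union", {
  cat <- comp_catalog()
  # gene sets: s1 = {GP1, GP2}, s2 = {GP2, GP3}, s3 = {GP2}
  cm <- count_matrix(list(
    s1 = c(P1 = 5, P2 = 5), s2 = c(P2 = 5, P3 = 5), s3 = c(P2 = 5)), cat)
  groups <- data.frame(sample_id = c("s1", "s2", "s3"),
                       group = c("Exo", "Exo", "MV"))
  res <- intrinsic_genes(cm, groups, cat)
  expect_equal(res$intrinsic_genes, "GP2")
  expect_equal(res$proportion, 1 / 3)

  # identical samples -> proportion 1
  cm2 <- count_matrix(list(a = c(P1 = 2, P2 = 2), b = c(P1 = 2, P2 = 2)),
                      cat)
  g2 <- data.frame(sample_id = c("a", "b"), group = c("Exo", "MV"))
  expect_equal(intrinsic_genes(cm2, g2, cat)$proportion, 1)

  # single group: sets computed, test skipped with a notice
  g3 <- data.frame(sample_id = c("s1", "s2", "s3"), group = "Exo")
  expect_message(res3 <- intrinsic_genes(cm, g3, cat), "skipped")
  expect_null(res3$test)
  expect_equal(res3$intrinsic_genes, "GP2")
})

test_that("correlation matrix is symmetric PSD with unit self-correlation", {
  cat <- comp_catalog()
  x <- c(P1 = 3, P2 = 10, P3 = 0, R1 = 44)
  cm <- count_matrix(list(s1 = x, s2 = x, s3 = c(P1 = 9, P2 = 1, R1 = 30)),
                     cat)
  r <- correlation_matrix(cm)
  expect_equal(unname(r["s1", "s1"]), 1)
  expect_equal(unname(r["s1", "s2"]), 1)  # identical profiles
  expect_equal(r, t(r))
  expect_true(all(eigen(r, only.values = TRUE)$values > -1e-12))

  # r = 1 under affine relation on the correlated scale
  cm2 <- cbind(cm, s4 = (cm[, "s3"] + 1)^2 - 1)
  r2 <- correlation_matrix(cm2, transform = "log1p10")
  expect_equal(unname(r2["s3", "s4"]), 1)

  # zero-variance profile -> NA, not 0
  cm3 <- cbind(cm, s5 = 0)
  r3 <- correlation_matrix(cm3)
  expect_true(is.na(r3["s5", "s1"]))

  # five-point toy matches the direct formula
  a <- log10(cm[, "s1"] + 1); b <- log10(cm[, "s3"] + 1)
  expect_equal(unname(r["s1", "s3"]), oracle_pearson(a, b)$r,
               tolerance = 1e-12)
})

test_that("group-specific sets roll up to genes correctly", {
  cat <- comp_catalog()
  groups <- data.frame(sample_id = c("e1", "e2", "m1"),
                       group = c("Exo", "Exo", "MV"))
  # disjoint groups
  cm <- count_matrix(list(e1 = c(P1 = 5), e2 = c(P2 = 5),
                          m1 = c(R1 = 5)), cat)
  res <- group_specific_sets(cm, groups, cat)
  expect_equal(res$shared_transcripts, character(0))
  expect_equal(res$Exo$transcripts, c("P1", "P2"))
  expect_equal(res$MV$transcripts, "R1")
  expect_equal(res$MV$genes, "GR1")

  # identical groups -> both unique sets empty
  cm2 <- count_matrix(list(e1 = c(P1 = 5), e2 = c(P1 = 5),
                           m1 = c(P1 = 5)), cat)
  res2 <- group_specific_sets(cm2, groups, cat)
  expect_equal(res2$Exo$n_transcripts, 0L)
  expect_equal(res2$MV$n_transcripts, 0L)

  # one MV-only transcript is listed with its gene
  cm3 <- count_matrix(list(e1 = c(P1 = 5), e2 = c(P1 = 2),
                           m1 = c(P1 = 1, P3 = 4)), cat)
  res3 <- group_specific_sets(cm3, groups, cat)
  expect_equal(res3$MV$transcripts, "P3")
  expect_equal(res3$MV$genes, "GP3")
})

test_that("degradation machinery screen honours prefix patterns", {
  path <- write_toy_gtf(c(
    gtf_exon(start1 = 1, end1 = 100, tx = "t1", gene = "PARN"),
    gtf_exon(start1 = 201, end1 = 300, tx = "t2", gene = "LSM3"),
    gtf_exon(start1 = 401, end1 = 500, tx = "t3", gene = "ACTB")
  ))
  cat <- read_transcript_catalog(path)
  cm <- count_matrix(list(s1 = c(t1 = 5, t2 = 5, t3 = 5),
                          s2 = c(t3 = 5)), cat)
  groups <- data.frame(sample_id = c("s1", "s2"), group = c("Exo", "MV"))
  tab <- flag_degradation_machinery(cm, groups, cat)
  expect_true(tab$detected[tab$gene == "PARN" & tab$sample_id == "s1"])
  expect_false(tab$detected[tab$gene == "PARN" & tab$sample_id == "s2"])
  expect_true("LSM3" %in% tab$gene)  # LSM* prefix match
  expect_true(tab$detected[tab$gene == "LSM3" & tab$sample_id == "s1"])
  # absent genes stay in the table, undetected
  expect_true(all(!tab$detected[tab$gene == "SMG5"]))
  # empty gene list -> empty table
  expect_equal(nrow(flag_degradation_machinery(cm, groups, cat,
                                               genes = character(0))), 0L)
})
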