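test_that("catalog simulation is deterministic and validated", {
  cfg <- sim_config(seed = 3L, n_transcripts = 40L)
  c1 <- simulate_catalog(cfg)
  c2 <- simulate_catalog(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_catalog_gtf(c1, f1); write_catalog_gtf(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  fa1 <- tempfile(); fa2 <- tempfile()
  write_catalog_fasta(c1, fa1); write_catalog_fasta(c2, fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  expect_error(simulate_catalog(sim_config(seed = 1L, n_transcripts = 0L)),
               "n_transcripts")

  # lengths respect the truncation range; sequences match lengths
  expect_true(all(c1$info$length >= 200L & c1$info$length <= 32000L))
  expect_equal(unname(Biostrings::width(c1$seq)), c1$info$length)

  # the written GTF round-trips through the annotation loader
  back <- read_transcript_catalog(f1)
  expect_equal(back$info$length, c1$info$length)
  expect_equal(back$info$biotype, c1$info$biotype)
})

test_that("simulated biotype frequencies track the configured mixture", {
  cfg <- sim_config(seed = 19L, n_transcripts = 10000L)
  cat <- simulate_catalog(cfg, with_sequences = FALSE)
  freq <- table(cat$info$biotype) / nrow(cat$info)
  for (b in names(cfg$biotype_probs)) {
    expect_lt(abs(freq[[b]] - cfg$biotype_probs[[b]]), 0.02)
  }
})

test_that("generated reads obey their generative definitions", {
  cfg <- sim_config(seed = 5L, n_transcripts = 50L, n_reads = 800L)
  cat <- simulate_catalog(cfg, with_sequences = FALSE)
  ab <- setNames(rep(1, 50L), cat$info$transcript_id)

  # p_intact = 1: every read is a full-length [0, L) copy
  all_int <- simulate_sample(cat, ab, cfg, "s", seed = 2L, p_intact = 1)
  expect_true(all(all_int$truth$is_intact))
  expect_true(all(all_int$alignments$t_start == 0L))
  expect_equal(all_int$alignments$t_end, all_int$alignments$t_len)

  # direction_weights (1,0,0): every fragment keeps the 5' end only
  cfg35 <- sim_config(seed = 5L, n_transcripts = 50L, n_reads = 800L,
                      direction_weights = c(deg_3to5 = 1, endo = 0,
                                            deg_5to3 = 0))
  one_dir <- simulate_sample(cat, ab, cfg35, "s", seed = 2L, p_intact = 0)
  expect_true(all(one_dir$alignments$t_start == 0L))
  expect_true(all(one_dir$alignments$t_end < one_dir$alignments$t_len))

  # fragments stay below the intact threshold
  mixed <- simulate_sample(cat, ab, cfg, "s", seed = 9L)
  frag <- mixed$truth[!mixed$truth$is_intact, ]
  expect_true(all(frag$retained_fraction < 0.9))
})

test_that("truth intervals reproduce emitted alignments when jitter is 0", {
  cfg <- sim_config(seed = 8L, n_transcripts = 30L, n_reads = 500L)
  cat <- simulate_catalog(cfg, with_sequences = FALSE)
  ab <- setNames(rep(1, 30L), cat$info$transcript_id)
  sim <- simulate_sample(cat, ab, cfg, "s", seed = 4L)
  expect_identical(sim$alignments$t_start, sim$truth$t_start)
  expect_identical(sim$alignments$t_end, sim$truth$t_end)
  expect_identical(sim$alignments$blocks,
                   sprintf("%d-%d", sim$truth$t_start, sim$truth$t_end))

  # with jitter, alignments deviate but truth keeps pre-jitter intervals
  cfg_j <- sim_config(seed = 8L, n_transcripts = 30L, n_reads = 500L,
                      boundary_jitter_sd = 15)
  sim_j <- simulate_sample(cat, ab, cfg_j, "s", seed = 4L)
  expect_true(any(sim_j$alignments$t_start != sim_j$truth$t_start |
                    sim_j$alignments$t_end != sim_j$truth$t_end))
  expect_true(all(sim_j$alignments$t_start >= 0L))
  expect_true(all(sim_j$alignments$t_end <= sim_j$alignments$t_len))
})

test_that("per-sample RNG streams are independent of other samples", {
  cfg <- sim_config(seed = 21L, n_transcripts = 30L, n_reads = 200L)
  cat <- simulate_catalog(cfg, with_sequences = FALSE)
  ab <- setNames(rep(1, 30L), cat$info$transcript_id)
  a1 <- simulate_sample(cat, ab, cfg, "s1", seed = 101L)
  simulate_sample(cat, ab, cfg, "sX", seed = 999L)  # interleaved draw
  a2 <- simulate_sample(cat, ab, cfg, "s1", seed = 101L)
  expect_identical(a1$alignments, a2$alignments)
})

test_that("the study fixture bundles all files with a complete manifest", {
  dir <- file.path(tempdir(), "fx_schema")
  fx <- make_study_fixture(dir, seed = 12L,
                           cfg = sim_config(seed = 12L, n_reads = 300L,
                                            n_transcripts = 40L))
  files <- list.files(dir)
  expect_true(all(c("annotation.gtf", "transcripts.fa", "truth.tsv",
                    "sample_sheet.tsv", "manifest.json") %in% files))
  expect_equal(sum(grepl("alignments\\.tsv$", files)), 6L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 12L)
  expect_equal(length(man$samples), 6L)
  expect_true(all(c("n_reads", "p_intact", "direction_weights") %in%
                    names(man$config)))

  # different seed: same schema, different reads
  dir2 <- file.path(tempdir(), "fx_schema2")
  make_study_fixture(dir2, seed = 13L,
                     cfg = sim_config(seed = 13L, n_reads = 300L,
                                      n_transcripts = 40L))
  expect_equal(sort(list.files(dir2)), sort(files))
  expect_false(identical(readLines(file.path(dir, "Exo1.alignments.tsv")),
                         readLines(file.path(dir2, "Exo1.alignments.tsv"))))
})

test_that("fixture groups differ in intact probability as configured", {
  dir <- file.path(tempdir(), "fx_groups")
  fx <- make_study_fixture(dir, seed = 33L,
                           cfg = sim_config(seed = 33L, n_reads = 2000L,
                                            n_transcripts = 60L))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  p <- tapply(truth$is_intact, substr(truth$sample_id, 1L, 2L), mean)
  expect_gt(p[["Ex"]], p[["MV"]])
})
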