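# In-code fixtures shared by the unit tests.

write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon <- function(chr = "chr1", start1, end1, strand = "+", gene = "G1",
                     tx = "T1", biotype = "protein_coding") {
  sprintf(paste0("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
                 "transcript_id \"%s\"; transcript_biotype \"%s\";"),
          chr, start1, end1, strand, gene, tx, biotype)
}

# Two-exon toy transcript: exons [100,200) + [300,450), length 250.
toy_catalog <- function(strand = "+") {
  path <- write_toy_gtf(c(
    gtf_exon(start1 = 101, end1 = 200, strand = strand),
    gtf_exon(start1 = 301, end1 = 450, strand = strand)
  ))
  read_transcript_catalog(path)
}

# Minimal single-block alignment row(s).
aln_row <- function(read_id, transcript_id, t_len, t_start, t_end,
                    matches = t_end - t_start,
                    blocks = sprintf("%d-%d", t_start, t_end)) {
  data.frame(read_id = read_id, transcript_id = transcript_id,
             t_len = t_len, t_start = t_start, t_end = t_end,
             matches = matches, blocks = blocks, stringsAsFactors = FALSE)
}

random_blocks <- function(t_len, max_blocks = 5L) {
  k <- sample.int(max_blocks, 1L)
  s <- sort(sample.int(t_len, 2L * k))
  m <- matrix(s, ncol = 2L, byrow = TRUE)
  m[, 1L] <- m[, 1L] - 1L  # 0-based starts
  keep <- m[, 2L] > m[, 1L]
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) m <- matrix(c(0L, 1L), ncol = 2L)
  colnames(m) <- c("start", "end")
  m
}
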