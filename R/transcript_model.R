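# Reference transcript models: strand-aware exon structure, biotype and
# length, plus genomic -> transcript coordinate conversion. All internal
# coordinates are 0-based half-open; GTF/FASTA I/O converts at the boundary.

# Closed biotype vocabulary; anything else collapses to "other".
BIOTYPE_VOCABULARY <- c("protein_coding", "retained_intron", "lncRNA",
                        "nonsense_mediated_decay", "processed_transcript",
                        "misc_RNA", "rRNA")

#' Load a transcript catalog from GTF (and optionally transcript FASTA)
#'
#' Reads exon features from an Ensembl-dialect GTF and builds one transcript
#' model per `transcript_id`: ordered exons, strand, biotype and spliced
#' length. Records with unparsable `transcript_id`/`gene_id` attributes are
#' skipped and counted in the load report. Biotypes outside the closed
#' vocabulary (protein_coding, retained_intron, lncRNA,
#' nonsense_mediated_decay, processed_transcript, misc_RNA, rRNA) collapse
#' to `"other"` with a warning. If a transcript FASTA is supplied, any
#' transcript whose sequence length disagrees with its exon-sum length is
#' rejected and reported.
#'
#' @param gtf_file Path to a GTF/GFF2 annotation with exon features carrying
#'   `transcript_id "x"; gene_id "y";` and optionally
#'   `transcript_biotype "z"` attributes.
#' @param fasta_file Optional path to transcript sequences (record ids must
#'   be transcript ids; the first whitespace-delimited token is used).
#' @return An object of class `transcript_catalog`: a list with `info`
#'   (data.frame: transcript_id, gene_id, biotype, strand, seqname, length),
#'   `exons` (data.frame: transcript_id, start, end; 0-based half-open,
#'   ascending genomic start), `seq` (`DNAStringSet` or NULL) and `report`
#'   (skipped/rejected record accounting).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr1\tx\texon\t101\t200\t.\t+\t.\t",
#'                   "gene_id \"G1\"; transcript_id \"T1\"; ",
#'                   "transcript_biotype \"protein_coding\";"), gtf)
#' cat <- read_transcript_catalog(gtf)
#' cat$info$length  # 100
#' @export
read_transcript_catalog <- function(gtf_file, fasta_file = NULL) {
  if (!file.exists(gtf_file)) stop("annotation file not found: ", gtf_file)
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]

  tid <- as.character(df$transcript_id %||% rep(NA_character_, nrow(df)))
  gid <- as.character(df$gene_id %||% rep(NA_character_, nrow(df)))
  bad <- is.na(tid) | is.na(gid) | tid == "" | gid == ""
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    message(n_skipped, " exon record(s) with missing/malformed ",
            "transcript_id or gene_id skipped")
  }
  df <- df[!bad, , drop = FALSE]; tid <- tid[!bad]; gid <- gid[!bad]
  if (nrow(df) == 0L) stop("empty catalog: no usable exon records in ", gtf_file)

  biotype <- if ("transcript_biotype" %in% names(df)) {
    as.character(df$transcript_biotype)
  } else rep(NA_character_, nrow(df))
  biotype[is.na(biotype)] <- "other"
  unknown <- setdiff(unique(biotype), c(BIOTYPE_VOCABULARY, "other"))
  if (length(unknown) > 0L) {
    warning("unknown biotype label(s) mapped to \"other\": ",
            paste(unknown, collapse = ", "))
    biotype[biotype %in% unknown] <- "other"
  }

  exons <- data.frame(
    transcript_id = tid,
    start = df$start - 1L,      # GTF is 1-based inclusive
    end = df$end,
    stringsAsFactors = FALSE
  )
  meta <- data.frame(
    transcript_id = tid, gene_id = gid, biotype = biotype,
    strand = as.character(df$strand), seqname = as.character(df$seqnames),
    stringsAsFactors = FALSE
  )

  # A transcript id must map to exactly one gene/strand/chromosome.
  per_tx <- split(meta, meta$transcript_id)
  for (m in per_tx) {
    if (length(unique(m$gene_id)) > 1L || length(unique(m$strand)) > 1L ||
        length(unique(m$seqname)) > 1L) {
      stop("conflicting definitions for duplicated transcript_id: ",
           m$transcript_id[1L])
    }
  }

  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L &&
        any(exons$start[idx][-1L] < exons$end[idx][-length(idx)])) {
      stop("overlapping exons in transcript ", exons$transcript_id[idx[1L]])
    }
  }

  widths <- exons$end - exons$start
  if (any(widths <= 0L)) stop("exon with non-positive width in annotation")
  len <- vapply(by_tx, function(i) sum(widths[i]), numeric(1L))

  first <- !duplicated(meta$transcript_id)
  info <- meta[first, , drop = FALSE]
  info <- info[order(info$transcript_id), , drop = FALSE]
  info$length <- as.integer(len[info$transcript_id])
  rownames(info) <- NULL

  report <- list(n_exon_records = nrow(df), n_skipped = n_skipped,
                 rejected = character(0))
  seqs <- NULL
  if (!is.null(fasta_file)) {
    seqs <- Biostrings::readDNAStringSet(fasta_file)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    have <- info$transcript_id[info$transcript_id %in% names(seqs)]
    mismatch <- have[Biostrings::width(seqs[have]) != info$length[
      match(have, info$transcript_id)]]
    if (length(mismatch) > 0L) {
      message(length(mismatch), " transcript(s) rejected: FASTA length ",
              "disagrees with exon-sum length")
      report$rejected <- mismatch
      info <- info[!info$transcript_id %in% mismatch, , drop = FALSE]
      exons <- exons[!exons$transcript_id %in% mismatch, , drop = FALSE]
    }
    seqs <- seqs[names(seqs) %in% info$transcript_id]
  }
  if (nrow(info) == 0L) stop("empty catalog after validation")

  structure(list(info = info, exons = exons, seq = seqs, report = report),
            class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat("transcript_catalog:", nrow(x$info), "transcripts,",
      length(unique(x$info$gene_id)), "genes\n")
  tab <- sort(table(x$info$biotype), decreasing = TRUE)
  cat("biotypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract one transcript model from a catalog
#'
#' @param catalog A `transcript_catalog`.
#' @param transcript_id Transcript identifier.
#' @return A list with `transcript_id`, `gene_id`, `biotype`, `strand`,
#'   `length` and `exons` (genomic 0-based half-open intervals in ascending
#'   genomic order).
#' @export
transcript_model <- function(catalog, transcript_id) {
  i <- match(transcript_id, catalog$info$transcript_id)
  if (is.na(i)) stop("unknown transcript_id: ", transcript_id)
  ex <- catalog$exons[catalog$exons$transcript_id == transcript_id,
                      c("start", "end"), drop = FALSE]
  rownames(ex) <- NULL
  c(as.list(catalog$info[i, c("transcript_id", "gene_id", "biotype",
                              "strand", "length")]),
    list(exons = ex))
}

#' Convert a genomic interval to transcript coordinates
#'
#' Maps the exonic part of a genomic interval into the transcript's own
#' 5'->3' coordinate system (0-based half-open; position 0 is the 5' end of
#' the mature transcript). On minus-strand transcripts position 0
#' corresponds to the exon base with the largest genomic coordinate, so all
#' downstream degradation-direction logic can reason in one orientation.
#'
#' @param model A transcript model from [transcript_model()].
#' @param g_start,g_end Genomic interval, 0-based half-open.
#' @return Integer vector `c(t_start, t_end)` spanning the exonic part of
#'   the query in transcript space, or `NULL` when the query is entirely
#'   intronic/outside the transcript.
#' @examples
#' cat <- NULL # see read_transcript_catalog() for building a catalog
#' @export
genome_to_transcript <- function(model, g_start, g_end) {
  stopifnot(g_end > g_start)
  ex <- model$exons
  w <- ex$end - ex$start
  ov_s <- pmax(ex$start, g_start)
  ov_e <- pmin(ex$end, g_end)
  hit <- which(ov_e > ov_s)
  if (length(hit) == 0L) return(NULL)
  if (model$strand == "+") {
    off <- cumsum(c(0L, w))[seq_len(nrow(ex))]
    ts <- off[hit] + (ov_s[hit] - ex$start[hit])
    te <- off[hit] + (ov_e[hit] - ex$start[hit])
  } else {
    # transcript order is reverse genomic; offset of exon i = total width of
    # exons genomically downstream of it
    rev_off <- rev(cumsum(c(0L, rev(w)))[seq_len(nrow(ex))])
    ts <- rev_off[hit] + (ex$end[hit] - ov_e[hit])
    te <- rev_off[hit] + (ex$end[hit] - ov_s[hit])
  }
  as.integer(c(min(ts), max(te)))
}
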