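# Read-level QC, read summary statistics and alignment ingestion.
# Alignments live in transcript space as block lists (0-based half-open).

#' Read per-read length/quality records from a FASTQ file
#'
#' Mean quality is the arithmetic mean of the per-base Phred scores
#' (NanoStat-style reporting), not error-probability averaging.
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @return data.frame with `read_id`, `length`, `mean_quality`.
#' @export
read_fastq_records <- function(path) {
  # Biostrings warns about dropped metadata columns during coercion
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  q <- methods::as(Biostrings::quality(x), "IntegerList")
  data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    length = Biostrings::width(x),
    mean_quality = vapply(q, function(v) mean(as.numeric(v)), numeric(1L)),
    stringsAsFactors = FALSE
  )
}

#' Quality-filter reads on mean Phred score
#'
#' Drops reads whose mean base quality is below `min_mean_quality`
#' (default 7). Reads exactly at the threshold are kept: the filter removes
#' quality strictly below the cutoff.
#'
#' @param reads data.frame with at least a `mean_quality` column (see
#'   [read_fastq_records()]).
#' @param min_mean_quality Phred threshold, default 7.
#' @return list with `reads` (kept rows) and `report`
#'   (n_input/n_kept/n_removed and the threshold used).
#' @examples
#' r <- data.frame(read_id = c("a", "b", "c"), length = c(100, 200, 300),
#'                 mean_quality = c(6.9, 7, 11.6))
#' qc_filter(r)$report$n_kept  # 2
#' @export
qc_filter <- function(reads, min_mean_quality = 7) {
  stopifnot(is.numeric(min_mean_quality), min_mean_quality >= 0)
  keep <- reads$mean_quality >= min_mean_quality
  list(
    reads = reads[keep, , drop = FALSE],
    report = list(n_input = nrow(reads), n_kept = sum(keep),
                  n_removed = sum(!keep),
                  min_mean_quality = min_mean_quality)
  )
}

#' N50 of a set of read lengths
#'
#' The largest observed length L such that reads of length >= L contain
#' strictly more than half of all sequenced bases.
#'
#' @param lengths Positive read lengths.
#' @return N50 in nt.
#' @examples
#' read_n50(c(100, 200, 700))   # 700
#' read_n50(c(500, 500, 1000))  # 500
#' @export
read_n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths >= 1))
  ls <- sort(lengths, decreasing = TRUE)
  ls[which(cumsum(as.numeric(ls)) > sum(as.numeric(ls)) / 2)[1L]]
}

#' Summary statistics for a read set
#'
#' @param lengths Read lengths (>= 1 read required).
#' @param qualities Optional per-read mean qualities.
#' @return data.frame row: n_reads, mean_length, median_length, n50,
#'   max_length, mean_quality (NA when qualities are not supplied).
#' @export
summarize_reads <- function(lengths, qualities = NULL) {
  if (length(lengths) == 0L) stop("no reads")
  data.frame(
    n_reads = length(lengths),
    mean_length = mean(lengths),
    median_length = median(lengths),
    n50 = read_n50(lengths),
    max_length = max(lengths),
    mean_quality = if (is.null(qualities)) NA_real_ else mean(qualities)
  )
}

paf_cigar_blocks <- function(cigar, t_start) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- substring(ops, nchar(ops))
  pos <- t_start
  blocks <- list()
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      blocks[[length(blocks) + 1L]] <- c(pos, pos + n[i])
      pos <- pos + n[i]
    } else if (op[i] %in% c("D", "N")) {
      pos <- pos + n[i]
    } # I, S, H, P consume no target bases
  }
  m <- matrix(unlist(blocks), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  merge_blocks(m)
}

#' Parse transcript-space alignments (PAF or alignment-TSV)
#'
#' The alignment-TSV dialect is a 5-column headered table
#' (`read_id`, `transcript_id`, `t_len`, `blocks`, `matches`) with blocks
#' serialized as `start-end;start-end` in 0-based half-open transcript
#' coordinates; it is what the bundled simulator emits. PAF rows use
#' columns 1-12 plus an optional `cg:Z:` CIGAR; with a CIGAR, coverage
#' blocks are the M/=/X runs in target space (deletions split blocks),
#' without one the whole target span `[t_start, t_end)` is a single block.
#' PAF records flagged secondary (`tp:A:S`) are excluded.
#'
#' @param path Alignment file.
#' @param dialect `"auto"` (by extension: `.paf` vs anything else),
#'   `"paf"` or `"tsv"`.
#' @param catalog Optional `transcript_catalog`; records whose target is
#'   absent from the catalog are dropped and counted in the report.
#' @param bridge_deletions Merge coverage blocks separated by at most this
#'   many deleted target bases (default 0: deletions split blocks).
#' @return data.frame with `read_id`, `transcript_id`, `t_len`, `t_start`,
#'   `t_end`, `matches`, `blocks`; attribute `report` counts dropped rows.
#' @export
parse_alignments <- function(path, dialect = c("auto", "paf", "tsv"),
                             catalog = NULL, bridge_deletions = 0L) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.paf(\\.gz)?$", path)) "paf" else "tsv"
  }
  report <- list(n_unknown_target = 0L, n_bad_coord = 0L, n_secondary = 0L)

  if (dialect == "tsv") {
    df <- read.delim(path, header = TRUE, colClasses = c(
      read_id = "character", transcript_id = "character", t_len = "integer",
      blocks = "character", matches = "integer"), comment.char = "#")
    simple <- !grepl(";", df$blocks, fixed = TRUE)
    bl <- vector("list", nrow(df))
    if (any(simple)) {
      m <- utils::strcapture("^([0-9]+)-([0-9]+)$", df$blocks[simple],
                             proto = list(start = integer(),
                                          end = integer()))
      if (anyNA(m$start)) stop("malformed block string in ", path)
      idx <- which(simple)
      for (j in seq_along(idx)) {
        bl[[idx[j]]] <- matrix(c(m$start[j], m$end[j]), ncol = 2L,
                               dimnames = list(NULL, c("start", "end")))
      }
    }
    for (i in which(!simple)) bl[[i]] <- parse_blocks(df$blocks[i])
  } else {
    lines <- readLines(path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(fields, length, integer(1L)) >= 12L
    if (any(!ok)) report$n_bad_coord <- report$n_bad_coord + sum(!ok)
    fields <- fields[ok]
    tags <- vapply(fields, function(f)
      paste(f[-seq_len(12L)], collapse = "\t"), character(1L))
    secondary <- grepl("tp:A:[Ss]", tags)
    report$n_secondary <- sum(secondary)
    fields <- fields[!secondary]; tags <- tags[!secondary]
    get <- function(i) vapply(fields, `[[`, character(1L), i)
    df <- data.frame(
      read_id = get(1L), transcript_id = get(6L),
      t_len = as.integer(get(7L)), t_start = as.integer(get(8L)),
      t_end = as.integer(get(9L)), matches = as.integer(get(10L)),
      stringsAsFactors = FALSE
    )
    cig <- sub("^.*cg:Z:([0-9MIDNSHP=X]+).*$", "\\1", tags)
    cig[!grepl("cg:Z:", tags)] <- NA_character_
    bl <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      bl[[i]] <- if (is.na(cig[i])) {
        matrix(c(df$t_start[i], df$t_end[i]), ncol = 2L,
               dimnames = list(NULL, c("start", "end")))
      } else {
        paf_cigar_blocks(cig[i], df$t_start[i])
      }
    }
  }

  if (bridge_deletions > 0L) {
    bl <- lapply(bl, merge_blocks, gap = as.integer(bridge_deletions))
  }
  df$t_start <- vapply(bl, function(m) m[1L, 1L], numeric(1L))
  df$t_end <- vapply(bl, function(m) m[nrow(m), 2L], numeric(1L))
  df$blocks <- vapply(bl, format_blocks, character(1L))

  bad <- df$t_start < 0 | df$t_end > df$t_len | df$t_end <= df$t_start |
    df$matches < 0
  if (any(bad)) {
    message(sum(bad), " alignment record(s) with out-of-range coordinates dropped")
    report$n_bad_coord <- report$n_bad_coord + sum(bad)
    df <- df[!bad, , drop = FALSE]
  }
  if (!is.null(catalog)) {
    known <- df$transcript_id %in% catalog$info$transcript_id
    report$n_unknown_target <- sum(!known)
    if (any(!known)) {
      message(sum(!known), " alignment record(s) to unknown transcripts dropped")
      df <- df[known, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df <- df[, c("read_id", "transcript_id", "t_len", "t_start", "t_end",
               "matches", "blocks")]
  attr(df, "report") <- report
  df
}

#' Write alignments in the alignment-TSV dialect
#'
#' @param aln Alignment data.frame as returned by [parse_alignments()].
#' @param path Output file.
#' @export
write_alignment_tsv <- function(aln, path) {
  df <- aln[, c("read_id", "transcript_id", "t_len", "blocks", "matches")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' Select one primary alignment per read
#'
#' Keeps, per read, the alignment with the most matched bases; ties broken
#' by longer target span, then lexicographically smallest transcript id
#' (fully deterministic).
#'
#' @param aln Alignment data.frame.
#' @return One row per read id.
#' @export
select_primary <- function(aln) {
  if (nrow(aln) == 0L) return(aln)
  span <- aln$t_end - aln$t_start
  o <- order(aln$read_id, -aln$matches, -span, aln$transcript_id,
             method = "radix")
  out <- aln[o, , drop = FALSE]
  out <- out[!duplicated(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
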