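# Per-read transcript coverage rate and intact/fragmented classification.

#' Per-read coverage rate of the assigned transcript
#'
#' Coverage rate is the width of the union of a read's aligned match blocks
#' divided by the transcript length. Deletions split blocks (unless bridged
#' at parse time), so only target bases physically covered by the read
#' count.
#'
#' @param aln Alignment data.frame (one row per read after
#'   [select_primary()]).
#' @return Numeric vector of coverage rates in `[0, 1]`.
#' @examples
#' a <- data.frame(read_id = "r", transcript_id = "t", t_len = 100L,
#'                 t_start = 0L, t_end = 100L, matches = 90L,
#'                 blocks = "0-50;60-100")
#' coverage_rate(a)  # 0.9
#' @export
coverage_rate <- function(aln) {
  if (any(aln$t_len <= 0L)) stop("transcript length must be positive")
  cov <- numeric(nrow(aln))
  simple <- !grepl(";", aln$blocks, fixed = TRUE)
  if (any(simple)) {
    m <- utils::strcapture("^([0-9]+)-([0-9]+)$", aln$blocks[simple],
                           proto = list(start = integer(),
                                        end = integer()))
    bad <- is.na(m$start) | m$end <= m$start | m$end > aln$t_len[simple]
    if (any(bad)) {
      stop("alignment blocks outside [0, transcript length) for read ",
           aln$read_id[simple][which(bad)[1L]])
    }
    cov[simple] <- (m$end - m$start) / aln$t_len[simple]
  }
  for (i in which(!simple)) {
    b <- parse_blocks(aln$blocks[i])
    if (b[nrow(b), 2L] > aln$t_len[i] || b[1L, 1L] < 0L) {
      stop("alignment blocks outside [0, transcript length) for read ",
           aln$read_id[i])
    }
    cov[i] <- blocks_union_width(b) / aln$t_len[i]
  }
  cov
}

#' Classify coverage rates as intact vs fragmented
#'
#' A read is intact when its coverage rate is STRICTLY greater than the
#' threshold (default 0.90); a read at exactly the threshold is fragmented.
#'
#' @param cov Coverage rates in `[0, 1]`.
#' @param intact_threshold Fraction in (0, 1), default 0.9.
#' @return Character vector, `"intact"` or `"fragmented"`.
#' @export
classify_integrity <- function(cov, intact_threshold = 0.9) {
  stopifnot(intact_threshold > 0, intact_threshold < 1)
  if (any(cov < 0 | cov > 1)) stop("coverage rate outside [0, 1]")
  ifelse(cov > intact_threshold, "intact", "fragmented")
}

#' Per-read integrity calls
#'
#' @param aln Primary alignments (one row per read).
#' @param intact_threshold Intact threshold, default 0.9 (strict `>`).
#' @return data.frame: read_id, transcript_id, coverage_rate, label.
#' @export
integrity_calls <- function(aln, intact_threshold = 0.9) {
  cov <- coverage_rate(aln)
  data.frame(
    read_id = aln$read_id,
    transcript_id = aln$transcript_id,
    coverage_rate = cov,
    label = classify_integrity(cov, intact_threshold),
    stringsAsFactors = FALSE
  )
}

#' Compare intact proportions between EV subtypes
#'
#' Computes the per-sample intact proportion (read-weighted by default;
#' transcript-weighted uses the best coverage per transcript) and a
#' two-sided Welch t-test between the two groups when both have at least
#' two samples.
#'
#' @param calls Integrity calls with an added `sample_id` column.
#' @param sample_groups data.frame `sample_id`, `group`.
#' @param unit `"read"` (default) or `"transcript"`.
#' @param intact_threshold Threshold used when re-deriving labels for the
#'   transcript-weighted unit.
#' @return list: `per_sample` (data.frame sample_id, group, n, n_intact,
#'   intact_proportion), `test` (Welch result or NULL with a notice).
#' @export
intact_proportion_comparison <- function(calls, sample_groups,
                                         unit = c("read", "transcript"),
                                         intact_threshold = 0.9) {
  unit <- match.arg(unit)
  per <- lapply(split(calls, calls$sample_id), function(d) {
    if (nrow(d) == 0L) return(NULL)
    if (unit == "transcript") {
      best <- tapply(d$coverage_rate, d$transcript_id, max)
      lab <- classify_integrity(as.numeric(best), intact_threshold)
    } else {
      lab <- d$label
    }
    data.frame(sample_id = d$sample_id[1L], n = length(lab),
               n_intact = sum(lab == "intact"),
               intact_proportion = mean(lab == "intact"))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  per$group <- sample_groups$group[match(per$sample_id,
                                         sample_groups$sample_id)]
  per <- per[, c("sample_id", "group", "n", "n_intact", "intact_proportion")]
  by_grp <- split(per$intact_proportion, per$group)
  test <- NULL
  if (length(by_grp) == 2L && all(lengths(by_grp) >= 2L)) {
    test <- welch_t(by_grp[[1L]], by_grp[[2L]])
  } else {
    message("fewer than 2 samples in a group: t-test skipped")
  }
  list(per_sample = per, test = test, unit = unit)
}
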