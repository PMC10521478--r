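# Degradation-direction classification of fragmented reads in transcript
# 5'->3' space, plus direction proportions and coverage-by-direction
# histograms.

DIRECTION_LEVELS <- c("deg_3to5", "deg_5to3", "endo", "ambiguous_internal")

# End-proximity tolerance: a terminus counts as covered when the alignment
# comes within delta of it.
end_tolerance <- function(t_len, end_tolerance_fraction = 0.10,
                          end_tolerance_min = 20) {
  pmax(end_tolerance_min, end_tolerance_fraction * t_len)
}

#' Classify the degradation direction of fragmented reads
#'
#' Works entirely in transcript 5'->3' coordinates (position 0 = 5' end;
#' minus-strand genes were already flipped by the coordinate converter). A
#' terminus is covered when the alignment reaches within
#' `delta = max(end_tolerance_min, end_tolerance_fraction * length)` of it:
#' 5' covered and 3' lost is 3'->5' exonucleolytic degradation
#' (`deg_3to5`), the mirror case is `deg_5to3`, neither terminus is
#' endodegradation (`endo`), and a fragmented read that still reaches both
#' termini (internal gaps) is `ambiguous_internal`.
#'
#' @param aln Fragmented primary alignments (one row per read). Passing a
#'   read whose coverage exceeds `intact_threshold` is a contract violation
#'   and raises an error.
#' @param end_tolerance_fraction Fraction of transcript length, default 0.10.
#' @param end_tolerance_min Minimum tolerance in nt, default 20.
#' @param intact_threshold Intact threshold used for the contract check.
#' @return data.frame: read_id, transcript_id, coverage_rate,
#'   covers_5prime, covers_3prime, direction.
#' @export
classify_direction <- function(aln, end_tolerance_fraction = 0.10,
                               end_tolerance_min = 20,
                               intact_threshold = 0.9) {
  if (nrow(aln) == 0L) {
    return(data.frame(read_id = character(0), transcript_id = character(0),
                      coverage_rate = numeric(0), covers_5prime = logical(0),
                      covers_3prime = logical(0), direction = character(0)))
  }
  delta <- end_tolerance(aln$t_len, end_tolerance_fraction, end_tolerance_min)
  if (any(delta >= aln$t_len / 2)) {
    stop("end tolerance reaches half the transcript length for ",
         sum(delta >= aln$t_len / 2), " alignment(s); lower the tolerance")
  }
  cov <- coverage_rate(aln)
  if (any(cov > intact_threshold)) {
    stop("intact read(s) passed to classify_direction: ",
         paste(utils::head(aln$read_id[cov > intact_threshold], 3L),
               collapse = ", "))
  }
  covers5 <- aln$t_start <= delta
  covers3 <- aln$t_end >= aln$t_len - delta
  direction <- ifelse(covers5 & !covers3, "deg_3to5",
               ifelse(!covers5 & covers3, "deg_5to3",
               ifelse(!covers5 & !covers3, "endo", "ambiguous_internal")))
  data.frame(
    read_id = aln$read_id, transcript_id = aln$transcript_id,
    coverage_rate = cov, covers_5prime = covers5, covers_3prime = covers3,
    direction = direction, stringsAsFactors = FALSE
  )
}

#' Direction proportions over fragmented reads
#'
#' Fractions over the three mechanistic classes (3'->5', endo, 5'->3');
#' `ambiguous_internal` reads are excluded from the denominator and
#' reported separately.
#'
#' @param directions Character vector of direction labels (or a
#'   [classify_direction()] data.frame).
#' @return list: `proportions` (named, sums to 1), `n` (non-ambiguous
#'   count), `n_ambiguous`. When every call is ambiguous the proportions
#'   are NA.
#' @export
direction_proportions <- function(directions) {
  if (is.data.frame(directions)) directions <- directions$direction
  if (length(directions) == 0L) stop("no fragmented calls")
  stopifnot(all(directions %in% DIRECTION_LEVELS))
  n_amb <- sum(directions == "ambiguous_internal")
  d <- directions[directions != "ambiguous_internal"]
  lv <- c("deg_3to5", "endo", "deg_5to3")
  if (length(d) == 0L) {
    return(list(proportions = setNames(rep(NA_real_, 3L), lv),
                n = 0L, n_ambiguous = n_amb))
  }
  tab <- table(factor(d, levels = lv))
  list(proportions = setNames(as.numeric(tab) / length(d), lv),
       n = length(d), n_ambiguous = n_amb)
}

#' Coverage-rate histograms per degradation direction
#'
#' Bins fragmented reads' coverage rates into width-0.1 bins over
#' `[0, 0.9]` per direction class. End-anchored classes can reach the top
#' bin; endodegradation is geometrically bounded by `(L - 2*delta)/L`.
#'
#' @param dir_calls [classify_direction()] output (carries coverage_rate).
#' @return data.frame: direction, bin (label `[lo,hi)`), count.
#' @export
coverage_by_direction <- function(dir_calls) {
  breaks <- seq(0, 0.9, by = 0.1)
  labs <- sprintf("[%.1f,%.1f)", breaks[-length(breaks)], breaks[-1L])
  b <- cut(dir_calls$coverage_rate, breaks = breaks, right = FALSE,
           include.lowest = TRUE, labels = labs)
  tab <- table(factor(dir_calls$direction, levels = DIRECTION_LEVELS), b)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("direction", "bin", "count")
  out[order(out$direction, out$bin), c("direction", "bin", "count")] |>
    (\(d) { rownames(d) <- NULL; d })()
}
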