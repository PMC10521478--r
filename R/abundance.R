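# Read-to-transcript assignment and per-sample composition / concordance
# statistics.

#' Assign reads to transcripts (primary-only or EM)
#'
#' In `primary_only` mode each read contributes one count to its
#' [select_primary()] transcript. In `em` mode multi-mapping reads are
#' apportioned by a standard mixture-model EM (NanoCount-style): transcript
#' abundances start uniform over the observed transcripts; the E-step gives
#' each read responsibilities proportional to current abundance over its
#' candidate transcripts; the M-step sets abundance proportional to summed
#' responsibilities; iteration stops when the largest absolute abundance
#' change drops below `tol` or after `max_iter` iterations. Counts are
#' responsibilities summed per transcript, so reads are conserved exactly.
#'
#' @param aln Candidate alignments (data.frame from [parse_alignments()]);
#'   multiple rows per read are its candidates.
#' @param mode `"em"` (default) or `"primary_only"`.
#' @param tol EM convergence tolerance on max abs abundance change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return list with `counts` (named numeric vector of expected read counts),
#'   `n_reads`, `mode`, and for EM `n_iter`, `converged` and `loglik`
#'   (per-iteration log-likelihood trace).
#' @export
em_assign <- function(aln, mode = c("em", "primary_only"), tol = 1e-8,
                      max_iter = 1000L) {
  mode <- match.arg(mode)
  if (nrow(aln) == 0L) {
    return(list(counts = numeric(0), n_reads = 0L, mode = mode))
  }
  if (mode == "primary_only") {
    prim <- select_primary(aln)
    counts <- vapply(split(prim$read_id, prim$transcript_id), length,
                     integer(1L))
    return(list(counts = as.numeric(counts) |>
                  setNames(names(counts)), n_reads = nrow(prim), mode = mode))
  }
  # deduplicate (read, transcript) pairs, keeping the best candidate
  key <- paste(aln$read_id, aln$transcript_id, sep = "\r")
  o <- order(key, -aln$matches, method = "radix")
  aln <- aln[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]

  r <- factor(aln$read_id)
  t <- factor(aln$transcript_id)
  n_reads <- nlevels(r)
  n_tx <- nlevels(t)
  ri <- as.integer(r); ti <- as.integer(t)

  abund <- rep(1 / n_tx, n_tx)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- abund[ti]
    denom <- as.numeric(rowsum(w, ri))         # per-read total weight
    loglik <- c(loglik, sum(log(denom)))
    resp <- w / denom[ri]
    counts <- as.numeric(rowsum(resp, ti))     # ordered by factor level
    new_abund <- counts / n_reads
    delta <- max(abs(new_abund - abund))
    abund <- new_abund
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  counts <- abund * n_reads
  names(counts) <- levels(t)
  list(counts = counts, n_reads = n_reads, n_iter = iter,
       converged = converged, loglik = loglik, mode = mode)
}

#' Build a transcript-by-sample count matrix
#'
#' @param count_list Named list (sample -> named count vector from
#'   [em_assign()]).
#' @param catalog Optional catalog fixing the transcript universe (rows);
#'   otherwise the union of observed transcripts is used.
#' @return Numeric matrix, transcripts x samples.
#' @export
count_matrix <- function(count_list, catalog = NULL) {
  tx <- if (!is.null(catalog)) catalog$info$transcript_id else
    sort(unique(unlist(lapply(count_list, names))))
  m <- matrix(0, nrow = length(tx), ncol = length(count_list),
              dimnames = list(tx, names(count_list)))
  for (s in names(count_list)) {
    v <- count_list[[s]]
    v <- v[names(v) %in% tx]
    m[names(v), s] <- v
  }
  m
}

# Transcript ids detected in a sample: expected counts are floored at
# `floor` and detection requires count >= min_count.
detect_ids <- function(counts, min_count = 1, floor = 1e-3) {
  counts[counts < floor] <- 0
  names(counts)[counts >= min_count]
}

# Aggregate transcript counts to gene counts via the catalog.
gene_counts <- function(counts, catalog) {
  g <- catalog$info$gene_id[match(names(counts), catalog$info$transcript_id)]
  keep <- !is.na(g)
  rowsum(counts[keep], g[keep])[, 1L]
}

#' Biotype composition of one sample: transcript share vs read share
#'
#' Two complementary metrics per biotype: `composition_pct`, the share of
#' DISTINCT detected transcripts, and `read_count_pct`, the share of summed
#' read counts. Long-read EV profiles typically show protein_coding
#' dominating the first metric while lncRNA/misc_RNA/rRNA dominate the
#' second. Every vocabulary biotype (plus "other") is always reported, even
#' at zero.
#'
#' @param counts Named transcript count vector for one sample.
#' @param catalog `transcript_catalog`.
#' @param presence_threshold A transcript counts as present when its count
#'   is strictly greater than this (default 0).
#' @return data.frame: biotype, n_transcripts, composition_pct, reads,
#'   read_count_pct. Both percentage columns sum to 100.
#' @export
biotype_composition <- function(counts, catalog, presence_threshold = 0) {
  if (length(counts) == 0L || sum(counts) <= 0) stop("empty count profile")
  bt <- catalog$info$biotype[match(names(counts), catalog$info$transcript_id)]
  bt[is.na(bt)] <- "other"
  levels <- c(BIOTYPE_VOCABULARY, "other")
  bt <- factor(bt, levels = levels)
  present <- counts > presence_threshold
  n_tx <- as.integer(table(bt[present]))
  reads <- as.numeric(tapply(counts, bt, sum, default = 0))
  data.frame(
    biotype = levels,
    n_transcripts = n_tx,
    composition_pct = 100 * n_tx / sum(n_tx),
    reads = reads,
    read_count_pct = 100 * reads / sum(reads)
  )
}

#' Intrinsic genes: detected in every sample
#'
#' The intrinsic set is the intersection of per-sample detected gene sets;
#' its proportion is reported against the union of genes detected in any
#' sample. A 2x2 chi-square (no continuity correction) contrasts
#' intrinsic/non-intrinsic membership between the two per-group
#' detected-in-all-samples gene sets.
#'
#' @param cm Transcript-by-sample count matrix ([count_matrix()]).
#' @param sample_groups data.frame with `sample_id` and `group`
#'   (`"Exo"`/`"MV"`).
#' @param catalog `transcript_catalog`.
#' @param min_count Detection threshold on expected counts (default 1).
#' @return list: `intrinsic_genes`, `n_intrinsic`, `n_union`, `proportion`,
#'   `denominator` ("union"), `table` (2x2) and `test`
#'   ([chi_square_2x2()] result, or NULL with a notice when a group is
#'   absent or a margin is empty).
#' @export
intrinsic_genes <- function(cm, sample_groups, catalog, min_count = 1) {
  stopifnot(ncol(cm) >= 2L)
  per_sample <- lapply(colnames(cm), function(s)
    names(which(gene_counts(cm[, s], catalog) >= min_count)))
  names(per_sample) <- colnames(cm)
  intrinsic <- Reduce(intersect, per_sample)
  all_genes <- Reduce(union, per_sample)
  res <- list(
    intrinsic_genes = sort(intrinsic),
    n_intrinsic = length(intrinsic),
    n_union = length(all_genes),
    proportion = length(intrinsic) / length(all_genes),
    denominator = "union"
  )
  grp <- sample_groups$group[match(colnames(cm), sample_groups$sample_id)]
  if (length(unique(grp)) < 2L) {
    message("only one group present: chi-square test skipped")
    res$table <- NULL; res$test <- NULL
    return(res)
  }
  group_sets <- lapply(split(colnames(cm), grp), function(ss)
    Reduce(intersect, per_sample[ss]))
  tab <- vapply(group_sets, function(g)
    c(intrinsic = sum(g %in% intrinsic),
      non_intrinsic = sum(!g %in% intrinsic)), numeric(2L))
  res$table <- tab
  res$test <- tryCatch(chi_square_2x2(tab),
                       error = function(e) {
                         message("chi-square test skipped: ",
                                 conditionMessage(e))
                         NULL
                       })
  res
}

#' Pairwise Pearson correlation of sample expression profiles
#'
#' Expression is transformed as log10(count + 1) by default before
#' correlating. With `top_n`, profiles are restricted to the top-n
#' transcripts by mean raw expression across all samples. Zero-variance
#' profiles yield NA (undefined), never 0.
#'
#' @param cm Transcript-by-sample count matrix.
#' @param top_n Optional number of top transcripts to keep.
#' @param transform `"log1p10"` (default) or `"none"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(cm, top_n = NULL,
                               transform = c("log1p10", "none")) {
  transform <- match.arg(transform)
  stopifnot(ncol(cm) >= 2L)
  if (!is.null(top_n)) {
    keep <- order(rowMeans(cm), decreasing = TRUE)[
      seq_len(min(top_n, nrow(cm)))]
    cm <- cm[keep, , drop = FALSE]
  }
  x <- if (transform == "log1p10") log10(cm + 1) else cm
  suppressWarnings(r <- stats::cor(x, method = "pearson"))
  # zero-variance profiles stay NA (undefined), including their diagonal
  r
}

#' Transcripts and genes unique to each EV subtype
#'
#' A feature is unique to a group when it is detected in at least one
#' sample of that group and in no sample of the other.
#'
#' @inheritParams intrinsic_genes
#' @return list with per-group `transcripts`/`genes` id vectors and counts,
#'   plus the shared transcript set.
#' @export
group_specific_sets <- function(cm, sample_groups, catalog, min_count = 1) {
  grp <- sample_groups$group[match(colnames(cm), sample_groups$sample_id)]
  groups <- sort(unique(grp))
  stopifnot(length(groups) == 2L)
  det_tx <- lapply(groups, function(g) {
    ss <- colnames(cm)[grp == g]
    Reduce(union, lapply(ss, function(s) detect_ids(cm[, s], min_count)))
  })
  det_gene <- lapply(groups, function(g) {
    ss <- colnames(cm)[grp == g]
    Reduce(union, lapply(ss, function(s)
      names(which(gene_counts(cm[, s], catalog) >= min_count))))
  })
  names(det_tx) <- names(det_gene) <- groups
  out <- list(shared_transcripts = sort(intersect(det_tx[[1L]], det_tx[[2L]])))
  for (i in 1:2) {
    g <- groups[i]; other <- groups[3L - i]
    tx <- sort(setdiff(det_tx[[g]], det_tx[[other]]))
    gn <- sort(setdiff(det_gene[[g]], det_gene[[other]]))
    out[[g]] <- list(transcripts = tx, genes = gn,
                     n_transcripts = length(tx), n_genes = length(gn))
  }
  out
}

#' Flag RNA-degradation-machinery genes across samples
#'
#' Screens per-sample detected gene sets for a configurable list of
#' degradation-machinery gene symbols; a trailing `*` matches by prefix
#' (e.g. `"LSM*"` matches the whole LSM family).
#'
#' @inheritParams intrinsic_genes
#' @param genes Gene symbols/patterns; default covers the endoribonuclease
#'   SMG5, the deadenylases PARN and CNOT1, and the LSM assembly factors.
#' @return data.frame gene x sample of detection flags (long format:
#'   pattern, gene, sample_id, detected).
#' @export
flag_degradation_machinery <- function(cm, sample_groups, catalog,
                                       genes = c("SMG5", "PARN", "CNOT1",
                                                 "LSM*"),
                                       min_count = 1) {
  if (length(genes) == 0L) {
    return(data.frame(pattern = character(0), gene = character(0),
                      sample_id = character(0), detected = logical(0)))
  }
  all_genes <- unique(catalog$info$gene_id)
  matched <- lapply(genes, function(p) {
    if (grepl("\\*$", p)) {
      hits <- all_genes[startsWith(all_genes, sub("\\*$", "", p))]
    } else {
      hits <- intersect(p, all_genes)
    }
    if (length(hits) == 0L) hits <- p  # keep the row, will be undetected
    hits
  })
  rows <- list()
  for (i in seq_along(genes)) {
    for (g in matched[[i]]) {
      for (s in colnames(cm)) {
        det <- g %in% names(which(gene_counts(cm[, s], catalog) >= min_count))
        rows[[length(rows) + 1L]] <-
          data.frame(pattern = genes[i], gene = g, sample_id = s,
                     detected = det)
      }
    }
  }
  do.call(rbind, rows)
}
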