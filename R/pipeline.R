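# Pipeline configuration and end-to-end orchestration: from annotation +
# per-sample transcript-space alignments to the full report bundle.

#' Build and validate a pipeline configuration
#'
#' Validation happens here, before any compute: referenced files must
#' exist and thresholds must be in range. The configuration round-trips
#' losslessly through YAML ([write_pipeline_config()] /
#' [load_pipeline_config()]).
#'
#' @param annotation GTF annotation path.
#' @param sample_sheet TSV with columns `sample_id`, `group` (Exo/MV) and
#'   `alignment` (path, relative to the sheet's directory or absolute).
#' @param out_dir Output directory for the report bundle.
#' @param fasta Optional transcript FASTA (length cross-check).
#' @param min_mean_quality QC threshold on mean read quality (default 7;
#'   applies only when FASTQ records are provided).
#' @param intact_threshold Intact coverage threshold (default 0.9,
#'   strict `>`).
#' @param end_tolerance_fraction,end_tolerance_min Degradation end
#'   tolerance (defaults 0.10 / 20 nt).
#' @param abundance_mode `"em"` or `"primary_only"`.
#' @param correlation_transform `"log1p10"` or `"none"`.
#' @param top_n Top-transcript count for the restricted correlation
#'   (default 100).
#' @param min_count Detection threshold for presence/absence (default 1).
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return A validated list of class `ev_pipeline_config`.
#' @export
pipeline_config <- function(annotation, sample_sheet, out_dir,
                            fasta = NULL,
                            min_mean_quality = 7,
                            intact_threshold = 0.9,
                            end_tolerance_fraction = 0.10,
                            end_tolerance_min = 20,
                            abundance_mode = c("em", "primary_only"),
                            correlation_transform = c("log1p10", "none"),
                            top_n = 100L,
                            min_count = 1,
                            seed = 1L) {
  abundance_mode <- match.arg(abundance_mode)
  correlation_transform <- match.arg(correlation_transform)
  if (!file.exists(annotation)) {
    stop("config error: annotation not found: ", annotation)
  }
  if (!file.exists(sample_sheet)) {
    stop("config error: sample sheet not found: ", sample_sheet)
  }
  if (!is.null(fasta) && !file.exists(fasta)) {
    stop("config error: fasta not found: ", fasta)
  }
  stopifnot(intact_threshold > 0, intact_threshold < 1,
            end_tolerance_fraction > 0, end_tolerance_min >= 0,
            min_mean_quality >= 0)
  cfg <- list(annotation = annotation, sample_sheet = sample_sheet,
              out_dir = out_dir, fasta = fasta,
              min_mean_quality = min_mean_quality,
              intact_threshold = intact_threshold,
              end_tolerance_fraction = end_tolerance_fraction,
              end_tolerance_min = end_tolerance_min,
              abundance_mode = abundance_mode,
              correlation_transform = correlation_transform,
              top_n = as.integer(top_n), min_count = min_count,
              seed = as.integer(seed))
  class(cfg) <- "ev_pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg An `ev_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1L))])
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full EV long-read analysis pipeline
#'
#' Orchestrates every stage on per-sample transcript-space alignments:
#' primary-alignment selection, (EM) read-to-transcript assignment,
#' read summaries, biotype composition, sample correlation, intrinsic and
#' group-specific gene sets, degradation-machinery screen, integrity and
#' degradation-direction classification, and the group statistics. Writes
#' the report bundle to `cfg$out_dir`; every report file carries a
#' fingerprint of the configuration, so reruns on identical inputs are
#' byte-identical.
#'
#' Report bundle: `read_summary.tsv`, `biotype_composition.tsv`,
#' `correlation_matrix.tsv`, `gene_sets.json`, `integrity_summary.json`,
#' `degradation_summary.json`, `coverage_histogram.tsv`; plus the larger
#' per-read `integrity_calls.tsv` / `degradation_calls.tsv` and
#' `counts.tsv`.
#'
#' @param cfg An [pipeline_config()] object.
#' @return Invisible list of all computed results (class `ev_report`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "ev_pipeline_config"))
  # fingerprint covers the analysis parameters, not filesystem paths, so
  # identical analyses of the same data hash identically anywhere
  hash <- config_fingerprint(unclass(cfg)[setdiff(
    names(cfg), c("annotation", "sample_sheet", "out_dir", "fasta"))])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  catalog <- run_stage("annotation",
                       read_transcript_catalog(cfg$annotation, cfg$fasta))
  sheet <- run_stage("sample_sheet", {
    s <- read.delim(cfg$sample_sheet, header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
    stopifnot(all(c("sample_id", "group", "alignment") %in% names(s)))
    s$alignment <- ifelse(file.exists(s$alignment), s$alignment,
                          file.path(dirname(cfg$sample_sheet), s$alignment))
    missing <- !file.exists(s$alignment)
    if (any(missing)) stop("alignment file(s) not found: ",
                           paste(s$alignment[missing], collapse = ", "))
    s
  })

  counts_list <- list()
  summaries <- list()
  int_calls <- list()
  dir_calls <- list()
  lens_by_sample <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    aln <- run_stage(paste0("parse_alignments:", sid),
                     parse_alignments(sheet$alignment[i], catalog = catalog))
    if (nrow(aln) == 0L) stop("stage 'parse_alignments:", sid,
                              "' failed: empty alignment set", call. = FALSE)
    prim <- select_primary(aln)
    counts_list[[sid]] <- em_assign(aln, mode = cfg$abundance_mode)$counts
    lens <- vapply(prim$blocks, function(b)
      blocks_union_width(parse_blocks(b)), numeric(1L), USE.NAMES = FALSE)
    lens_by_sample[[sid]] <- lens
    summaries[[sid]] <- cbind(sample_id = sid, group = sheet$group[i],
                              summarize_reads(lens))
    ic <- integrity_calls(prim, cfg$intact_threshold)
    ic$sample_id <- sid
    int_calls[[sid]] <- ic
    frag <- prim[ic$label == "fragmented", , drop = FALSE]
    dc <- classify_direction(frag, cfg$end_tolerance_fraction,
                             cfg$end_tolerance_min, cfg$intact_threshold)
    if (nrow(dc) > 0L) dc$sample_id <- sid
    dir_calls[[sid]] <- dc
  }

  res <- run_stage("aggregate", {
    cm <- count_matrix(counts_list, catalog)
    comp <- do.call(rbind, lapply(names(counts_list), function(s)
      cbind(sample_id = s, biotype_composition(counts_list[[s]], catalog))))
    corr <- correlation_matrix(cm, transform = cfg$correlation_transform)
    corr_top <- correlation_matrix(cm, top_n = cfg$top_n,
                                   transform = cfg$correlation_transform)
    intr <- intrinsic_genes(cm, sheet, catalog, cfg$min_count)
    uniq <- group_specific_sets(cm, sheet, catalog, cfg$min_count)
    mach <- flag_degradation_machinery(cm, sheet, catalog,
                                       min_count = cfg$min_count)
    ic_all <- do.call(rbind, int_calls)
    integ <- intact_proportion_comparison(ic_all, sheet,
                                          intact_threshold =
                                            cfg$intact_threshold)
    dc_all <- do.call(rbind, dir_calls)
    dir_per_sample <- lapply(split(dc_all, dc_all$sample_id),
                             direction_proportions)
    dir_overall <- direction_proportions(dc_all)
    hist_tab <- coverage_by_direction(dc_all)

    # group mean expression concordance (total and top-n transcripts)
    grp <- sheet$group[match(colnames(cm), sheet$sample_id)]
    concord <- NULL
    if (length(unique(grp)) == 2L) {
      lx <- log10(cm + 1)
      m1 <- rowMeans(lx[, grp == unique(grp)[1L], drop = FALSE])
      m2 <- rowMeans(lx[, grp == unique(grp)[2L], drop = FALSE])
      top <- order(rowMeans(cm), decreasing = TRUE)[
        seq_len(min(cfg$top_n, nrow(cm)))]
      concord <- list(total = pearson_r(m1, m2),
                      top_n = pearson_r(m1[top], m2[top]))
    }
    # two-way ANOVA on binned read-length proportions
    anova_res <- NULL
    if (length(unique(sheet$group)) == 2L &&
        all(table(sheet$group) >= 2L)) {
      bins <- do.call(rbind, lapply(sheet$sample_id, function(s)
        cbind(sample_id = s,
              group = sheet$group[sheet$sample_id == s],
              bin_length_proportions(lens_by_sample[[s]]))))
      anova_res <- two_way_anova_lengths(bins)
    }
    list(catalog = catalog, sample_sheet = sheet, counts = cm,
         read_summary = do.call(rbind, summaries), composition = comp,
         correlation = corr, correlation_top = corr_top,
         intrinsic = intr, group_specific = uniq, machinery = mach,
         integrity = integ, integrity_calls = ic_all,
         direction_calls = dc_all,
         direction = list(per_sample = dir_per_sample,
                          overall = dir_overall),
         coverage_histogram = hist_tab,
         concordance = concord, length_anova = anova_res,
         config = cfg, config_hash = hash)
  })

  run_stage("report", write_report_bundle(res))
  class(res) <- "ev_report"
  invisible(res)
}

test_result_json <- function(t) {
  if (is.null(t)) return(NULL)
  list(statistic = t$statistic, df = t$df, p_value = t$p_value,
       method = t$method)
}

write_report_bundle <- function(res) {
  out <- res$config$out_dir
  hash <- res$config_hash
  rs <- res$read_summary
  rownames(rs) <- NULL
  write_report_tsv(rs, file.path(out, "read_summary.tsv"), hash)
  write_report_tsv(res$composition,
                   file.path(out, "biotype_composition.tsv"), hash)
  cor_df <- data.frame(sample_id = rownames(res$correlation),
                       res$correlation, check.names = FALSE)
  write_report_tsv(cor_df, file.path(out, "correlation_matrix.tsv"), hash)

  cnt <- data.frame(transcript_id = rownames(res$counts), res$counts,
                    check.names = FALSE)
  write_report_tsv(cnt, file.path(out, "counts.tsv"), hash)

  gs <- list(
    config_hash = hash,
    intrinsic = list(n_intrinsic = res$intrinsic$n_intrinsic,
                     n_union = res$intrinsic$n_union,
                     proportion = res$intrinsic$proportion,
                     denominator = res$intrinsic$denominator,
                     table = res$intrinsic$table,
                     chi_square = test_result_json(res$intrinsic$test)),
    group_specific = lapply(
      res$group_specific[setdiff(names(res$group_specific),
                                 "shared_transcripts")],
      function(g) list(n_transcripts = g$n_transcripts,
                       n_genes = g$n_genes)),
    n_shared_transcripts = length(res$group_specific$shared_transcripts),
    machinery_detected = res$machinery[res$machinery$detected,
                                       c("gene", "sample_id")]
  )
  write_report_json(gs, file.path(out, "gene_sets.json"))

  write_report_tsv(res$integrity_calls,
                   file.path(out, "integrity_calls.tsv"), hash)
  isum <- list(
    config_hash = hash,
    intact_threshold = res$config$intact_threshold,
    unit = res$integrity$unit,
    per_sample = res$integrity$per_sample,
    per_group = lapply(split(res$integrity$per_sample,
                             res$integrity$per_sample$group), function(d)
      list(n_samples = nrow(d),
           mean_intact_proportion = mean(d$intact_proportion))),
    overall = list(
      n_reads = sum(res$integrity$per_sample$n),
      intact_proportion = sum(res$integrity$per_sample$n_intact) /
        sum(res$integrity$per_sample$n)),
    welch_t = test_result_json(res$integrity$test)
  )
  write_report_json(isum, file.path(out, "integrity_summary.json"))

  write_report_tsv(res$direction_calls,
                   file.path(out, "degradation_calls.tsv"), hash)
  dsum <- list(
    config_hash = hash,
    end_tolerance_fraction = res$config$end_tolerance_fraction,
    end_tolerance_min = res$config$end_tolerance_min,
    per_sample = lapply(res$direction$per_sample, function(d)
      list(proportions = as.list(d$proportions), n = d$n,
           n_ambiguous = d$n_ambiguous)),
    overall = list(proportions = as.list(res$direction$overall$proportions),
                   n = res$direction$overall$n,
                   n_ambiguous = res$direction$overall$n_ambiguous)
  )
  write_report_json(dsum, file.path(out, "degradation_summary.json"))

  write_report_tsv(res$coverage_histogram,
                   file.path(out, "coverage_histogram.tsv"), hash)

  stats_block <- list(
    config_hash = hash,
    intact_welch_t = test_result_json(res$integrity$test),
    intrinsic_chi_square = test_result_json(res$intrinsic$test),
    length_anova = test_result_json(res$length_anova),
    concordance = res$concordance
  )
  write_report_json(stats_block, file.path(out, "stats.json"))
  invisible(out)
}
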