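# Independent oracles, deliberately implemented with a different strategy
# than the package code they check.

# Per-base bitmap coverage: mark every covered base, count the marks.
oracle_coverage_bitmap <- function(blocks, t_len) {
  hit <- logical(t_len)
  for (i in seq_len(nrow(blocks))) {
    hit[(blocks[i, 1L] + 1L):blocks[i, 2L]] <- TRUE
  }
  sum(hit) / t_len
}

# Brute-force N50: largest observed L whose >=L suffix holds strictly more
# than half of all bases.
oracle_n50 <- function(lengths) {
  total <- sum(as.numeric(lengths))
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(as.numeric(lengths[lengths >= L])) > total / 2) return(L)
  }
  stop("unreachable")
}

# Reference EM: naive per-read loops, fixed-point iteration at high
# precision.
oracle_em <- function(cand, tol = 1e-12, max_iter = 5000L) {
  reads <- split(cand$transcript_id, cand$read_id)
  tx <- sort(unique(cand$transcript_id))
  abund <- setNames(rep(1 / length(tx), length(tx)), tx)
  for (it in seq_len(max_iter)) {
    counts <- setNames(rep(0, length(tx)), tx)
    for (r in reads) {
      w <- abund[r]
      counts[r] <- counts[r] + w / sum(w)
    }
    new_abund <- counts / length(reads)
    if (max(abs(new_abund - abund)) < tol) {
      abund <- new_abund
      break
    }
    abund <- new_abund
  }
  abund * length(reads)
}

# Closed-form Welch t.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Hand sum((O-E)^2/E) for a 2x2 table.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Direct product-moment formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Sum-of-squares decomposition for a BALANCED two-way design without
# interaction (every sample contributes every bin exactly once).
oracle_anova_group <- function(data) {
  y <- data$proportion
  g <- factor(data$group)
  b <- factor(data$bin)
  grand <- mean(y)
  ss_g <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_b <- sum(tapply(y, b, function(v) length(v) * (mean(v) - grand)^2))
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_g - ss_b
  df_g <- nlevels(g) - 1L
  df_b <- nlevels(b) - 1L
  df_res <- length(y) - 1L - df_g - df_b
  f <- (ss_g / df_g) / (ss_res / df_res)
  list(f = f, df = c(df_g, df_res),
       p = pf(f, df_g, df_res, lower.tail = FALSE))
}

# Map a transcript-space interval back to genomic intervals via an explicit
# per-base coordinate map (used for round-trip checks of
# genome_to_transcript).
oracle_base_map <- function(model) {
  g <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
    model$exons$start[i]:(model$exons$end[i] - 1L)))
  if (model$strand == "-") g <- rev(g)
  g  # g[p + 1] = genomic coordinate of transcript position p
}
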