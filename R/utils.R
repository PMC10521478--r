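# Internal helpers shared across modules. All coordinates are 0-based,
# half-open; blocks serialize as "start-end;start-end".

#' @importFrom stats median rbinom rlnorm rnorm rpois runif sd setNames
#' @importFrom utils read.delim write.table
NULL

# Parse a block string into an integer matrix with columns start, end.
parse_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  if (any(is.na(m)) || any(m[, 2L] <= m[, 1L])) {
    stop("malformed block string: ", s)
  }
  m[order(m[, 1L]), , drop = FALSE]
}

format_blocks <- function(m) {
  paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ";")
}

# Merge overlapping/adjacent-within-gap intervals; gap = 0 merges only
# overlapping or touching blocks.
merge_blocks <- function(m, gap = 0L) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out_s <- m[1L, 1L]; out_e <- m[1L, 2L]
  res <- vector("list", nrow(m))
  k <- 0L
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] <= out_e + gap) {
      out_e <- max(out_e, m[i, 2L])
    } else {
      k <- k + 1L; res[[k]] <- c(out_s, out_e)
      out_s <- m[i, 1L]; out_e <- m[i, 2L]
    }
  }
  k <- k + 1L; res[[k]] <- c(out_s, out_e)
  matrix(unlist(res[seq_len(k)]), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

# Total number of distinct covered bases.
blocks_union_width <- function(m) {
  u <- merge_blocks(m)
  sum(u[, 2L] - u[, 1L])
}

# Derive a child seed from a master seed and a stream index so that each
# sample gets an independent, reproducible RNG stream (< 2^31).
derive_seed <- function(seed, stream) {
  ((as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 1009 + 7) %%
    2147483647
}

# Short stable fingerprint of a configuration list (polynomial hash of its
# canonical JSON serialization), used to stamp report files.
config_fingerprint <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10,
                                     null = "null", force = TRUE))
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Stable numeric formatting for TSV report files (byte-identical reruns).
fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.6g", x)))
}

write_report_tsv <- function(df, path, hash = NULL) {
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash=", hash), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

write_report_json <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(
    x, auto_unbox = TRUE, digits = 10, pretty = TRUE, null = "null",
    na = "null", force = TRUE)), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
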