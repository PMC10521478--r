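# The four statistical procedures the pipeline reports, with a common
# result container. These delegate to the standard base-R tests and are
# validated against closed-form oracles in the test suite.

test_result <- function(statistic, df, p_value, method) {
  stopifnot(!is.nan(statistic))  # +/-Inf allowed as a degenerate limit
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method),
            class = "ev_test_result")
}

#' @export
print.ev_test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 6),
      ", df = ", paste(format(x$df, digits = 6), collapse = "/"),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Unpaired t-test (Welch by default)
#'
#' Welch's t-statistic `(mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)` with
#' Welch-Satterthwaite degrees of freedom; a pooled-variance Student test
#' is available via `pooled = TRUE`. Two identical constant samples give
#' t = 0, p = 1; constant samples with different means give the limiting
#' p = 0.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param two_sided Two-sided p-value (default); otherwise the one-sided
#'   upper-tail p for `mean(x) > mean(y)`.
#' @param pooled Use the pooled-variance Student t instead of Welch.
#' @return An `ev_test_result` (statistic, df, p_value, method).
#' @export
welch_t <- function(x, y, two_sided = TRUE, pooled = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  eps <- .Machine$double.eps
  if (sd(x) < eps && sd(y) < eps) {
    method <- if (pooled) "Student t" else "Welch t"
    if (abs(mean(x) - mean(y)) < eps) {
      return(test_result(0, length(x) + length(y) - 2L, 1, method))
    }
    return(test_result(sign(mean(x) - mean(y)) * Inf,
                       length(x) + length(y) - 2L, 0, method))
  }
  alt <- if (two_sided) "two.sided" else "greater"
  r <- stats::t.test(x, y, alternative = alt, var.equal = pooled)
  test_result(r$statistic, r$parameter, r$p.value,
              if (pooled) "Student t" else "Welch t")
}

#' Chi-square test on a 2x2 contingency table
#'
#' Plain `sum((O - E)^2 / E)` with df = 1 and no continuity correction by
#' default; Yates' correction is available by flag. Zero marginals are an
#' error.
#'
#' @param tab 2x2 numeric matrix/table of counts.
#' @param yates Apply Yates' continuity correction (default FALSE).
#' @return An `ev_test_result`.
#' @export
chi_square_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, ncol(tab) == 2L, all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  r <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  test_result(r$statistic, r$parameter, r$p.value,
              if (yates) "chi-square (Yates)" else "chi-square")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return list with `r`, `p_value`, `n` and `method`; `r` is NA with a
#'   note when either input has zero variance (undefined, not 0).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                method = "Pearson", note = "zero variance: r undefined"))
  }
  r <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(r$estimate), p_value = r$p.value, n = length(x),
       method = "Pearson")
}

#' Bin read lengths into fixed-width proportion bins
#'
#' Fixed 200-nt bins `[0,200), ..., [1800,2000)` plus a `>=2000` overflow
#' bin; proportions sum to 1 per sample.
#'
#' @param lengths Read lengths for one sample.
#' @param bin_width Bin width in nt (default 200).
#' @param max_length Start of the overflow bin (default 2000).
#' @return data.frame: bin (ordered factor), proportion.
#' @export
bin_length_proportions <- function(lengths, bin_width = 200,
                                   max_length = 2000) {
  breaks <- seq(0, max_length, by = bin_width)
  labs <- c(sprintf("[%d,%d)", breaks[-length(breaks)], breaks[-1L]),
            sprintf(">=%d", max_length))
  b <- cut(pmin(lengths, max_length), breaks = c(breaks, Inf),
           right = FALSE, labels = labs)
  tab <- table(b)
  data.frame(bin = factor(labs, levels = labs),
             proportion = as.numeric(tab) / length(lengths))
}

#' Two-way ANOVA on binned read-length proportions
#'
#' Fixed-effects two-way ANOVA without interaction,
#' `proportion ~ group + bin`, over per-sample binned length proportions;
#' reports the group main effect. This is the length-distribution
#' comparison between EV subtypes (does the read-length profile differ by
#' group once bin-to-bin structure is accounted for).
#'
#' @param data data.frame with columns `sample_id`, `group`, `bin`,
#'   `proportion`; >= 2 groups, >= 2 bins, >= 2 samples per group, and
#'   every group x bin cell populated.
#' @return An `ev_test_result` for the group effect; `df` is
#'   `c(df_group, df_residual)`.
#' @export
two_way_anova_lengths <- function(data) {
  stopifnot(all(c("sample_id", "group", "bin", "proportion") %in%
                  names(data)))
  data$group <- factor(data$group)
  data$bin <- factor(data$bin)
  if (nlevels(data$group) < 2L) stop("need >= 2 groups")
  if (nlevels(data$bin) < 2L) stop("need >= 2 length bins")
  reps <- tapply(data$sample_id, data$group,
                 function(s) length(unique(s)))
  if (any(reps < 2L)) stop("need >= 2 replicate samples per group")
  cells <- table(data$group, data$bin)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: group ", rownames(cells)[empty[1L]],
         " x bin ", colnames(cells)[empty[2L]])
  }
  fit <- stats::aov(proportion ~ group + bin, data = data)
  s <- summary(fit)[[1L]]
  rn <- trimws(rownames(s))
  i <- rn == "group"; res <- rn == "Residuals"
  test_result(s[i, "F value"], c(s[i, "Df"], s[res, "Df"]),
              s[i, "Pr(>F)"], "two-way ANOVA (group effect)")
}
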