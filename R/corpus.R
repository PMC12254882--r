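# Corpus-level statistics: descriptive summaries of completeness scores,
# the paired fields-only vs with-notes comparison (Wilcoxon signed rank),
# and the two-route well-documented proportion comparison.

#' Summarize a set of completeness scores
#'
#' Descriptive statistics over final completeness scores: minimum, maximum,
#' mean, median (midpoint convention for even n), interquartile range
#' (type-7 linear-interpolation quantiles), and the count and proportion of
#' well-documented reports (score of 0.8 or higher).
#'
#' @param scores Numeric vector of final scores in (0, 1]; must be
#'   non-empty.
#' @return An object of class `corpus_summary` with fields `n`, `min`,
#'   `max`, `mean`, `median`, `iqr`, `n_well_documented`,
#'   `proportion_well_documented`.
#' @export
summarize_scores <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0 || any(is.na(scores))) {
    stop("'scores' must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  if (any(scores <= 0 | scores > 1)) {
    stop("scores must lie in (0, 1]", call. = FALSE)
  }
  q <- quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  nwd <- sum(scores >= WELL_DOCUMENTED_THRESHOLD)
  structure(list(
    n = length(scores),
    min = min(scores),
    max = max(scores),
    mean = mean(scores),
    median = median(scores),
    iqr = q[2] - q[1],
    n_well_documented = nwd,
    proportion_well_documented = nwd / length(scores)
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf(
    "<corpus_summary> n=%d min=%.2f max=%.2f mean=%.2f median=%.2f iqr=%.2f well-documented %d/%d (%.1f%%)\n",
    x$n, x$min, x$max, x$mean, x$median, x$iqr, x$n_well_documented, x$n,
    100 * x$proportion_well_documented))
  invisible(x)
}

new_comparison <- function(method, statistic, p_value, detail = "") {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, detail = detail),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic=%s p=%.4g%s\n", x$method,
              if (is.null(x$statistic) || is.na(x$statistic)) "NA"
              else format(x$statistic, digits = 4),
              x$p_value,
              if (nzchar(x$detail)) paste0(" [", x$detail, "]") else ""))
  invisible(x)
}

# exact null distribution of the signed-rank statistic W+ (sum of ranks of
# positive differences) by dynamic programming over doubled ranks, which
# stays exact under tied (average, half-integer) ranks where the classical
# psignrank distribution does not apply
signed_rank_exact_p <- function(ranks, w_obs) {
  dr <- as.integer(round(2 * ranks))
  total <- sum(dr)
  f <- numeric(total + 1)
  f[1] <- 1
  for (d in dr) {
    shifted <- c(numeric(d), f[seq_len(total + 1 - d)])
    f <- f + shifted
  }
  f <- f / sum(f)
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[seq.int(w2 + 1, total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired comparison of two score sets (Wilcoxon signed rank)
#'
#' Compares index-aligned final scores from two assessments of the same
#' reports — typically fields-only vs with-notes. Zero differences are
#' dropped before ranking (the classic signed-rank treatment). The exact
#' null distribution is used when the number of nonzero differences is at
#' most 25, computed by dynamic programming so that tied (average) ranks —
#' the norm on the penalty lattice — remain exact; larger samples use the
#' normal approximation with tie correction. Two-sided p is twice the
#' smaller tail, capped at 1.
#'
#' @param fields_only,with_notes Equal-length numeric vectors of final
#'   scores, aligned by report.
#' @return A `comparison_result` with method `WILCOXON_SIGNED_RANK`,
#'   statistic `W+` (sum of positive-difference ranks), `p_value`, and a
#'   `detail` string recording zero-difference handling and the routine
#'   used.
#' @export
paired_score_test <- function(fields_only, with_notes) {
  fields_only <- as.numeric(fields_only)
  with_notes <- as.numeric(with_notes)
  if (length(fields_only) != length(with_notes) || length(fields_only) < 1) {
    stop("score vectors must be index-aligned and non-empty", call. = FALSE)
  }
  d <- with_notes - fields_only
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_comparison("WILCOXON_SIGNED_RANK", statistic = 0,
                          p_value = 1,
                          detail = "degenerate: no nonzero differences"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    p <- signed_rank_exact_p(r, w)
    detail <- sprintf("exact (dp over tied ranks); %d zero difference(s) dropped",
                      n_zero)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    detail <- sprintf(
      "normal approximation with tie correction; %d zero difference(s) dropped",
      n_zero)
  }
  new_comparison("WILCOXON_SIGNED_RANK", statistic = w, p_value = p,
                 detail = detail)
}

#' Compare well-documented proportions between two report routes
#'
#' Builds the 2x2 table of well-documented vs not for two groups (e.g.
#' practice-system reports vs standard-route submissions) and tests for a
#' difference in proportions. Fisher's exact test (two-sided,
#' hypergeometric-tail definition) is used when any cell is below 5 —
#' by default judged on the observed counts, optionally on the
#' conventional expected counts — and the chi-squared test otherwise,
#' without Yates continuity correction unless requested.
#'
#' @param k1,n1 Well-documented count and total for group 1.
#' @param k2,n2 Well-documented count and total for group 2.
#' @param correction Apply Yates continuity correction to the chi-squared
#'   test (default `FALSE`).
#' @param rule `"observed"` (default): Fisher when any observed cell < 5;
#'   `"expected"`: Fisher when any expected cell < 5.
#' @return A `comparison_result` with method `FISHER_EXACT`,
#'   `CHI_SQUARED` or `CHI_SQUARED_YATES`.
#' @export
#' @examples
#' proportion_test(43, 45, 19, 45)   # Fisher (a cell below 5), p << 0.001
proportion_test <- function(k1, n1, k2, n2, correction = FALSE,
                            rule = c("observed", "expected")) {
  rule <- match.arg(rule)
  counts <- c(k1 = k1, n1 = n1, k2 = k2, n2 = n2)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)) || k1 > n1 || k2 > n2 ||
      n1 < 1 || n2 < 1) {
    stop("impossible counts: need 0 <= k <= n and n >= 1 in both groups",
         call. = FALSE)
  }
  m <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  use_fisher <- if (rule == "observed") any(m < 5) else any(expected < 5)
  if (use_fisher) {
    p <- fisher.test(m)$p.value
    return(new_comparison("FISHER_EXACT", statistic = NA_real_, p_value = p,
                          detail = sprintf("cell below 5 (%s rule)", rule)))
  }
  ct <- suppressWarnings(chisq.test(m, correct = correction))
  new_comparison(if (correction) "CHI_SQUARED_YATES" else "CHI_SQUARED",
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value,
                 detail = sprintf("all cells >= 5 (%s rule)", rule))
}
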