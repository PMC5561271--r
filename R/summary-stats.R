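#' One-sample t statistic from summary data
#'
#' `t = mean / (sd / sqrt(n))`, df = n - 1: the test applied to
#' regulation-minus-viewing rating differences against zero.
#'
#' @param mean sample mean of the differences.
#' @param sd sample standard deviation (> 0).
#' @param n sample size (>= 2).
#' @return A list with `t`, `df` and the two-tailed `p`.
#' @export
one_sample_t <- function(mean, sd, n) {
  stopifnot(sd > 0, n >= 2)
  t <- mean / (sd / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA from group summaries
#'
#' Computes the between-group F from `(n, mean, sd)` per group:
#' `SSB = sum n_i (m_i - m)^2` with `m` the n-weighted grand mean,
#' `MSW = sum (n_i - 1) s_i^2 / (N - k)`, `F = (SSB/(k-1)) / MSW`,
#' df = (k - 1, N - k). Equivalent to the ANOVA on any raw data with these
#' exact summaries.
#'
#' @param n,mean,sd numeric vectors, one entry per group (all `n >= 2`).
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
oneway_anova_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd),
            length(n) >= 2, all(n >= 2), all(sd >= 0))
  N <- sum(n); k <- length(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  msw <- sum((n - 1) * sd^2) / (N - k)
  if (msw == 0 && ssb == 0) stop("all groups constant and equal; F undefined")
  F <- if (msw == 0) Inf else (ssb / (k - 1)) / msw
  list(F = F, df1 = k - 1, df2 = N - k,
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-square for a 2x2 table
#'
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1, without Yates
#' continuity correction (the convention that reproduces classic
#' crosstab statistics computed from group percentages).
#'
#' @param a,b,c,d cell counts (row = group, column = outcome), or `a` may be
#'   a 2x2 matrix.
#' @return A list with `chisq`, `df`, `p`.
#' @export
chisq_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  N <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("chi-square undefined: a margin is zero")
  chisq <- N * (a * d - b * c)^2 / prod(margins)
  list(chisq = chisq, df = 1,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Compute a statistics table from a YAML summary file
#'
#' Reads a YAML file with two optional sections — `anova`, a list of named
#' entries each holding parallel vectors `n`, `mean`, `sd`; and `chisq`, a
#' list of named entries each holding counts `a`, `b`, `c`, `d` — and
#' returns one row per test. The package ships an example file for a
#' three-group clinical cohort in
#' `system.file("extdata", "cohort_table.yaml", package = "seedfc")`.
#'
#' @param path YAML file path.
#' @return data.frame with columns name, test, statistic, df1, df2, p.
#' @export
summary_table <- function(path) {
  spec <- yaml::read_yaml(path)
  rows <- list()
  for (nm in names(spec$anova)) {
    e <- spec$anova[[nm]]
    res <- oneway_anova_summary(e$n, e$mean, e$sd)
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, test = "oneway_anova", statistic = res$F,
      df1 = res$df1, df2 = res$df2, p = res$p)
  }
  for (nm in names(spec$chisq)) {
    e <- spec$chisq[[nm]]
    res <- chisq_2x2(e$a, e$b, e$c, e$d)
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, test = "chisq_2x2", statistic = res$chisq,
      df1 = 1, df2 = NA, p = res$p)
  }
  for (nm in names(spec$one_sample_t)) {
    e <- spec$one_sample_t[[nm]]
    res <- one_sample_t(e$mean, e$sd, e$n)
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, test = "one_sample_t", statistic = res$t,
      df1 = res$df, df2 = NA, p = res$p)
  }
  do.call(rbind, rows)
}
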