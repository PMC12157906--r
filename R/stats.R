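#' @include AllClasses.R
NULL

asScoreMatrix <- function(table) {
  v <- if (is(table, "MethodScoreTable")) scoreMatrix(table) else
    as.matrix(table)
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("need at least 2 users (rows) and 2 methods (columns)")
  v
}

#' Friedman rank test over a users x methods table
#'
#' Within-user ranks (average ranks on ties) feed the chi-square-form
#' Friedman statistic with the standard tie correction; the p-value comes
#' from the chi-square distribution with k-1 degrees of freedom. The
#' Iman-Davenport F transformation is reported alongside.
#'
#' @param table a [MethodScoreTable-class] or numeric matrix (users in
#'   rows, methods in columns).
#' @return list with `statistic` (tie-corrected chi-square), `p`, `df`,
#'   `mean_ranks`, and the Iman-Davenport variant `iman_davenport`
#'   (`statistic`, `p`, `df1`, `df2`).
#' @examples
#' friedmanStatistic(matrix(c(1, 2, 3, 1, 2, 3), 2, byrow = TRUE,
#'                          dimnames = list(c("u1", "u2"), c("a", "b", "c"))))
#' @export
friedmanStatistic <- function(table) {
  v <- asScoreMatrix(table)
  n <- nrow(v)
  k <- ncol(v)
  R <- t(apply(v, 1L, rank))
  Rj <- colSums(R)
  raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(v, 1L, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  })
  corr <- 1 - sum(ties) / (n * (k^3 - k))
  stat <- if (corr > 0) raw / corr else raw
  df1 <- k - 1
  id_stat <- if (n * df1 - stat > 0) (n - 1) * stat / (n * df1 - stat)
             else Inf
  list(statistic = stat,
       p = pchisq(stat, df = df1, lower.tail = FALSE),
       df = df1,
       mean_ranks = colMeans(R),
       iman_davenport = list(
         statistic = id_stat,
         p = pf(id_stat, df1, (n - 1) * df1, lower.tail = FALSE),
         df1 = df1, df2 = (n - 1) * df1))
}

#' Nemenyi all-pairs post hoc test
#'
#' Pairwise p-values for mean-rank differences after a Friedman test,
#' using the studentized-range distribution: for methods i and j,
#' `q = |R_i - R_j| / sqrt(k (k + 1) / (6 n))` is referred to the
#' studentized range with infinite degrees of freedom
#' (`p = 1 - ptukey(q * sqrt(2), k, Inf)`).
#'
#' @inheritParams friedmanStatistic
#' @return symmetric k x k matrix of p-values with unit diagonal.
#' @export
nemenyiPosthoc <- function(table) {
  v <- asScoreMatrix(table)
  n <- nrow(v)
  k <- ncol(v)
  Rbar <- colMeans(t(apply(v, 1L, rank)))
  q <- abs(outer(Rbar, Rbar, "-")) / sqrt(k * (k + 1) / (6 * n))
  p <- 1 - ptukey(q * sqrt(2), nmeans = k, df = Inf)
  diag(p) <- 1
  dimnames(p) <- list(colnames(v), colnames(v))
  p
}

#' Cliff's delta effect size
#'
#' `delta = (#(x_i > y_j) - #(x_i < y_j)) / (|x| |y|)` over all cross
#' pairs; positive values mean `x` tends to exceed `y`. Exact integer
#' counting, so `cliffsDelta(x, y) == -cliffsDelta(y, x)` holds exactly.
#'
#' @param x,y non-empty numeric vectors.
#' @return numeric(1) in [-1, 1].
#' @examples
#' cliffsDelta(2:4, 1:3)
#' @export
cliffsDelta <- function(x, y) {
  if (!length(x) || !length(y)) stop("inputs must be non-empty")
  sum(sign(outer(x, y, "-"))) / (length(x) * length(y))
}

#' Paired t and Wilcoxon signed-rank tests
#'
#' Two-sided paired comparisons of two score columns. The Wilcoxon test
#' drops zero differences, uses the exact signed-rank null distribution
#' when n <= 25 and the absolute differences are tie-free, and otherwise a
#' normal approximation with tie and continuity corrections. All-zero
#' differences give a degenerate p of 1 with a warning.
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return list with `t_p` and `wilcoxon_p`.
#' @export
pairedTests <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  d <- x - y
  if (all(d == 0)) {
    warning("all paired differences are zero; tests are degenerate")
    return(list(t_p = 1, wilcoxon_p = 1))
  }
  t_p <- t.test(x, y, paired = TRUE)$p.value
  dz <- d[d != 0]
  n <- length(dz)
  r <- rank(abs(dz))
  W <- sum(r[dz > 0])
  has_ties <- anyDuplicated(r) > 0L
  if (n <= 25L && !has_ties) {
    p_low <- psignrank(W, n)
    p_high <- psignrank(W - 1, n, lower.tail = FALSE)
    w_p <- min(1, 2 * min(p_low, p_high))
  } else {
    mu <- n * (n + 1) / 4
    tt <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48)
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sigma
    w_p <- 2 * pnorm(-abs(z))
  }
  list(t_p = t_p, wilcoxon_p = w_p)
}

#' Per-method mean and standard deviation
#'
#' @inheritParams friedmanStatistic
#' @return data.frame with one row per method: `mean`, `sd` (sample,
#'   n-1 denominator) and `sd_population` (n denominator).
#' @export
summarizeScores <- function(table) {
  v <- asScoreMatrix(table)
  n <- nrow(v)
  data.frame(method = colnames(v),
             mean = colMeans(v),
             sd = apply(v, 2L, sd),
             sd_population = apply(v, 2L, sd) * sqrt((n - 1) / n),
             row.names = NULL)
}

#' Full method-comparison report
#'
#' Convenience wrapper producing the summary, omnibus Friedman test,
#' Nemenyi post hoc matrix, and all pairwise Cliff's deltas and paired
#' tests for a users x methods table.
#'
#' @inheritParams friedmanStatistic
#' @return list with `summary`, `friedman`, `nemenyi`, and `pairwise`
#'   (data.frame of method pairs with `cliffs_delta`, `t_p`,
#'   `wilcoxon_p`).
#' @export
compareMethods <- function(table) {
  v <- asScoreMatrix(table)
  pairs <- utils::combn(colnames(v), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    pt <- suppressWarnings(pairedTests(v[, a], v[, b]))
    data.frame(method_a = a, method_b = b,
               cliffs_delta = cliffsDelta(v[, a], v[, b]),
               t_p = pt$t_p, wilcoxon_p = pt$wilcoxon_p)
  }))
  list(summary = summarizeScores(v), friedman = friedmanStatistic(v),
       nemenyi = nemenyiPosthoc(v), pairwise = pw)
}

#' Read / write a users x methods score table as CSV
#'
#' The CSV has a `user_id` column plus one numeric column per method.
#'
#' @param path CSV file path.
#' @return [MethodScoreTable-class].
#' @export
readScoreTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"user_id" %in% colnames(df)) stop("score table CSV needs a 'user_id' column")
  m <- as.matrix(df[, setdiff(colnames(df), "user_id"), drop = FALSE])
  rownames(m) <- as.character(df$user_id)
  methodScoreTable(m)
}

#' @param table a [MethodScoreTable-class].
#' @rdname readScoreTable
#' @export
writeScoreTable <- function(table, path) {
  v <- scoreMatrix(table)
  df <- data.frame(user_id = rownames(v), v, check.names = FALSE,
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled reference benchmark of per-user macro F1 scores
#'
#' The published per-user macro F1 results (in percent) of the five
#' compared selection strategies on the 19-subject running-fatigue
#' benchmark: the offline random-forest baseline (`ml`), uniform random
#' example selection (`random`), distance-only selection (`distance`), and
#' the hybrid selector under its two presets (`hedlm_paramA`,
#' `hedlm_paramB`). Used by the statistics examples, the test suite and
#' the acceptance script.
#'
#' @return a 19 x 5 [MethodScoreTable-class].
#' @examples
#' summarizeScores(fatigueBenchmarkScores())
#' @export
fatigueBenchmarkScores <- function() {
  readScoreTable(system.file("extdata", "fatigue_benchmark_macro_f1.csv",
                             package = "hedlm", mustWork = TRUE))
}
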