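#' @include AllClasses.R
NULL

#' Two-sample t test from summary statistics
#'
#' Pooled-variance (default) or Welch two-sample t test computed from group
#' means, SDs and sizes, as used for cohort description tables. The pooled
#' test on raw-data summaries equals the classic raw-data pooled t test
#' exactly.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @param pooled use the pooled-variance test (FALSE = Welch).
#' @return list: `t`, `df`, `p` (two-sided).
#' @examples
#' tTestSummary(28.2, 4.57, 35, 30, 4.3, 46)
#' @export
tTestSummary <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("SDs must be positive")
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    tval <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Pearson chi-square without continuity correction by default (the
#' convention that reproduces printed cohort-table p-values); Yates
#' correction available by flag.
#'
#' @param a,b first row (group 1: yes, no).
#' @param c,d second row (group 2: yes, no).
#' @param correction apply Yates continuity correction.
#' @return list: `chisq`, `df` (= 1), `p`.
#' @examples
#' chisq2x2(30, 16, 38, 7) # female counts, two patient groups
#' @export
chisq2x2 <- function(a, b, c, d, correction = FALSE) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(m < 0)) stop("cell counts must be nonnegative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  ct <- stats::chisq.test(m, correct = correction)
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Group comparison table for a cohort
#'
#' Convenience wrapper producing a descriptive comparison of two groups:
#' pooled t tests for numeric columns, 2 x 2 chi-square for two-level
#' categorical columns.
#'
#' @param cohort data.frame with a `group` column.
#' @param groups the two group labels to contrast.
#' @param columns columns to compare (default: all except identifiers).
#' @return data.frame: `variable`, `type`, per-group summary strings,
#'   `statistic`, `p`.
#' @export
cohortComparisonTable <- function(cohort, groups,
                                  columns = setdiff(colnames(cohort),
                                                    c("subject_id", "group"))) {
  cohort <- as.data.frame(cohort)
  rows <- list()
  for (v in columns) {
    x1 <- cohort[[v]][cohort$group == groups[1]]
    x2 <- cohort[[v]][cohort$group == groups[2]]
    if (is.numeric(x1)) {
      tt <- tTestSummary(mean(x1), stats::sd(x1), length(x1),
                         mean(x2), stats::sd(x2), length(x2))
      rows[[v]] <- data.frame(
        variable = v, type = "numeric",
        group1 = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
        group2 = sprintf("%.2f ± %.2f", mean(x2), stats::sd(x2)),
        statistic = tt$t, p = tt$p)
    } else {
      lev <- sort(unique(as.character(cohort[[v]])))
      if (length(lev) != 2L) next
      cs <- chisq2x2(sum(x1 == lev[1]), sum(x1 == lev[2]),
                     sum(x2 == lev[1]), sum(x2 == lev[2]))
      rows[[v]] <- data.frame(
        variable = v, type = "categorical",
        group1 = sprintf("%d/%d %s", sum(x1 == lev[1]), length(x1), lev[1]),
        group2 = sprintf("%d/%d %s", sum(x2 == lev[1]), length(x2), lev[1]),
        statistic = cs$chisq, p = cs$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
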