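#' Crude incidence rate as a percentage
#'
#' `100 * n_events / n_total`, reported to one decimal place, the
#' conventional crude (non-actuarial) complication rate.
#'
#' @param n_events number of events.
#' @param n_total denominator (> 0).
#' @return Percentage, rounded to one decimal.
#' @export
crude_rate <- function(n_events, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_events < 0 || n_events > n_total)
    stop("n_events must lie in [0, n_total]")
  round(100 * n_events / n_total, 1)
}

#' Compare categorical characteristics between groups
#'
#' Pearson chi-square test without continuity correction when all
#' expected cell counts are at least 5, otherwise Fisher's exact test
#' (two-sided). The method actually used is reported.
#'
#' @param tab contingency table (matrix of non-negative integer counts,
#'   2 x 2 or 2 x k).
#' @return List with `method` (`"pearson"` or `"fisher"`), `statistic`
#'   (chi-square, `NA` for Fisher), `p_value`, and `expected` counts.
#' @export
compare_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin: a row or column is all zero")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(tab, correct = FALSE)
    list(method = "pearson", statistic = unname(ct$statistic),
         p_value = ct$p.value, expected = expected)
  } else {
    ft <- stats::fisher.test(tab)
    list(method = "fisher", statistic = NA_real_, p_value = ft$p.value,
         expected = expected)
  }
}

#' Compare a continuous characteristic between two groups
#'
#' Two-sided two-sample t-test, Welch (unequal variances) by default;
#' a Wilcoxon rank-sum alternative is available.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param method `"welch"` (default), `"student"`, or `"wilcoxon"`.
#' @return List with `method`, `statistic`, `p_value`.
#' @export
compare_continuous <- function(x, y, method = c("welch", "student",
                                                "wilcoxon")) {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0 && method != "wilcoxon") {
    if (identical(mean(x), mean(y)))
      return(list(method = method, statistic = 0, p_value = 1))
    stop("zero variance in both groups: t-test undefined")
  }
  res <- switch(method,
    welch = stats::t.test(x, y, var.equal = FALSE),
    student = stats::t.test(x, y, var.equal = TRUE),
    wilcoxon = stats::wilcox.test(x, y, exact = FALSE))
  list(method = method, statistic = unname(res$statistic),
       p_value = res$p.value)
}

#' Baseline-characteristics comparison table for a bilateral cohort
#'
#' Builds the standard injured-vs-uninjured patient comparison: counts
#' and percentages for sex, T stage and chemotherapy with
#' [compare_categorical()], and age with [compare_continuous()]. A
#' patient counts as injured if either lobe is.
#'
#' @param lobes cohort data.frame in the schema of [read_cohort()].
#' @return data.frame: `characteristic`, `level`, `n_no_injury`,
#'   `n_injury`, `method`, `p_value`.
#' @export
cohort_summary <- function(lobes) {
  pat <- lapply(split(lobes, lobes$patient_id), function(d)
    data.frame(injured = any(d$event == 1), age = d$age[1], sex = d$sex[1],
               t_stage = d$t_stage[1], chemo = d$chemo[1]))
  pat <- do.call(rbind, pat)
  rows <- list()
  for (v in c("sex", "t_stage", "chemo")) {
    tab <- table(pat[[v]], pat$injured)
    if (ncol(tab) < 2 || nrow(tab) < 2) next
    cmp <- compare_categorical(as.matrix(tab))
    for (lev in rownames(tab)) {
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = v, level = lev,
        n_no_injury = tab[lev, "FALSE"], n_injury = tab[lev, "TRUE"],
        method = cmp$method, p_value = cmp$p_value)
    }
  }
  agecmp <- tryCatch(
    compare_continuous(pat$age[!pat$injured], pat$age[pat$injured]),
    error = function(e) NULL)
  if (!is.null(agecmp)) {
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = "age", level = "(years)",
      n_no_injury = sum(!pat$injured), n_injury = sum(pat$injured),
      method = agecmp$method, p_value = agecmp$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
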