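# Cohort summary statistics in the SPSS conventions the reference tables
# were produced with: HAVERAGE (Hyndman-Fan type 6) quantiles for group
# medians/interquartiles, Pearson chi-square without continuity
# correction for contingency tables, and both mean-based and rank-based
# group comparisons reported side by side.

#' Type-6 (SPSS HAVERAGE) sample quantile
#'
#' Interpolates the sorted values at rank `h = p * (n + 1)`, clamped to
#' `[1, n]` -- the HAVERAGE rule SPSS prints, implemented by
#' `stats::quantile(type = 6)`. This is the rule that reproduces the
#' reference cohort's printed interquartiles exactly.
#'
#' @param values Non-empty numeric vector.
#' @param p Probability in (0, 1); may be a vector.
#' @return The quantile value(s), unnamed.
#' @export
#' @examples
#' quantile_type6(c(37, 139, 374, 827), 0.25)  # 62.5
quantile_type6 <- function(values, p) {
  if (!length(values)) stop("empty input: quantile of no values")
  if (any(is.na(values))) stop("values must not contain NA")
  if (any(p <= 0 | p >= 1)) .stop_field("p", "must lie strictly in (0, 1)")
  unname(quantile(values, probs = p, type = 6))
}

#' Group summaries as median and type-6 interquartiles
#'
#' @param records Data frame of sample records.
#' @param group_by Name of the grouping column (or a factor of
#'   `nrow(records)` values).
#' @param variable Name of the numeric column to summarise.
#' @return Data frame with columns `group`, `n`, `median`, `q1`, `q3`.
#'   Empty groups are omitted with a warning.
#' @export
#' @examples
#' group_summary(crc_cohort(), "msi", "aberration_count")
group_summary <- function(records, group_by, variable) {
  g <- if (length(group_by) == 1 && is.character(group_by)) {
    if (!group_by %in% names(records))
      stop("unknown grouping field: ", group_by)
    records[[group_by]]
  } else group_by
  v <- records[[variable]]
  if (!is.numeric(v)) stop("variable must be numeric: ", variable)
  g <- as.factor(g)
  empty <- levels(g)[!levels(g) %in% unique(as.character(g))]
  if (length(empty))
    warning("empty groups omitted: ", paste(empty, collapse = ", "))
  rows <- lapply(levels(droplevels(g)), function(lev) {
    x <- v[g == lev]
    data.frame(group = lev, n = length(x),
               median = quantile_type6(x, 0.5),
               q1 = quantile_type6(x, 0.25),
               q3 = quantile_type6(x, 0.75), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with expectations from the margins and
#' `df = (r - 1)(c - 1)`, no continuity correction (the SPSS "Pearson
#' Chi-Square" row). Empty rows and columns are dropped first.
#'
#' @param contingency Matrix or table of non-negative counts.
#' @return List with `statistic`, `df`, `p.value` and `expected`.
#' @export
#' @examples
#' tab <- matrix(c(1, 17, 0, 4, 4, 1), nrow = 2)  # location x MSI
#' pearson_chisq(tab)$p.value  # < 0.001
pearson_chisq <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) == 0) stop("zero grand total")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 rows and 2 columns after dropping empty margins")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected)
}

#' Mean-based and rank-based group comparisons, side by side
#'
#' For two groups reports Student's t test and the Mann-Whitney
#' (Wilcoxon rank-sum) test; for three or more, one-way ANOVA and
#' Kruskal-Wallis. Both families are reported without privileging either.
#' Groups with fewer than 2 observations cause the affected test to be
#' skipped with a reason.
#'
#' @param records Data frame of sample records.
#' @param group_by Grouping column name (or factor).
#' @param variable Numeric column name.
#' @return Data frame with columns `test`, `statistic`, `df`, `p`,
#'   `note`.
#' @export
group_tests <- function(records, group_by, variable) {
  g <- if (length(group_by) == 1 && is.character(group_by))
    records[[group_by]] else group_by
  v <- records[[variable]]
  if (!is.numeric(v)) stop("variable must be numeric: ", variable)
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups")
  small <- names(which(table(g) < 2))
  rows <- list()
  push <- function(test, statistic = NA_real_, df = NA_real_,
                   p = NA_real_, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, statistic = statistic, df = df, p = p, note = note,
      stringsAsFactors = FALSE)
  }
  if (length(small)) {
    note <- paste("groups with n < 2:", paste(small, collapse = ", "))
    if (k == 2) {
      push("t", note = note)
      push("mann_whitney", note = note)
    } else {
      push("anova", note = note)
      push("kruskal_wallis", note = note)
    }
  } else if (k == 2) {
    tt <- t.test(v ~ g)
    push("t", unname(tt$statistic), unname(tt$parameter), tt$p.value)
    wt <- suppressWarnings(wilcox.test(v ~ g))
    push("mann_whitney", unname(wt$statistic), p = wt$p.value)
  } else {
    av <- summary(aov(v ~ g))[[1]]
    push("anova", av$`F value`[1], av$Df[1], av$`Pr(>F)`[1])
    kt <- kruskal.test(v ~ g)
    push("kruskal_wallis", unname(kt$statistic), unname(kt$parameter),
         kt$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MSI association table (clinical covariates by MSI status)
#'
#' Summarises a clinical cohort by MSI group: type-6 age summaries per
#' group with a rank test, and sex, location and stage counts with
#' Pearson chi-square p values.
#'
#' @param clinical Clinical table (see [crc_cohort()]).
#' @return List with `age` (a [group_summary()] plus tests), `sex`,
#'   `location`, `stage` (each a list of `table` and `p`), and `msi_tally`.
#' @export
msi_association_table <- function(clinical) {
  msi <- factor(clinical$msi, levels = c("MSS", "MSI-L", "MSI-H"))
  age <- group_summary(clinical, msi, "age")
  age_tests <- tryCatch(group_tests(clinical, msi, "age"),
                        error = function(e)
                          data.frame(test = "none", statistic = NA_real_,
                                     df = NA_real_, p = NA_real_,
                                     note = conditionMessage(e)))
  assoc <- function(var) {
    tab <- table(clinical[[var]], msi)
    p <- tryCatch(pearson_chisq(tab)$p.value, error = function(e) NA_real_)
    list(table = tab, p = p)
  }
  list(msi_tally = cohort_msi_table(data.frame(status = clinical$msi)),
       age = age, age_tests = age_tests,
       sex = assoc("sex"), location = assoc("location"),
       stage = assoc("stage"))
}

#' Aberration-count association table
#'
#' Median (type-6 25-75% interquartile) aberration counts by sex,
#' location, stage, the three MSI groups, and the MSI-H versus
#' non-MSI-H dichotomy, each with mean-based and rank-based tests.
#'
#' @param clinical Clinical table including `aberration_count`.
#' @return Named list of lists, each with `summary` ([group_summary()])
#'   and `tests` ([group_tests()]).
#' @export
aberration_summary_table <- function(clinical) {
  msi3 <- factor(clinical$msi, levels = c("MSS", "MSI-L", "MSI-H"))
  msi2 <- factor(ifelse(clinical$msi == "MSI-H", "MSI-H", "non-MSI-H"),
                 levels = c("non-MSI-H", "MSI-H"))
  grp <- list(sex = clinical$sex, location = clinical$location,
              stage = clinical$stage, msi = msi3, msi_dichotomy = msi2)
  lapply(grp, function(g) {
    list(summary = group_summary(clinical, g, "aberration_count"),
         tests = tryCatch(group_tests(clinical, g, "aberration_count"),
                          error = function(e)
                            data.frame(test = "none", statistic = NA,
                                       df = NA, p = NA,
                                       note = conditionMessage(e))))
  })
}
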