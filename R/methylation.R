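# Methylation-specific PCR tabulation: per-gene methylation frequencies
# and their stratified association with clinical covariates.

#' Per-gene methylation frequency
#'
#' Percent of evaluable samples (state `M` or `U`; `NA` states are removed
#' gene-wise) whose promoter is methylated, reported to one decimal.
#'
#' @param calls Long-format methylation calls: columns `sample`, `gene`,
#'   `state` (`"M"`, `"U"` or `NA`).
#' @param gene Gene symbol to tabulate.
#' @param subset Optional character vector of sample ids to restrict to.
#' @return A list with `percent` (1-decimal, `NA` if no sample is
#'   evaluable), `n_methylated` and `n_evaluable`.
#' @export
#' @examples
#' calls <- data.frame(sample = paste0("S", 1:16), gene = "P16",
#'                     state = rep(c("M", "U"), c(9, 7)))
#' methylation_frequency(calls, "P16")$percent  # 56.2
methylation_frequency <- function(calls, gene, subset = NULL) {
  x <- calls[calls$gene == gene, , drop = FALSE]
  if (!is.null(subset)) x <- x[x$sample %in% subset, , drop = FALSE]
  x <- x[!is.na(x$state) & x$state %in% c("M", "U"), , drop = FALSE]
  n <- nrow(x)
  m <- sum(x$state == "M")
  if (n == 0) {
    warning("no evaluable samples for gene ", gene)
    return(list(percent = NA_real_, n_methylated = 0L, n_evaluable = 0L))
  }
  list(percent = round(100 * m / n, 1), n_methylated = as.integer(m),
       n_evaluable = as.integer(n))
}

# build the stratum factor for a covariate from the clinical table;
# age is dichotomised at 60 and MSI means MSI-H versus the rest
.stratum_factor <- function(clinical, covariate) {
  switch(covariate,
    msi = factor(ifelse(clinical$msi == "MSI-H", "MSI-H", "non-MSI-H"),
                 levels = c("MSI-H", "non-MSI-H")),
    sex = factor(clinical$sex, levels = c("F", "M")),
    location = factor(clinical$location, levels = c("R", "L")),
    differentiation = factor(clinical$differentiation,
                             levels = c("Poorly", "Moderately", "Well")),
    age = factor(ifelse(clinical$age < 60, "<60", ">=60"),
                 levels = c("<60", ">=60")),
    stop("unknown covariate: ", covariate))
}

#' Stratified association of a gene's methylation with a covariate
#'
#' Builds the methylated/unmethylated x stratum contingency table and
#' tests it with the Pearson chi-square (no continuity correction, the
#' convention of the SPSS "Pearson Chi-Square" row). When any expected
#' cell count falls below 1 the Fisher exact test is substituted and
#' flagged. Covariates: `msi` (MSI-H versus the rest), `sex`, `location`,
#' `differentiation`, and `age` dichotomised at 60 years.
#'
#' @param calls Long-format methylation calls (see
#'   [methylation_frequency()]).
#' @param clinical Clinical table with `sample` plus the covariate columns.
#' @param gene Gene symbol.
#' @param covariate One of `"msi"`, `"sex"`, `"location"`,
#'   `"differentiation"`, `"age"`.
#' @return A one-row data frame: `gene`, `covariate`, one
#'   `pct_<stratum>` column per stratum, `p`, `method` (`"chisq"`,
#'   `"fisher"` or `"none"`) and `note` (reason when `p` is `NA`).
#' @export
stratified_association <- function(calls, clinical, gene, covariate) {
  x <- calls[calls$gene == gene & !is.na(calls$state) &
               calls$state %in% c("M", "U"), , drop = FALSE]
  stratum <- .stratum_factor(clinical, covariate)[
    match(x$sample, clinical$sample)]
  ok <- !is.na(stratum)
  x <- x[ok, , drop = FALSE]
  stratum <- droplevels(stratum[ok])
  pct <- vapply(levels(stratum), function(s) {
    n <- sum(stratum == s)
    if (n == 0) NA_real_ else round(100 * sum(x$state[stratum == s] == "M") / n, 1)
  }, numeric(1))
  tab <- table(factor(x$state, levels = c("M", "U")), stratum)
  p <- NA_real_
  method <- "none"
  note <- ""
  if (any(rowSums(tab) == 0)) {
    note <- "no variation in methylation state"
  } else if (nlevels(stratum) < 2) {
    note <- "fewer than two strata"
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      p <- stats::fisher.test(tab)$p.value
      method <- "fisher"
      note <- "expected cell < 1; Fisher exact substituted"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
      method <- "chisq"
    }
  }
  out <- data.frame(gene = gene, covariate = covariate,
                    stringsAsFactors = FALSE)
  for (s in names(pct)) out[[paste0("pct_", s)]] <- pct[[s]]
  out$p <- p
  out$method <- method
  out$note <- note
  out
}

#' Full methylation association table
#'
#' One row per gene and covariate, mirroring a genes-by-parameters
#' methylation frequency/association table.
#'
#' @param calls Long-format methylation calls.
#' @param clinical Clinical table.
#' @param covariates Covariates to test (default all five).
#' @return Data frame with columns `gene`, `covariate`, the stratum
#'   percentages, `p`, `method`, `note`.
#' @export
methylation_table <- function(calls, clinical,
                              covariates = c("msi", "sex", "location",
                                             "differentiation", "age")) {
  genes <- unique(calls$gene)
  rows <- list()
  for (g in genes) for (cv in covariates) {
    r <- stratified_association(calls, clinical, g, cv)
    r2 <- data.frame(gene = g, covariate = cv,
                     strata = paste(grep("^pct_", names(r), value = TRUE),
                                    collapse = ";"),
                     percents = paste(.fmt_num(unlist(
                       r[grep("^pct_", names(r))])), collapse = ";"),
                     p = r$p, method = r$method, note = r$note,
                     stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- r2
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a long-format methylation table written by [write_cohort()]
#'
#' @param path Path to a tab-separated file with columns `sample`, `gene`,
#'   `state`.
#' @return The methylation calls data frame.
#' @export
read_methylation <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("sample", "gene", "state"), names(x))
  if (length(miss))
    stop("methylation table is missing columns: ",
         paste(miss, collapse = ", "))
  x
}
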