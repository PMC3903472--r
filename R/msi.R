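# MSI classification from the standard five mononucleotide markers
# (BAT25, BAT26, NR21, NR22, NR27): >= 2 unstable markers -> MSI-H,
# exactly 1 -> MSI-L, 0 -> MSS.

.msi_markers <- c("BAT25", "BAT26", "NR21", "NR22", "NR27")

#' Classify microsatellite-instability status from the 5-marker panel
#'
#' Applies the standard mononucleotide-panel rule: tumors with at least
#' two unstable markers are MSI-H, those with exactly one are MSI-L, and
#' those with none are MSS. Samples with fewer than `min_evaluable`
#' non-missing markers are explicitly reported as `Unclassifiable` rather
#' than silently called MSS.
#'
#' @param marker_calls Data frame with a `sample` column and one column
#'   per marker (`BAT25`, `BAT26`, `NR21`, `NR22`, `NR27`) holding
#'   `"stable"`, `"unstable"` or `"missing"`/`NA`.
#' @param min_evaluable Minimum number of evaluable markers required to
#'   classify (default 4).
#' @return Data frame with columns `sample`, `status` (`MSS`, `MSI-L`,
#'   `MSI-H` or `Unclassifiable`), `n_unstable`, `n_evaluable`.
#' @export
#' @examples
#' x <- data.frame(sample = "T1", BAT25 = "unstable", BAT26 = "unstable",
#'                 NR21 = "stable", NR22 = "stable", NR27 = "stable")
#' classify_msi(x)$status  # "MSI-H"
classify_msi <- function(marker_calls, min_evaluable = 4) {
  miss <- setdiff(.msi_markers, names(marker_calls))
  if (length(miss))
    stop("marker table is missing the panel markers: ",
         paste(miss, collapse = ", "))
  m <- as.matrix(marker_calls[, .msi_markers, drop = FALSE])
  bad <- !(m %in% c("stable", "unstable", "missing", NA))
  if (any(bad))
    stop("invalid marker call values: ",
         paste(unique(m[bad]), collapse = ", "))
  unstable <- matrix(m == "unstable", nrow = nrow(m))
  evaluable <- matrix(m %in% c("stable", "unstable"), nrow = nrow(m))
  n_unstable <- rowSums(unstable)
  n_evaluable <- rowSums(evaluable)
  status <- ifelse(n_evaluable < min_evaluable, "Unclassifiable",
                   ifelse(n_unstable >= 2, "MSI-H",
                          ifelse(n_unstable == 1, "MSI-L", "MSS")))
  data.frame(sample = marker_calls$sample, status = status,
             n_unstable = as.integer(n_unstable),
             n_evaluable = as.integer(n_evaluable),
             stringsAsFactors = FALSE)
}

#' Tally MSI statuses across a cohort
#'
#' @param statuses Output of [classify_msi()], or any data frame with a
#'   `status` column.
#' @return Named integer vector with counts for `MSS`, `MSI-L`, `MSI-H`
#'   and `Unclassifiable`.
#' @export
cohort_msi_table <- function(statuses) {
  lev <- c("MSS", "MSI-L", "MSI-H", "Unclassifiable")
  tab <- table(factor(statuses$status, levels = lev))
  stats::setNames(as.integer(tab), lev)
}

#' Read a marker-call table written by [write_cohort()]
#'
#' @param path Path to a tab-separated marker table.
#' @return The marker-call data frame.
#' @export
read_msi_markers <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("sample", .msi_markers), names(x))
  if (length(miss))
    stop("marker table is missing columns: ", paste(miss, collapse = ", "))
  x
}
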