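#' The 27-tumor colorectal cohort shipped with the package
#'
#' Clinical and molecular characteristics of the 27 colorectal tumors the
#' package's summary tables are built from: age, sex, AJCC stage, tumor
#' location (right/left colon), differentiation grade, microsatellite
#' instability status and the number of copy-number aberrations called per
#' tumor. This table is the package's reference dataset; the raw array data
#' behind the aberration counts are not distributed.
#'
#' @return A data frame with 27 rows and columns `sample`, `age`, `sex`
#'   (`"M"`/`"F"`), `stage` (1-4), `location` (`"R"`/`"L"`),
#'   `differentiation` (`"Well"`/`"Moderately"`/`"Poorly"`), `msi`
#'   (`"MSS"`/`"MSI-L"`/`"MSI-H"`) and `aberration_count`.
#' @export
#' @examples
#' tab <- crc_cohort()
#' table(tab$msi)
crc_cohort <- function() {
  path <- system.file("extdata", "table1_cohort.tsv", package = "oncoclade",
                      mustWork = TRUE)
  read_clinical(path)
}

#' Read a clinical cohort table
#'
#' Reads a tab-separated clinical table in the package's cohort format
#' (see [crc_cohort()] for the column contract).
#'
#' @param path Path to a tab-separated file.
#' @return A validated clinical data frame.
#' @export
read_clinical <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "age", "sex", "stage", "location", "differentiation",
            "msi")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("clinical table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(!x$sex %in% c("M", "F"))) .stop_field("sex", "values must be M/F")
    if (any(!x$location %in% c("R", "L")))
      .stop_field("location", "values must be R/L")
    if (any(!x$msi %in% c("MSS", "MSI-L", "MSI-H", "Unclassifiable")))
      .stop_field("msi", "values must be MSS/MSI-L/MSI-H/Unclassifiable")
    if (any(x$age <= 0)) .stop_field("age", "ages must be positive")
    if ("aberration_count" %in% names(x) && any(x$aberration_count < 0))
      .stop_field("aberration_count", "counts must be non-negative")
    if (anyDuplicated(x$sample))
      .stop_field("sample", "sample identifiers must be unique")
  }
  x
}

#' Gene annotation panels shipped with the package
#'
#' Two editable gene panels with toy coordinates on the simplified genome
#' ([genome_model()]): `"oncogene"` — a 41-gene oncogene/tumor-suppressor
#' panel; `"can"` — the candidate cancer (CAN) gene panel from large-scale
#' tumor sequencing, restricted to the genes analysed here. Coordinates are
#' synthetic placeholders, not assembly positions.
#'
#' @param panel `"oncogene"` or `"can"`.
#' @return A gene annotation data frame (see [read_gene_annotation()]).
#' @export
gene_panel <- function(panel = c("oncogene", "can")) {
  panel <- match.arg(panel)
  f <- c(oncogene = "genes_oncogene_panel_synthetic.bed",
         can = "genes_can_panel_synthetic.bed")[[panel]]
  read_gene_annotation(system.file("extdata", f, package = "oncoclade",
                                   mustWork = TRUE))
}

#' Read a BED-like gene annotation table
#'
#' Expects four tab-separated columns `chrom`, `start`, `end`, `gene`
#' (0-based half-open coordinates, no header required; a header line is
#' detected and skipped).
#'
#' @param path Path to a BED-like file.
#' @return A data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("^(chrom|#)", first) && !grepl("^chr[0-9XYM]", first)) 1L else 0L
  x <- read.delim(path, header = FALSE, skip = skip, stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop("gene annotation needs columns chrom, start, end, gene")
  x <- x[, 1:4]
  names(x) <- c("chrom", "start", "end", "gene")
  if (any(x$start >= x$end)) .stop_field("start", "start must be < end")
  if (anyDuplicated(x$gene)) .stop_field("gene", "gene symbols must be unique")
  x[, c("gene", "chrom", "start", "end")]
}
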