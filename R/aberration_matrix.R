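# The "polarity assessment": pool every specimen's aberrations, remove
# duplicates, and score each specimen 1/0 for presence/absence of each
# pooled aberration, giving the binary specimens x characters matrix that
# the parsimony analysis consumes.

#' Canonical aberration keys for interval calls
#'
#' Maps each call to the string key `chrom:start-end:direction`; with a
#' positive `merge_tolerance_bp` the coordinates are first snapped down to
#' that grid, so intervals differing by less than the tolerance share a
#' key. The default tolerance 0 requires exact coordinate identity.
#'
#' @param calls Data frame with `chrom`, `start`, `end`, `direction`.
#' @param merge_tolerance_bp Grid size in bp (0 = exact identity).
#' @return Character vector of keys, one per call.
#' @export
#' @examples
#' canonicalize(data.frame(chrom = "chr1", start = 1001, end = 5001,
#'                         direction = "gain"), merge_tolerance_bp = 1000)
canonicalize <- function(calls, merge_tolerance_bp = 0) {
  if (merge_tolerance_bp < 0)
    .stop_field("merge_tolerance_bp", "must be non-negative")
  s <- calls$start
  e <- calls$end
  if (merge_tolerance_bp > 0) {
    s <- (s %/% merge_tolerance_bp) * merge_tolerance_bp
    e <- (e %/% merge_tolerance_bp) * merge_tolerance_bp
  }
  sprintf("%s:%d-%d:%s", calls$chrom, as.integer(s), as.integer(e),
          calls$direction)
}

#' Build the binary specimen-by-aberration character matrix
#'
#' Characters are the deduplicated union of canonical aberration keys over
#' all specimens (interval mode) or of `gene:direction` pairs (gene mode),
#' sorted by genomic position; the entry for (specimen, character) is 1
#' exactly when the specimen carries that aberration. Characters shared by
#' every specimen are retained -- they are parsimony-uninformative but part
#' of the pooled aberration list.
#'
#' @param calls Interval calls (`sample`, `chrom`, `start`, `end`,
#'   `direction`) or gene events (`sample`, `gene`, `direction`) from
#'   [intersect_genes()].
#' @param merge_tolerance_bp Coordinate snap used by [canonicalize()]
#'   (interval mode only).
#' @param mode `"interval"` (default) or `"gene"` character identity.
#' @return An integer 0/1 matrix of class `aberration_matrix` with
#'   specimens as rows (sorted by identifier) and characters as columns;
#'   attributes `mode`, `merge_tolerance_bp` and `character_map` (a data
#'   frame describing each column).
#' @export
build_matrix <- function(calls, merge_tolerance_bp = 0,
                         mode = c("interval", "gene")) {
  mode <- match.arg(mode)
  taxa <- sort(unique(calls$sample))
  if (length(taxa) < 3)
    stop("tree inference needs >= 3 specimens; got ", length(taxa))
  if (mode == "interval") {
    keys <- canonicalize(calls, merge_tolerance_bp)
    map <- data.frame(key = keys, chrom = calls$chrom,
                      start = calls$start, end = calls$end,
                      direction = calls$direction, stringsAsFactors = FALSE)
    map <- map[!duplicated(map$key), , drop = FALSE]
    map <- map[order(.chrom_rank(map$chrom), map$start, map$end,
                     map$direction), , drop = FALSE]
  } else {
    keys <- paste(calls$gene, calls$direction, sep = ":")
    map <- data.frame(key = keys, gene = calls$gene,
                      direction = calls$direction, stringsAsFactors = FALSE)
    map <- map[!duplicated(map$key), , drop = FALSE]
    map <- map[order(map$gene, map$direction), , drop = FALSE]
  }
  m <- matrix(0L, nrow = length(taxa), ncol = nrow(map),
              dimnames = list(taxa, map$key))
  m[cbind(match(calls$sample, taxa), match(keys, map$key))] <- 1L
  rownames(map) <- NULL
  structure(m, mode = mode, merge_tolerance_bp = merge_tolerance_bp,
            character_map = map, class = c("aberration_matrix", "matrix",
                                           "array"))
}

#' @export
print.aberration_matrix <- function(x, ...) {
  cat(sprintf("Binary aberration matrix: %d specimens x %d characters (%s mode, tolerance %g bp)\n",
              nrow(x), ncol(x), attr(x, "mode"),
              attr(x, "merge_tolerance_bp")))
  info <- colSums(x)
  cat(sprintf("  parsimony-informative characters: %d; singletons: %d; shared by all: %d\n",
              sum(info >= 2 & info <= nrow(x) - 2), sum(info == 1),
              sum(info == nrow(x))))
  invisible(x)
}

# sanitize taxon names for PHYLIP: non-alphanumerics -> "_", truncate to
# 10, disambiguate collisions with a numeric suffix
.phylip_names <- function(taxa) {
  s <- gsub("[^A-Za-z0-9_.]", "_", taxa)
  s <- substr(s, 1, 10)
  while (anyDuplicated(s)) {
    d <- which(duplicated(s) | duplicated(s, fromLast = TRUE))
    for (grp in split(d, s[d])) {
      for (k in seq_along(grp)) {
        suf <- as.character(k)
        s[grp[k]] <- paste0(substr(s[grp[k]], 1, 10 - nchar(suf)), suf)
      }
    }
    if (anyDuplicated(s) && all(nchar(s) >= 10))
      stop("cannot disambiguate taxon names within 10 characters")
  }
  s
}

#' Write a binary character matrix in PHYLIP discrete format
#'
#' The dialect read by PHYLIP's discrete-character programs: a header line
#' `ntax nchar`, then one line per taxon with the name padded to width 10
#' followed by the 0/1 character string. Names longer than 10 characters
#' are truncated and disambiguated; the original-to-sanitized mapping is
#' written next to the matrix as `<path>.names.tsv` when any name changed.
#'
#' @param m An [build_matrix()] result (or any 0/1 matrix with rownames).
#' @param path Output file path.
#' @return Invisibly, the data frame mapping original to written names.
#' @export
write_phylip_discrete <- function(m, path) {
  taxa <- rownames(m)
  if (is.null(taxa)) stop("matrix must have specimen rownames")
  nm <- .phylip_names(taxa)
  lines <- c(sprintf("%d %d", nrow(m), ncol(m)),
             sprintf("%-10s%s", nm,
                     apply(m, 1, function(r) paste0(r, collapse = ""))))
  writeLines(lines, path)
  mapping <- data.frame(original = taxa, written = nm,
                        stringsAsFactors = FALSE)
  if (any(mapping$original != mapping$written))
    write.table(mapping, paste0(path, ".names.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(mapping)
}

#' Read a PHYLIP discrete-character matrix
#'
#' @param path File written by [write_phylip_discrete()] (or by PHYLIP
#'   itself, with names in the first 10 columns).
#' @return An integer 0/1 matrix with taxon rownames.
#' @export
read_phylip_discrete <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr)))
    stop("malformed PHYLIP header in ", path)
  body <- lines[1 + seq_len(hdr[1])]
  taxa <- trimws(substr(body, 1, 10))
  chars <- gsub("\\s", "", substr(body, 11, nchar(body)))
  if (any(nchar(chars) != hdr[2]))
    stop("character rows do not match the header in ", path)
  m <- t(vapply(strsplit(chars, ""), function(r) as.integer(r),
                integer(hdr[2])))
  if (hdr[2] == 1) m <- matrix(as.integer(unlist(strsplit(chars, ""))),
                               ncol = 1)
  rownames(m) <- taxa
  m
}
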