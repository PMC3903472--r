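# aCGH calling: a z-score moving-average segmenter for probe tracks,
# fold-change filtering of interval reports, interval-to-gene intersection
# and per-chromosome / per-sample aberration summaries.

#' Segment a probe log-ratio track into aberrant intervals
#'
#' Computes a moving average of probe log-ratios over a genomic window,
#' standardises it by the robust standard deviation of the whole track
#' (1.4826 x MAD -- aberrant segments would inflate a plain SD), and calls
#' maximal same-sign runs of probes whose standardised window mean reaches
#' `z_threshold`. Run edges are trimmed of probes whose own log-ratio is
#' below half the run's plateau (median) magnitude, so a noiseless planted
#' interval is recovered exactly over its covered probes. The reported
#' fold change is `2^(mean log-ratio)` of the run.
#'
#' @param probe_track Data frame with columns `chrom`, `position`,
#'   `log_ratio` (optionally `sample`), sorted by chromosome and position.
#' @param window_bp Moving-average window width in bp (default 0.2 Mb).
#' @param z_threshold Sensitivity threshold on the standardised window mean
#'   (default 2.5).
#' @return Data frame of interval calls: `chrom`, `start`, `end` (0-based
#'   half-open), `fold_change`, `direction`, `n_probes` (plus `sample` if
#'   present in the input).
#' @export
segment_probes <- function(probe_track, window_bp = 2e5, z_threshold = 2.5) {
  if (window_bp <= 0) .stop_field("window_bp", "must be positive")
  if (nrow(probe_track) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), fold_change = numeric(),
                      direction = character(), n_probes = integer(),
                      stringsAsFactors = FALSE))
  ord <- order(.chrom_rank(probe_track$chrom), probe_track$position)
  if (any(ord != seq_along(ord)))
    stop("probe track must be sorted by (chrom, position)")
  robust_sd <- stats::mad(probe_track$log_ratio)  # 1.4826 * MAD
  if (robust_sd == 0) robust_sd <- 1e-9
  calls <- list()
  for (ch in unique(probe_track$chrom)) {
    p <- probe_track[probe_track$chrom == ch, , drop = FALSE]
    pos <- p$position
    val <- p$log_ratio
    half <- window_bp / 2
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    cs <- cumsum(c(0, val))
    mv <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    z <- mv / robust_sd
    # hysteresis: a call is seeded where |z| reaches the threshold and
    # extended over flanking probes holding at least half of it, so brief
    # dips inside one aberration do not split the call
    seed_ <- abs(z) >= z_threshold
    flag <- abs(z) >= z_threshold / 2
    sgn <- sign(mv)
    run_id <- cumsum(c(TRUE, diff(flag) != 0 | diff(sgn) != 0))
    spacing <- if (length(pos) > 1) stats::median(diff(pos)) else window_bp
    runs <- lapply(unique(run_id[flag & seed_]),
                   function(r) which(run_id == r & flag))
    merged <- list()
    for (idx in runs) {
      if (length(merged)) {
        prev <- merged[[length(merged)]]
        if (pos[idx[1]] - pos[prev[length(prev)]] <= window_bp &&
            sgn[idx[1]] == sgn[prev[length(prev)]]) {
          merged[[length(merged)]] <- c(prev, idx)
          next
        }
      }
      merged[[length(merged) + 1L]] <- idx
    }
    for (idx in merged) {
      plateau <- stats::median(val[idx])
      if (plateau == 0) next
      keep <- abs(val[idx]) >= abs(plateau) / 2 & sign(val[idx]) == sign(plateau)
      # trim only from the edges inward
      first <- match(TRUE, keep)
      last <- length(keep) + 1L - match(TRUE, rev(keep))
      if (is.na(first)) next
      idx <- idx[first]:idx[last]  # contiguous probe range incl. merged gaps
      m <- mean(val[idx])
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, start = pos[idx[1]],
        end = pos[idx[length(idx)]] + spacing,
        fold_change = 2^m,
        direction = if (m > 0) "gain" else "loss",
        n_probes = length(idx), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               fold_change = numeric(), direction = character(),
               n_probes = integer(), stringsAsFactors = FALSE)
  if ("sample" %in% names(probe_track) && nrow(out))
    out <- cbind(sample = probe_track$sample[1], out,
                 stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter interval calls by fold-change thresholds
#'
#' Keeps gains strictly above `gain_fold` and losses strictly below
#' `loss_fold` (boundary values are dropped: a 1.2-fold event is not a
#' gain, a 1.21-fold event is). The `direction` column is (re)derived from
#' the thresholds.
#'
#' @param calls Data frame with at least a `fold_change` column.
#' @param gain_fold Gain threshold (> 1), default 1.2.
#' @param loss_fold Loss threshold (< 1), default 0.8.
#' @return The filtered calls with a consistent `direction` column.
#' @export
#' @examples
#' calls <- data.frame(fold_change = c(0.79, 0.8, 1.0, 1.2, 1.25))
#' filter_by_fold(calls)$fold_change  # 0.79 and 1.25 survive
filter_by_fold <- function(calls, gain_fold = 1.2, loss_fold = 0.8) {
  if (!(loss_fold < 1 && 1 < gain_fold))
    stop("thresholds must satisfy loss_fold < 1 < gain_fold")
  if (any(calls$fold_change <= 0)) .stop_field("fold_change", "must be > 0")
  keep <- calls$fold_change > gain_fold | calls$fold_change < loss_fold
  out <- calls[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold_change > gain_fold, "gain", "loss")
  rownames(out) <- NULL
  out
}

#' Intersect aberration calls with a gene annotation
#'
#' Emits one gene-level event for every (interval, gene) pair overlapping
#' by at least 1 bp on the same chromosome (half-open coordinates), with
#' the direction inherited from the interval; duplicate
#' (sample, gene, direction) events are collapsed, keeping the first
#' source interval.
#'
#' @param calls Interval calls with columns `sample`, `chrom`, `start`,
#'   `end`, `direction`.
#' @param annotation Gene annotation from [read_gene_annotation()].
#' @return Data frame of gene events: `sample`, `gene`, `direction`,
#'   `chrom`, `interval_start`, `interval_end`.
#' @export
intersect_genes <- function(calls, annotation) {
  missing_chr <- setdiff(unique(calls$chrom), unique(annotation$chrom))
  if (length(missing_chr))
    warning("chromosomes without gene annotation: ",
            paste(missing_chr, collapse = ", "))
  out <- list()
  for (ch in intersect(unique(calls$chrom), unique(annotation$chrom))) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    gg <- annotation[annotation$chrom == ch, , drop = FALSE]
    pairs <- expand.grid(i = seq_len(nrow(cc)), j = seq_len(nrow(gg)))
    ov <- cc$start[pairs$i] < gg$end[pairs$j] &
      gg$start[pairs$j] < cc$end[pairs$i]
    pairs <- pairs[ov, , drop = FALSE]
    if (!nrow(pairs)) next
    out[[ch]] <- data.frame(
      sample = cc$sample[pairs$i], gene = gg$gene[pairs$j],
      direction = cc$direction[pairs$i], chrom = ch,
      interval_start = cc$start[pairs$i], interval_end = cc$end[pairs$i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), gene = character(),
               direction = character(), chrom = character(),
               interval_start = integer(), interval_end = integer(),
               stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("sample", "gene", "direction")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chromosome aberration summary, split by sex
#'
#' Tabulates, for every chromosome of the genome model, the total number
#' of aberrations, amplifications and deletions, and the amplification and
#' deletion counts in male and female patients, so that
#' `total = amplifications + deletions` on every row.
#'
#' @param calls Filtered interval calls with `sample`, `chrom`, `direction`.
#' @param clinical Clinical table with `sample` and `sex` columns.
#' @return Data frame with one row per chromosome and columns `chrom`,
#'   `total`, `amplifications`, `deletions`, `amp_males`, `amp_females`,
#'   `del_males`, `del_females`.
#' @export
chromosome_summary <- function(calls, clinical) {
  miss <- setdiff(unique(calls$sample), clinical$sample)
  if (length(miss))
    stop("samples missing from clinical table: ", paste(miss, collapse = ", "))
  sex <- clinical$sex[match(calls$sample, clinical$sample)]
  if (nrow(calls) && any(!sex %in% c("M", "F")))
    stop("unknown sex code in clinical table")
  chroms <- .oncoclade_genome()$chrom
  cnt <- function(cond) {
    tab <- table(factor(calls$chrom[cond], levels = chroms))
    as.integer(tab)
  }
  gain <- calls$direction == "gain"
  data.frame(chrom = chroms,
             total = cnt(rep(TRUE, nrow(calls))),
             amplifications = cnt(gain),
             deletions = cnt(!gain),
             amp_males = cnt(gain & sex == "M"),
             amp_females = cnt(gain & sex == "F"),
             del_males = cnt(!gain & sex == "M"),
             del_females = cnt(!gain & sex == "F"),
             stringsAsFactors = FALSE)
}

#' Count aberration calls per sample
#'
#' @param calls Filtered interval calls with a `sample` column.
#' @param samples Optional character vector of sample identifiers to report
#'   (samples without calls are reported as 0).
#' @return Named integer vector of per-sample call counts.
#' @export
per_sample_totals <- function(calls, samples = NULL) {
  lev <- if (is.null(samples)) unique(calls$sample) else samples
  tab <- table(factor(calls$sample, levels = lev))
  stats::setNames(as.integer(tab), lev)
}

#' Read an interval report written by [write_cohort()]
#'
#' @param path Path to a tab-separated interval report with columns
#'   `sample`, `chrom`, `start`, `end`, `fold_change`, `n_probes`.
#' @return The interval report data frame.
#' @export
read_interval_report <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "fold_change")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("interval report is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(x) && any(x$start >= x$end))
    .stop_field("start", "intervals must satisfy start < end")
  x
}
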