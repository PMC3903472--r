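# Synthetic cohort generator. Emulates the joint structure the downstream
# analysis assumes: MSI-dependent aberration burden and tumor location,
# MSI-dependent promoter methylation, sex-linked direction of chrX events,
# and optional planted clades of identical shared aberrations that a
# parsimony analysis should recover.

#' Default gene-by-group methylation probability table
#'
#' Per-gene probability that a promoter is methylated, for MSI-H tumors and
#' for non-MSI-H (MSS/MSI-L) tumors. Defaults follow the methylation
#' frequencies observed in the reference cohort: `P16` 0.60 vs 0.045 and
#' `hMLH1` 0.80 vs 0.045 carry the planted MSI association; `SYNE1` and
#' `MMP2` are methylated in every tumor and `RNF182` in none.
#'
#' @return A 15 x 2 numeric matrix, rows = genes, columns `"MSI-H"`,
#'   `"non-MSI-H"`.
#' @export
default_methylation_prob <- function() {
  genes <- c("P16", "hMLH1", "SYNE1", "RNF182", "MMP2", "ICAM5", "CHD5",
             "CD109", "GPNMB", "EVL", "RET", "STARD8", "LGR6", "PTPRD",
             "APC2")
  msih  <- c(0.60, 0.80, 1, 0, 1, 0.20, 0.80, 0.20, 0.60, 1.00, 0.20,
             0.60, 0.60, 0.80, 1.00)
  rest  <- c(0.045, 0.045, 1, 0, 1, 0.045, 0.364, 0.318, 0.864, 0.773,
             0.409, 0.591, 0.273, 0.818, 0.864)
  m <- cbind(`MSI-H` = msih, `non-MSI-H` = rest)
  rownames(m) <- genes
  m
}

#' Configuration for a synthetic tumor cohort
#'
#' Bundles and validates every parameter of the simulator. The defaults are
#' the study conditions of the reference 27-tumor cohort: MSI mixture
#' 18/4/5, group mean aberration counts 37/256/10 (negative binomial --
#' tumor aberration burdens are heavily overdispersed, spanning 1 to
#' several hundred), right-sided location probability 0.8 for MSI-H versus
#' 1/18 for MSS and 0 for MSI-L, and the [default_methylation_prob()]
#' panel.
#'
#' @param n_samples Number of tumors.
#' @param msi_proportions Probabilities of MSS, MSI-L, MSI-H (sum to 1).
#' @param aberration_count_params List with per-group negative-binomial
#'   means `mu` and dispersions `size` (names MSS, MSI-L, MSI-H).
#' @param right_side_prob_by_group Per-group probability of a right-sided
#'   tumor.
#' @param methylation_prob Gene x group probability matrix with columns
#'   `"MSI-H"` and `"non-MSI-H"`.
#' @param sexlinked_X_effect Probability that a chrX event is an
#'   amplification in a male (deletion in a female) rather than of random
#'   direction.
#' @param loss_prob Probability that a non-chrX event is a deletion.
#' @param planted_clades List of `list(members = <sample indices>,
#'   n_shared = <count>)`: each clade's members all receive `n_shared`
#'   identical aberrant intervals found in no other sample.
#' @param age_params Per-group normal age means and common sd (years).
#' @param probe_spacing_bp Probe spacing used when probe tracks are emitted.
#' @param noise_sd Standard deviation of probe log-ratio noise.
#' @param seed Integer master seed; every random draw flows from it.
#' @return A validated object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_samples = 27,
                          msi_proportions = c(MSS = 18, `MSI-L` = 4,
                                              `MSI-H` = 5) / 27,
                          aberration_count_params = list(
                            mu = c(MSS = 37, `MSI-L` = 256, `MSI-H` = 10),
                            size = c(MSS = 1.5, `MSI-L` = 1.5,
                                     `MSI-H` = 1.5)),
                          right_side_prob_by_group = c(MSS = 1 / 18,
                                                       `MSI-L` = 0,
                                                       `MSI-H` = 0.8),
                          methylation_prob = default_methylation_prob(),
                          sexlinked_X_effect = 0.9,
                          loss_prob = 0.6,
                          planted_clades = list(),
                          age_params = list(mean = c(MSS = 63, `MSI-L` = 40,
                                                     `MSI-H` = 57), sd = 12),
                          probe_spacing_bp = 10000,
                          noise_sd = 0.2,
                          seed = 1) {
  cfg <- list(n_samples = n_samples, msi_proportions = msi_proportions,
              aberration_count_params = aberration_count_params,
              right_side_prob_by_group = right_side_prob_by_group,
              methylation_prob = methylation_prob,
              sexlinked_X_effect = sexlinked_X_effect,
              loss_prob = loss_prob, planted_clades = planted_clades,
              age_params = age_params, probe_spacing_bp = probe_spacing_bp,
              noise_sd = noise_sd, seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  grp <- c("MSS", "MSI-L", "MSI-H")
  if (length(cfg$n_samples) != 1 || cfg$n_samples < 0 ||
      cfg$n_samples != round(cfg$n_samples))
    .stop_field("n_samples", "must be a single non-negative integer")
  p <- cfg$msi_proportions
  if (length(p) != 3 || any(p < 0) || any(p > 1))
    .stop_field("msi_proportions", "must be 3 probabilities in [0,1]")
  if (abs(sum(p) - 1) > 1e-9)
    .stop_field("msi_proportions", "must sum to 1")
  ab <- cfg$aberration_count_params
  if (!all(grp %in% names(ab$mu)) || any(ab$mu <= 0))
    .stop_field("aberration_count_params",
                "mu must be positive and named MSS/MSI-L/MSI-H")
  if (!all(grp %in% names(ab$size)) || any(ab$size <= 0))
    .stop_field("aberration_count_params", "size must be positive per group")
  r <- cfg$right_side_prob_by_group
  if (!all(grp %in% names(r)) || any(r < 0 | r > 1))
    .stop_field("right_side_prob_by_group",
                "must be probabilities named MSS/MSI-L/MSI-H")
  m <- cfg$methylation_prob
  if (!is.matrix(m) || !all(c("MSI-H", "non-MSI-H") %in% colnames(m)) ||
      any(m < 0 | m > 1))
    .stop_field("methylation_prob",
                "must be a probability matrix with MSI-H / non-MSI-H columns")
  for (f in c("sexlinked_X_effect", "loss_prob")) {
    v <- cfg[[f]]
    if (length(v) != 1 || v < 0 || v > 1)
      .stop_field(f, "must be a probability")
  }
  if (cfg$probe_spacing_bp <= 0)
    .stop_field("probe_spacing_bp", "must be positive")
  if (cfg$noise_sd < 0) .stop_field("noise_sd", "must be non-negative")
  for (cl in cfg$planted_clades) {
    if (is.null(cl$members) || is.null(cl$n_shared) ||
        any(cl$members < 1) || any(cl$members > cfg$n_samples) ||
        cl$n_shared < 1)
      .stop_field("planted_clades",
                  "each clade needs valid member indices and n_shared >= 1")
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed))
    .stop_field("seed", "must be a single integer")
  invisible(cfg)
}

# run code with a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# draw one random aberrant interval set of size k for one sample
.draw_intervals <- function(k, sex, sexlinked, loss_prob, genome) {
  if (k == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), fold_change = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  chrom <- sample(genome$chrom, k, replace = TRUE, prob = genome$length)
  len <- pmin(round(stats::rexp(k, 1 / 1e6)) + 1e5, 2e7)
  start <- floor(runif(k) * (genome$length[match(chrom, genome$chrom)] - len))
  is_x <- chrom == "chrX"
  dir_loss <- runif(k) < loss_prob
  forced <- is_x & (runif(k) < sexlinked)
  dir_loss[forced] <- sex == "F"
  fold <- ifelse(dir_loss, runif(k, 0.3, 0.75), runif(k, 1.3, 2.5))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), fold_change = fold,
             direction = ifelse(dir_loss, "loss", "gain"),
             stringsAsFactors = FALSE)
}

# merge same-direction overlaps per chromosome; on cross-direction overlap
# the longer interval wins
.merge_sample_intervals <- function(iv) {
  if (nrow(iv) < 2) return(iv)
  chs <- ds <- character(0)
  ss <- es <- integer(0)
  fs <- numeric(0)
  grp <- paste(iv$chrom, iv$direction)
  for (key in unique(grp)) {
    sel <- which(grp == key)
    o <- sel[order(iv$start[sel])]
    st <- iv$start[o]
    en <- iv$end[o]
    lf <- log2(iv$fold_change[o])
    ce <- cummax(en)
    gid <- cumsum(c(TRUE, st[-1] >= ce[-length(ce)]))
    first <- !duplicated(gid)
    last <- !duplicated(gid, fromLast = TRUE)
    k <- sum(first)
    chs <- c(chs, rep(iv$chrom[o[1]], k))
    ds <- c(ds, rep(iv$direction[o[1]], k))
    ss <- c(ss, st[first])            # sorted: first of a run is its min
    es <- c(es, ce[last])             # runs never look back: cummax = run max
    fs <- c(fs, as.numeric(rowsum(lf, gid)) / tabulate(gid))
  }
  iv <- data.frame(chrom = chs, start = ss, end = es, fold_change = 2^fs,
                   direction = ds, stringsAsFactors = FALSE)
  # cross-direction conflicts: keep the longer interval
  keep <- rep(TRUE, nrow(iv))
  for (ch in unique(iv$chrom)) {
    gi <- which(iv$chrom == ch & iv$direction == "gain")
    li <- which(iv$chrom == ch & iv$direction == "loss")
    if (!length(gi) || !length(li)) next
    ov <- outer(iv$start[gi], iv$end[li], `<`) &
      outer(iv$end[gi], iv$start[li], `>`)
    for (p in which(ov)) {
      a <- gi[(p - 1L) %% length(gi) + 1L]
      b <- li[(p - 1L) %/% length(gi) + 1L]
      keep[if ((iv$end[a] - iv$start[a]) >= (iv$end[b] - iv$start[b]))
        b else a] <- FALSE
    }
  }
  iv[keep, , drop = FALSE]
}

.overlaps_any <- function(iv, other) {
  if (nrow(iv) == 0 || nrow(other) == 0) return(rep(FALSE, nrow(iv)))
  vapply(seq_len(nrow(iv)), function(i) {
    j <- other$chrom == iv$chrom[i]
    any(other$start[j] < iv$end[i] & iv$start[i] < other$end[j])
  }, logical(1))
}

#' Generate a complete synthetic tumor cohort
#'
#' Draws clinical covariates, MSI marker calls, methylation calls and
#' per-sample aberrant-interval reports under the structure described in
#' [cohort_config()]. Planted clades are injected as identical intervals
#' shared by exactly their members (random intervals overlapping a planted
#' interval are discarded before injection, so the shared characters are
#' perfect). All randomness flows from the config seed, with per-sample
#' sub-streams, so identical configs give identical cohorts.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `crc_cohort`: a list with elements `samples`
#'   (clinical table including `aberration_count`), `interval_reports`,
#'   `msi_marker_calls`, `methylation_calls`, `probe_tracks` (`NULL`
#'   unless emitted separately) and `truth` (the planted parameters --
#'   never read by any analysis stage).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_samples = 10, seed = 42))
#' coh$samples$msi
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  genome <- .oncoclade_genome()
  grp_levels <- c("MSS", "MSI-L", "MSI-H")
  markers <- c("BAT25", "BAT26", "NR21", "NR22", "NR27")
  genes <- rownames(config$methylation_prob)
  n <- config$n_samples

  .with_seed(config$seed, {
    ids <- sprintf("S%03d", seq_len(n))
    group <- if (n) sample(grp_levels, n, replace = TRUE,
                           prob = config$msi_proportions) else character()
    sub_seeds <- if (n) sample.int(.Machine$integer.max - 1L, n) else integer()

    # clade intervals drawn from the master stream, mutually non-overlapping
    clade_iv <- list()
    all_clade <- data.frame(chrom = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
    for (ci in seq_along(config$planted_clades)) {
      cl <- config$planted_clades[[ci]]
      got <- 0L
      rows <- list()
      while (got < cl$n_shared) {
        cand <- .draw_intervals(1L, "M", 0, 0.5, genome)
        if (!any(.overlaps_any(cand, all_clade))) {
          rows[[length(rows) + 1L]] <- cand
          all_clade <- rbind(all_clade, cand[, c("chrom", "start", "end")])
          got <- got + 1L
        }
      }
      clade_iv[[ci]] <- do.call(rbind, rows)
    }

    samples <- vector("list", n)
    reports <- vector("list", n)
    msicalls <- vector("list", n)
    methcalls <- vector("list", n)
    for (i in seq_len(n)) {
      g <- group[i]
      .with_seed(sub_seeds[i], {
        sex <- if (runif(1) < 0.5) "M" else "F"
        age <- max(25, min(90, round(rnorm(1, config$age_params$mean[[g]],
                                           config$age_params$sd))))
        stage_probs <- switch(g,
          "MSS" = c(3, 8, 7, 0) / 18,
          "MSI-L" = c(1, 3, 0, 0) / 4,
          "MSI-H" = c(2, 2, 1, 0) / 5)
        stage <- sample(1:4, 1, prob = stage_probs)
        location <- if (runif(1) < config$right_side_prob_by_group[[g]])
          "R" else "L"
        differentiation <- sample(c("Well", "Moderately", "Poorly"), 1,
                                  prob = c(0.58, 0.38, 0.04))
        k <- max(1L, rnbinom(1, size = config$aberration_count_params$size[[g]],
                             mu = config$aberration_count_params$mu[[g]]))
        iv <- .draw_intervals(k, sex, config$sexlinked_X_effect,
                              config$loss_prob, genome)
        iv <- .merge_sample_intervals(iv)
        if (nrow(all_clade))
          iv <- iv[!.overlaps_any(iv, all_clade), , drop = FALSE]
        for (ci in seq_along(config$planted_clades))
          if (i %in% config$planted_clades[[ci]]$members)
            iv <- rbind(iv, clade_iv[[ci]])
        iv <- iv[order(.chrom_rank(iv$chrom), iv$start), , drop = FALSE]
        reports[[i]] <- data.frame(
          sample = rep(ids[i], nrow(iv)),
          chrom = iv$chrom, start = iv$start, end = iv$end,
          fold_change = iv$fold_change,
          n_probes = pmax(1L, (iv$end - iv$start) %/% config$probe_spacing_bp),
          stringsAsFactors = FALSE)

        n_unstable <- switch(g, "MSS" = 0L,
                             "MSI-L" = 1L,
                             "MSI-H" = sample(2:5, 1,
                                              prob = c(0.4, 0.3, 0.2, 0.1)))
        unstable <- sample(markers, n_unstable)
        mc <- as.list(ifelse(markers %in% unstable, "unstable", "stable"))
        names(mc) <- markers
        msicalls[[i]] <- data.frame(sample = ids[i], mc,
                                    stringsAsFactors = FALSE)

        col <- if (g == "MSI-H") "MSI-H" else "non-MSI-H"
        st <- ifelse(runif(length(genes)) < config$methylation_prob[, col],
                     "M", "U")
        methcalls[[i]] <- data.frame(sample = ids[i], gene = genes,
                                     state = st, stringsAsFactors = FALSE)

        samples[[i]] <- data.frame(
          sample = ids[i], age = age, sex = sex, stage = stage,
          location = location, differentiation = differentiation, msi = g,
          aberration_count = nrow(iv), stringsAsFactors = FALSE)
      })
    }

    empty_iv <- data.frame(sample = character(), chrom = character(),
                           start = integer(), end = integer(),
                           fold_change = numeric(), n_probes = integer(),
                           stringsAsFactors = FALSE)
    cohort <- list(
      samples = if (n) do.call(rbind, samples) else
        crc_cohort()[0, c("sample", "age", "sex", "stage", "location",
                          "differentiation", "msi", "aberration_count")],
      interval_reports = if (n) do.call(rbind, reports) else empty_iv,
      msi_marker_calls = if (n) do.call(rbind, msicalls) else
        data.frame(sample = character(), BAT25 = character(),
                   BAT26 = character(), NR21 = character(),
                   NR22 = character(), NR27 = character(),
                   stringsAsFactors = FALSE),
      methylation_calls = if (n) do.call(rbind, methcalls) else
        data.frame(sample = character(), gene = character(),
                   state = character(), stringsAsFactors = FALSE),
      probe_tracks = NULL,
      truth = list(
        config = config, group = stats::setNames(group, ids),
        sample_seeds = stats::setNames(sub_seeds, ids),
        aberration_count = stats::setNames(
          if (n) vapply(reports, nrow, integer(1)) else integer(), ids),
        clades = lapply(seq_along(config$planted_clades), function(ci)
          list(members = ids[config$planted_clades[[ci]]$members],
               intervals = clade_iv[[ci]]))))
    rownames(cohort$samples) <- NULL
    rownames(cohort$interval_reports) <- NULL
    rownames(cohort$msi_marker_calls) <- NULL
    rownames(cohort$methylation_calls) <- NULL
    class(cohort) <- "crc_cohort"
    cohort
  })
}

#' @export
print.crc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic tumor cohort: %d samples, %d aberrant intervals\n",
              nrow(x$samples), nrow(x$interval_reports)))
  if (nrow(x$samples)) {
    tab <- table(factor(x$samples$msi, c("MSS", "MSI-L", "MSI-H")))
    cat(sprintf("MSI status: MSS %d, MSI-L %d, MSI-H %d\n",
                tab[["MSS"]], tab[["MSI-L"]], tab[["MSI-H"]]))
  }
  if (length(x$truth$clades))
    cat(sprintf("Planted clades: %d\n", length(x$truth$clades)))
  invisible(x)
}

#' Emit a probe-level log-ratio track for one sample
#'
#' Places probes at regular spacing along the given regions (by default the
#' whole chromosomes of the simplified genome that carry an interval) and
#' assigns each probe `log2(fold_change)` inside an aberrant interval plus
#' Gaussian noise, and pure noise elsewhere.
#'
#' @param intervals Data frame of one sample's intervals with columns
#'   `chrom`, `start`, `end`, `fold_change` (0-based half-open), typically
#'   mutually non-overlapping per chromosome.
#' @param probe_spacing_bp Distance between probes (bp, positive).
#' @param noise_sd Standard deviation of probe noise (>= 0).
#' @param seed Integer seed for the noise stream.
#' @param regions Optional data frame `chrom`, `start`, `end` restricting
#'   probe placement; required when `intervals` is empty.
#' @return Data frame with columns `chrom`, `position`, `log_ratio`, sorted
#'   by chromosome then position.
#' @export
#' @examples
#' iv <- data.frame(chrom = "chr1", start = 0L, end = 1e6L, fold_change = 1.5)
#' tr <- emit_probe_track(iv, probe_spacing_bp = 1e4, noise_sd = 0, seed = 1,
#'                        regions = data.frame(chrom = "chr1", start = 0L,
#'                                             end = 2e6L))
#' sum(tr$log_ratio > 0)  # 100 covered probes
emit_probe_track <- function(intervals, probe_spacing_bp = 10000,
                             noise_sd = 0.2, seed = 1, regions = NULL) {
  if (probe_spacing_bp <= 0) .stop_field("probe_spacing_bp", "must be positive")
  if (noise_sd < 0) .stop_field("noise_sd", "must be non-negative")
  if ("sample" %in% names(intervals) &&
      length(unique(intervals$sample)) > 1)
    stop("emit_probe_track expects intervals of a single sample")
  if (is.null(regions)) {
    if (nrow(intervals) == 0)
      stop("`regions` is required when no intervals are given")
    genome <- .oncoclade_genome()
    ch <- unique(intervals$chrom)
    regions <- data.frame(chrom = ch, start = 0L,
                          end = genome$length[match(ch, genome$chrom)])
  }
  # overlap check per chromosome
  for (ch in unique(intervals$chrom)) {
    p <- intervals[intervals$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
      stop("intervals overlap on ", ch)
  }
  .with_seed(seed, {
    out <- lapply(seq_len(nrow(regions)), function(i) {
      pos <- seq.int(regions$start[i], regions$end[i] - 1L,
                     by = probe_spacing_bp)
      val <- numeric(length(pos))
      p <- intervals[intervals$chrom == regions$chrom[i], , drop = FALSE]
      for (j in seq_len(nrow(p))) {
        inside <- pos >= p$start[j] & pos < p$end[j]
        val[inside] <- log2(p$fold_change[j])
      }
      if (noise_sd > 0) val <- val + rnorm(length(pos), 0, noise_sd)
      data.frame(chrom = regions$chrom[i], position = pos, log_ratio = val,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out <- out[order(.chrom_rank(out$chrom), out$position), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a cohort to a directory of tab-separated files
#'
#' Writes `clinical.tsv`, `interval_report.tsv`, `msi_markers.tsv` and
#' `methylation.tsv`, plus the planted truth as a separate sidecar
#' (`truth.json`) that no analysis stage reads.
#'
#' @param cohort A `crc_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             intervals = file.path(dir, "interval_report.tsv"),
             msi = file.path(dir, "msi_markers.tsv"),
             methylation = file.path(dir, "methylation.tsv"),
             truth = file.path(dir, "truth.json"))
  wr <- function(x, p) {
    ok <- tryCatch({
      write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("failed to write ", p)
  }
  wr(cohort$samples, paths[["clinical"]])
  wr(cohort$interval_reports, paths[["intervals"]])
  wr(cohort$msi_marker_calls, paths[["msi"]])
  wr(cohort$methylation_calls, paths[["methylation"]])
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' The truth sidecar is deliberately not read back: analyses run from the
#' written files cannot see the planted parameters.
#'
#' @param dir Directory containing the cohort files.
#' @return A `crc_cohort` with `truth = NULL`.
#' @export
read_cohort <- function(dir) {
  rd <- function(name, classes = NA) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("missing cohort file: ", p)
    read.delim(p, stringsAsFactors = FALSE, colClasses = classes)
  }
  cohort <- list(samples = rd("clinical.tsv"),
                 interval_reports = rd("interval_report.tsv"),
                 msi_marker_calls = rd("msi_markers.tsv",
                                       classes = "character"),
                 methylation_calls = rd("methylation.tsv",
                                        classes = "character"),
                 probe_tracks = NULL, truth = NULL)
  class(cohort) <- "crc_cohort"
  cohort
}
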