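# End-to-end orchestration: simulate (or read) a cohort, call and filter
# aberrations, classify MSI, tabulate methylation, summarise the cohort,
# build the polarity matrix, fit the cladogram, and write every artifact
# with a run manifest.

#' Configuration for a full pipeline run
#'
#' Either `simulate` (a [cohort_config()]) or `input_dir` (a directory in
#' the [write_cohort()] layout) must be given. Paths are checked at run
#' start.
#'
#' @param out_dir Output directory.
#' @param simulate Optional [cohort_config()] to generate the cohort.
#' @param input_dir Optional directory with cohort files.
#' @param annotation Optional gene annotation (data frame or BED path) for
#'   gene-level calls.
#' @param gain_fold,loss_fold Fold-change thresholds ([filter_by_fold()]).
#' @param z_threshold,window_bp Segmentation settings (recorded in the
#'   manifest; segmentation runs only when probe tracks are supplied).
#' @param matrix_mode,merge_tolerance_bp Character identity for
#'   [build_matrix()].
#' @param method,model,seed,n_starts Parsimony settings
#'   ([parsimony_search()]).
#' @param logfile Optional path appended with log lines (also sent to
#'   `message()`).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, input_dir = NULL,
                            annotation = NULL, gain_fold = 1.2,
                            loss_fold = 0.8, z_threshold = 2.5,
                            window_bp = 2e5, matrix_mode = "interval",
                            merge_tolerance_bp = 0,
                            method = "auto", model = "wagner", seed = 1L,
                            n_starts = 10L, logfile = NULL) {
  if (is.null(simulate) && is.null(input_dir))
    stop("either `simulate` or `input_dir` is required")
  if (!is.null(simulate) && !inherits(simulate, "cohort_config"))
    stop("`simulate` must be a cohort_config")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input directory does not exist: ", input_dir)
  if (is.character(annotation) && !file.exists(annotation))
    stop("annotation file does not exist: ", annotation)
  if (!(loss_fold < 1 && 1 < gain_fold))
    stop("thresholds must satisfy loss_fold < 1 < gain_fold")
  structure(list(out_dir = out_dir, simulate = simulate,
                 input_dir = input_dir, annotation = annotation,
                 gain_fold = gain_fold, loss_fold = loss_fold,
                 z_threshold = z_threshold, window_bp = window_bp,
                 matrix_mode = matrix_mode,
                 merge_tolerance_bp = merge_tolerance_bp, method = method,
                 model = model, seed = seed, n_starts = n_starts,
                 logfile = logfile), class = "pipeline_config")
}

.log <- function(config, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(config$logfile)) cat(line, "\n", file = config$logfile,
                                    append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate the cohort; filter aberration calls by fold
#' change; intersect genes (when an annotation is given); classify MSI;
#' tabulate methylation associations; compute the chromosome and cohort
#' summary tables; build the polarity matrix; fit and root the
#' maximum-parsimony cladogram. Every stage logs its row counts; outputs
#' and a JSON run manifest (config, input checksums, per-stage counts)
#' land in `config$out_dir`. When the cohort has no interval report
#' (statistics-only input) the CGH, matrix and parsimony stages are
#' skipped with a logged reason.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory stage results (also written
#'   to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("oncoclade")),
    config = lapply(config[setdiff(names(config), "simulate")],
                    function(x) if (is.atomic(x)) x else NULL),
    started = format(Sys.time()), counts = list())
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, null = "null")
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, mpath, auto_unbox = TRUE,
                           null = "null")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("load", {
    if (!is.null(config$simulate)) {
      .log(config, "simulating cohort (n=%d, seed=%d)",
           config$simulate$n_samples, config$simulate$seed)
      coh <- generate_cohort(config$simulate)
      write_cohort(coh, file.path(config$out_dir, "cohort"))
      coh
    } else {
      .log(config, "reading cohort from %s", config$input_dir)
      files <- list.files(config$input_dir, full.names = TRUE)
      manifest$input_checksums <- as.list(tools::md5sum(files))
      clin_path <- file.path(config$input_dir, "clinical.tsv")
      iv_path <- file.path(config$input_dir, "interval_report.tsv")
      coh <- list(
        samples = read_clinical(clin_path),
        interval_reports = if (file.exists(iv_path))
          read_interval_report(iv_path) else NULL,
        msi_marker_calls = if (file.exists(
          file.path(config$input_dir, "msi_markers.tsv")))
          read_msi_markers(file.path(config$input_dir, "msi_markers.tsv"))
        else NULL,
        methylation_calls = if (file.exists(
          file.path(config$input_dir, "methylation.tsv")))
          read_methylation(file.path(config$input_dir, "methylation.tsv"))
        else NULL,
        truth = NULL)
      class(coh) <- "crc_cohort"
      coh
    }
  })
  manifest$counts$samples <- nrow(cohort$samples)
  out <- list(cohort = cohort)
  tsv <- function(x, name) write.table(
    x, file.path(config$out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  have_cgh <- !is.null(cohort$interval_reports) &&
    nrow(cohort$interval_reports) > 0
  if (have_cgh) {
    out$calls <- stage("cgh_filter", {
      calls <- filter_by_fold(cohort$interval_reports,
                              config$gain_fold, config$loss_fold)
      .log(config, "fold filter kept %d of %d intervals", nrow(calls),
           nrow(cohort$interval_reports))
      tsv(calls, "calls.tsv")
      calls
    })
    manifest$counts$calls <- nrow(out$calls)
    if (!is.null(config$annotation)) {
      out$gene_events <- stage("gene_intersection", {
        ann <- if (is.character(config$annotation))
          read_gene_annotation(config$annotation) else config$annotation
        ev <- intersect_genes(out$calls, ann)
        .log(config, "gene intersection: %d events", nrow(ev))
        tsv(ev, "gene_events.tsv")
        ev
      })
      manifest$counts$gene_events <- nrow(out$gene_events)
    }
    out$chromosome_summary <- stage("chromosome_summary", {
      cs <- chromosome_summary(out$calls, cohort$samples)
      tsv(cs, "chromosome_summary.tsv")
      cs
    })
    out$per_sample_totals <- per_sample_totals(out$calls,
                                               cohort$samples$sample)
  } else {
    .log(config,
         "no interval report: statistics-only mode, skipping CGH, matrix and parsimony stages")
  }

  if (!is.null(cohort$msi_marker_calls) &&
      nrow(cohort$msi_marker_calls) > 0) {
    out$msi <- stage("msi", {
      st <- classify_msi(cohort$msi_marker_calls)
      .log(config, "MSI: %s", paste(names(cohort_msi_table(st)),
                                    cohort_msi_table(st), collapse = ", ",
                                    sep = "="))
      tsv(st, "msi_status.tsv")
      st
    })
    manifest$counts$msi_classified <- nrow(out$msi)
  }

  if (!is.null(cohort$methylation_calls) &&
      nrow(cohort$methylation_calls) > 0) {
    out$methylation <- stage("methylation", {
      mt <- methylation_table(cohort$methylation_calls, cohort$samples)
      tsv(mt, "methylation_associations.tsv")
      mt
    })
    manifest$counts$methylation_rows <- nrow(out$methylation)
  }

  if (nrow(cohort$samples) > 0)
    out$msi_table <- stage("cohort_stats", {
      mt <- msi_association_table(cohort$samples)
      tsv(mt$age, "msi_age_summary.tsv")
      mt
    })
  if (nrow(cohort$samples) > 0 &&
      "aberration_count" %in% names(cohort$samples)) {
    out$aberration_table <- stage("cohort_stats", {
      at <- aberration_summary_table(cohort$samples)
      tsv(at$msi$summary, "aberration_by_msi.tsv")
      at
    })
  }

  if (have_cgh && nrow(cohort$samples) >= 3) {
    out$matrix <- stage("polarity_matrix", {
      m <- build_matrix(out$calls, config$merge_tolerance_bp,
                        config$matrix_mode)
      .log(config, "polarity matrix: %d specimens x %d characters",
           nrow(m), ncol(m))
      write_phylip_discrete(m, file.path(config$out_dir, "matrix.phy"))
      write.table(attr(m, "character_map"),
                  file.path(config$out_dir, "character_map.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      m
    })
    manifest$counts$characters <- ncol(out$matrix)
    out$fit <- stage("parsimony", {
      fit <- parsimony_search(out$matrix, method = config$method,
                              model = config$model, seed = config$seed,
                              n_starts = config$n_starts)
      .log(config, "parsimony (%s): best length %d, %d optimal tree(s)",
           fit$method, fit$best_length, length(fit$trees))
      fit
    })
    out$cladogram <- stage("cladogram", {
      cl <- if (length(out$fit$trees) > 1)
        strict_consensus(out$fit) else root_and_annotate(out$fit)
      write_cladogram(cl, file.path(config$out_dir, "cladogram"))
      cl
    })
    manifest$counts$optimal_trees <- length(out$fit$trees)
  }

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, null = "null")
  .log(config, "pipeline complete: %s", config$out_dir)
  invisible(out)
}

.fmt_iqr <- function(s)
  sprintf("%s (%s-%s)", .fmt_num(s$median), .fmt_num(s$q1), .fmt_num(s$q3))

#' Render the pipeline's summary tables as aligned text
#'
#' Produces a human-readable report of the MSI association table, the
#' aberration-count table (median and 25-75% type-6 interquartiles), and
#' -- when CGH stages ran -- the per-chromosome counts with their
#' `total = amplifications + deletions` conservation check, and the
#' cladogram node summary.
#'
#' @param outputs The list returned by [run_pipeline()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
report_tables <- function(outputs) {
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  if (nrow(outputs$cohort$samples) == 0) {
    add("no samples")
    cat(ln, sep = "\n")
    return(invisible(ln))
  }
  mt <- outputs$msi_table
  add("== MSI status and age ==")
  add("MSI tally: MSS %d, MSI-L %d, MSI-H %d",
      mt$msi_tally[["MSS"]], mt$msi_tally[["MSI-L"]],
      mt$msi_tally[["MSI-H"]])
  for (i in seq_len(nrow(mt$age)))
    add("  age, %s: %s", mt$age$group[i], .fmt_iqr(mt$age[i, ]))
  if (!is.null(outputs$aberration_table)) {
    add("")
    add("== Aberration counts (median, 25-75%% interquartile) ==")
    for (nm in names(outputs$aberration_table)) {
      s <- outputs$aberration_table[[nm]]$summary
      for (i in seq_len(nrow(s)))
        add("  %s = %s: %s", nm, s$group[i], .fmt_iqr(s[i, ]))
    }
  }
  if (!is.null(outputs$chromosome_summary)) {
    cs <- outputs$chromosome_summary
    add("")
    add("== Aberrations per chromosome ==")
    add("  %-6s %6s %6s %6s  (conservation: total = amp + del %s)",
        "chrom", "total", "amp", "del",
        if (all(cs$total == cs$amplifications + cs$deletions)) "OK"
        else "VIOLATED")
    for (i in seq_len(nrow(cs)))
      add("  %-6s %6d %6d %6d", cs$chrom[i], cs$total[i],
          cs$amplifications[i], cs$deletions[i])
  }
  if (!is.null(outputs$cladogram)) {
    add("")
    add("== Cladogram ==")
    nt <- outputs$cladogram$node_table
    nd <- nt[grepl("^Nd", nt$node), , drop = FALSE]
    for (i in seq_len(min(nrow(nd), 15L)))
      add("  %s: n=%d%s", nd$node[i], nd$n_leaves[i],
          ifelse(nzchar(nd$synapomorphies[i]),
                 paste0("; defined by ", nd$synapomorphies[i]), ""))
  }
  cat(ln, sep = "\n")
  invisible(ln)
}
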