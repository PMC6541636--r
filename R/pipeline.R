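#' Assemble a pipeline configuration
#'
#' Inputs may be in-memory objects (tibbles, \code{signal_track}s, a
#' \code{count_matrix}) or file paths; paths are loaded during
#' [run_pipeline()] with the package readers. All thresholds default to the
#' package-wide analysis constants: 1.5 kb promoter flank and cutoff, 1.5 kb
#' width change, 1-fold (doubling) height change, p < 0.05, 2-fold
#' expression change, 2.5 kb TSS flank.
#'
#' @param peaks_control,peaks_mutant Peak tibbles or BED/narrowPeak paths.
#' @param genes Gene-model tibble or annotation path.
#' @param chrom_sizes Named vector, tibble or chrom-sizes path.
#' @param tracks_control,tracks_mutant Lists of \code{signal_track}s or
#'   bedGraph paths (one per replicate).
#' @param counts Optional \code{count_matrix}; when NULL it is derived from
#'   track mass over the shared regions.
#' @param de_table DE tibble or TSV path (gene_id, fold_change).
#' @param peak_dialect,gene_dialect File dialects for path inputs.
#' @param promoter_flank,promoter_cutoff,width_delta_bp,height_fold_delta,alpha,fc_threshold,tss_flank,min_overlap
#'   Analysis thresholds.
#' @param height_stat Peak-height summary statistic.
#' @param effective_genome_size For 1x normalization (default: genome size).
#' @param compute_tss_matrix Whether to build the TSS matrix/metaprofile in
#'   the report (off by default; it is the most expensive stage).
#' @param seed Seed for the Monte-Carlo fallback of the differential test.
#' @param outdir Optional directory for stage outputs.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(peaks_control, peaks_mutant, genes, chrom_sizes,
                            tracks_control = NULL, tracks_mutant = NULL,
                            counts = NULL, de_table = NULL,
                            peak_dialect = "BED6", gene_dialect = "BED12",
                            promoter_flank = 1500, promoter_cutoff = 1500,
                            width_delta_bp = 1500, height_fold_delta = 1,
                            alpha = 0.05, fc_threshold = 2, tss_flank = 2500,
                            min_overlap = 1, height_stat = "mean",
                            effective_genome_size = NULL,
                            compute_tss_matrix = FALSE,
                            seed = 1L, outdir = NULL) {
  structure(
    list(
      peaks_control = peaks_control, peaks_mutant = peaks_mutant,
      genes = genes, chrom_sizes = chrom_sizes,
      tracks_control = tracks_control, tracks_mutant = tracks_mutant,
      counts = counts, de_table = de_table,
      peak_dialect = peak_dialect, gene_dialect = gene_dialect,
      promoter_flank = promoter_flank, promoter_cutoff = promoter_cutoff,
      width_delta_bp = width_delta_bp, height_fold_delta = height_fold_delta,
      alpha = alpha, fc_threshold = fc_threshold, tss_flank = tss_flank,
      min_overlap = min_overlap, height_stat = height_stat,
      effective_genome_size = effective_genome_size,
      compute_tss_matrix = compute_tss_matrix,
      seed = as.integer(seed), outdir = outdir
    ),
    class = "pipeline_config"
  )
}

#' Build a pipeline configuration straight from a synthetic dataset
#' @param dataset From [simulate_dataset()].
#' @param ... Overrides passed to [pipeline_config()].
#' @export
pipeline_config_synthetic <- function(dataset, ...) {
  reps <- dataset$config$replicates
  tr <- dataset$signal$tracks
  pipeline_config(
    peaks_control = dataset$peaks$control,
    peaks_mutant = dataset$peaks$mutant,
    genes = dataset$genome$genes,
    chrom_sizes = dataset$genome$chrom_sizes,
    tracks_control = tr[seq_len(reps)],
    tracks_mutant = tr[reps + seq_len(reps)],
    counts = dataset$signal$counts,
    de_table = dataset$expression$table,
    seed = dataset$config$seed,
    ...
  )
}

#' Validate a pipeline configuration
#'
#' Checks every path, threshold and enum, aggregating problems instead of
#' stopping at the first.
#'
#' @param config A \code{pipeline_config}.
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  need <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  path_ok <- function(x) !is.character(x) || all(file.exists(x))
  for (field in c("peaks_control", "peaks_mutant", "genes", "de_table")) {
    x <- config[[field]]
    if (is.null(x) && field == "de_table") next
    need(!is.null(x), sprintf("%s: missing input", field))
    if (!is.null(x)) need(path_ok(x), sprintf("%s: file not found", field))
  }
  for (field in c("tracks_control", "tracks_mutant")) {
    x <- config[[field]]
    if (!is.null(x)) {
      need(path_ok(unlist(x[vapply(x, is.character, logical(1))])),
           sprintf("%s: file not found", field))
    }
  }
  need(!is.null(config$chrom_sizes), "chrom_sizes: missing input")
  for (th in c("promoter_flank", "promoter_cutoff", "width_delta_bp",
               "height_fold_delta", "alpha", "fc_threshold", "tss_flank",
               "min_overlap")) {
    need(is.numeric(config[[th]]) && length(config[[th]]) == 1 && config[[th]] > 0,
         sprintf("%s: must be a positive number", th))
  }
  if (is.numeric(config$alpha) && length(config$alpha) == 1) {
    need(config$alpha < 1, "alpha: must be below 1")
  }
  need(config$height_stat %in% c("mean", "max"),
       "height_stat: must be 'mean' or 'max'")
  errs
}

#' Create a stage cache for partial pipeline reruns
#' @return An environment usable as the \code{cache} of [run_pipeline()].
#' @export
new_pipeline_cache <- function() new.env(parent = emptyenv())

run_stage <- function(cache, log, name, inputs, fn) {
  key <- paste0(name, "_", rlang::hash(inputs))
  if (!is.null(cache) && !is.null(cache[[key]])) {
    log$events <- c(log$events, setNames("cached", name))
    return(cache[[key]])
  }
  t0 <- proc.time()[["elapsed"]]
  out <- fn()
  log$events <- c(log$events, setNames("computed", name))
  log$timing[[name]] <- proc.time()[["elapsed"]] - t0
  if (!is.null(cache)) cache[[key]] <- out
  out
}

resolve_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1) loader(x) else x
}

#' Run the full peak-redistribution analysis
#'
#' Executes the stages in dependency order: annotation (TSS table and
#' genome-wide promoter list), peak-set partition, replicate signal
#' summaries, differential occupancy on the shared regions, shape
#' classification, merge into gene lists, expression integration, report.
#' With a \code{cache} (see [new_pipeline_cache()]), stages whose inputs are
#' unchanged between runs are reused; the stage log records what was
#' computed versus cached.
#'
#' @param config A \code{pipeline_config}.
#' @param cache Optional cache environment shared across runs.
#' @return A list of class \code{pipeline_report}: stage outputs
#'   (\code{partition}, \code{shape_calls}, \code{differential},
#'   \code{gene_lists}, \code{de}), the \code{summary} fraction tibble,
#'   headline counts in \code{report}, and \code{stage_log}.
#' @export
run_pipeline <- function(config, cache = NULL) {
  errs <- validate_config(config)
  if (length(errs) > 0) {
    abort(paste0("invalid pipeline config:\n", paste("-", errs, collapse = "\n")))
  }
  log <- new.env()
  log$events <- character()
  log$timing <- list()

  chrom_sizes <- resolve_input(config$chrom_sizes, read_chrom_sizes)
  genes <- resolve_input(config$genes, function(p)
    read_gene_models(p, dialect = config$gene_dialect))
  pc <- resolve_input(config$peaks_control, function(p)
    read_peaks(p, dialect = config$peak_dialect, condition = "control"))
  pm <- resolve_input(config$peaks_mutant, function(p)
    read_peaks(p, dialect = config$peak_dialect, condition = "mutant"))
  load_tracks <- function(x, cond) {
    if (is.null(x)) return(NULL)
    map(x, function(t) {
      if (is.character(t)) load_coverage(t, chrom_sizes, condition = cond) else t
    })
  }
  trc <- load_tracks(config$tracks_control, "control")
  trm <- load_tracks(config$tracks_mutant, "mutant")

  ann <- run_stage(cache, log, "annotation", list(genes, chrom_sizes,
                                                  config$promoter_flank), function() {
    tss <- tss_table(genes)
    gwpl <- build_gwpl(genes, chrom_sizes, flank = config$promoter_flank)
    list(tss = tss, gwpl = gwpl)
  })

  partition <- run_stage(cache, log, "partition",
                         list(pc, pm, config$min_overlap), function() {
    partition_peak_sets(pc, pm, min_overlap = config$min_overlap)
  })

  signal <- run_stage(cache, log, "signal",
                      list(partition, trc, trm, config$height_stat,
                           config$effective_genome_size), function() {
    if (is.null(trc) || is.null(trm)) return(NULL)
    egs <- config$effective_genome_size %||% sum(as_chrom_sizes(chrom_sizes))
    norm_c <- map(trc, normalize_to_1x, effective_genome_size = egs)
    norm_m <- map(trm, normalize_to_1x, effective_genome_size = egs)
    sh <- partition$shared
    ctrl_peaks <- tibble(chrom = sh$control_chrom, start = sh$control_start,
                         end = sh$control_end, peak_id = sh$control_peak_id)
    mut_peaks <- tibble(chrom = sh$mutant_chrom, start = sh$mutant_start,
                        end = sh$mutant_end, peak_id = sh$mutant_peak_id)
    list(
      control_summary = summarize_peak_signal(norm_c, ctrl_peaks,
                                              height_stat = config$height_stat),
      mutant_summary = summarize_peak_signal(norm_m, mut_peaks,
                                             height_stat = config$height_stat),
      tracks_control = norm_c, tracks_mutant = norm_m
    )
  })

  differential <- run_stage(cache, log, "differential",
                            list(config$counts, partition, config$alpha,
                                 config$seed), function() {
    if (is.null(config$counts)) return(NULL)
    cm <- config$counts
    shared_ids <- intersect(rownames(cm$counts), partition$shared$mutant_peak_id)
    if (length(shared_ids) == 0) return(NULL)
    sub <- new_count_matrix(
      cm$counts[shared_ids, , drop = FALSE],
      cm$regions[match(shared_ids, cm$regions$region_id), , drop = FALSE],
      cm$conditions, cm$library_sizes
    )
    differential_test(sub, alpha = config$alpha, seed = config$seed)
  })

  shape_calls <- run_stage(cache, log, "classify",
                           list(partition, signal, config$width_delta_bp,
                                config$height_fold_delta), function() {
    if (is.null(signal)) return(NULL)
    classify_shared_peaks(
      partition$shared, signal$control_summary, signal$mutant_summary,
      shape_thresholds(config$width_delta_bp, config$height_fold_delta,
                       config$height_stat)
    )
  })

  gene_lists <- run_stage(cache, log, "merge",
                          list(shape_calls, differential, partition, ann),
                          function() {
    if (is.null(shape_calls)) return(NULL)
    dtab <- if (is.null(differential)) {
      tibble(region_id = character(), call = character())
    } else differential
    merge_with_differential(shape_calls, dtab, partition, ann$gwpl)
  })

  de <- run_stage(cache, log, "expression",
                  list(config$de_table, config$fc_threshold), function() {
    if (is.null(config$de_table)) return(NULL)
    filter_de_genes(resolve_input(config$de_table, function(p)
      readr::read_tsv(p, show_col_types = FALSE)), config$fc_threshold)
  })

  tssmat <- NULL
  if (isTRUE(config$compute_tss_matrix) && !is.null(signal)) {
    tssmat <- run_stage(cache, log, "tss_matrix",
                        list(signal, ann, config$tss_flank), function() {
      map(c(signal$tracks_control[1], signal$tracks_mutant[1]), function(tr) {
        tss_matrix(tr, ann$tss, flank = config$tss_flank)
      })
    })
  }

  summary_tbl <- summarize_partition(partition, shape_calls)
  report <- list(
    n_peaks = sum(summary_tbl$n[summary_tbl$level == "partition"]) +
      nrow(partition$shared),
    partition_fractions = summary_tbl
  )
  if (!is.null(de)) {
    n_de <- c(up = sum(de$direction == "up"),
              down = sum(de$direction == "down"),
              unchanged = sum(de$direction == "unchanged"))
    report$de_fractions <- tibble(
      direction = names(n_de),
      n = as.integer(n_de),
      fraction = as.numeric(n_de) / nrow(de)
    )
  }
  if (!is.null(gene_lists) && !is.null(de)) {
    report$up_vs_broader_higher <- intersect_gene_lists(
      de$gene_id[de$direction == "up"], gene_lists$broader_higher_genes
    )
    report$down_vs_narrower_lower <- intersect_gene_lists(
      de$gene_id[de$direction == "down"], gene_lists$narrower_lower_genes
    )
  }

  out <- list(
    partition = partition, annotation = ann, signal = signal,
    differential = differential, shape_calls = shape_calls,
    gene_lists = gene_lists, de = de, tss_matrices = tssmat,
    summary = summary_tbl, report = report,
    stage_log = list(events = log$events, timing = log$timing),
    config = config
  )
  class(out) <- "pipeline_report"
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$summary)
  if (!is.null(x$report$de_fractions)) {
    cat("expression directions:\n")
    print(x$report$de_fractions)
  }
  invisible(x)
}

write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_partition_beds(report$partition, file.path(dir, "partition"))
  readr::write_tsv(report$summary, file.path(dir, "summary.tsv"))
  if (!is.null(report$shape_calls)) {
    readr::write_tsv(report$shape_calls, file.path(dir, "shape_calls.tsv"))
  }
  if (!is.null(report$differential)) {
    write_differential_tsv(report$differential, file.path(dir, "differential.tsv"))
  }
  if (!is.null(report$gene_lists)) {
    for (nm in setdiff(names(report$gene_lists), "multi_list_genes")) {
      readr::write_lines(report$gene_lists[[nm]],
                         file.path(dir, paste0(nm, ".txt")))
    }
  }
  invisible(dir)
}
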