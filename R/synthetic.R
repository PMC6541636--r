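#' Configuration for the synthetic two-condition ChIP-seq dataset
#'
#' The defaults plant the study conditions the pipeline is built for: 84 /
#' 7 / 8.7 percent shared / control-only / mutant-only peak sites (the three
#' proportions are renormalized to sum to one), 2.1 percent of shared sites
#' broader+higher and 3 percent narrower+lower, 4.3 / 3.2 percent of genes
#' up- / down-regulated more than two-fold, and four replicates per
#' condition. Planted effects keep a configurable margin from the
#' classification thresholds so the truth table is unambiguous.
#'
#' Peaks and genes are laid out on a fixed grid of non-overlapping slots
#' (one site per slot, spacing \code{slot_pitch}), so planted peaks never
#' collide and every TSS is well separated. Expected fragment counts per
#' region are \code{height * width / fragment_len * depth} with
#' \code{fragment_len = 100} bp; coverage tracks are rectangular plateaus
#' whose mass equals \code{count * fragment_len}, keeping counts and
#' coverage consistent.
#'
#' @param seed Master seed; each generator stage derives its own stream.
#' @param n_chroms,chrom_length Toy genome shape.
#' @param n_genes Number of genes (one TSS each, strand-balanced).
#' @param n_peaks Number of peak sites.
#' @param prop_shared,prop_control_only,prop_mutant_only Partition
#'   proportions (renormalized to sum to 1).
#' @param prop_broader_higher,prop_narrower_lower Shape proportions among
#'   shared sites.
#' @param prop_up,prop_down Planted DE proportions.
#' @param promoter_peak_frac Fraction of peak sites centred on a TSS (capped
#'   at one per gene).
#' @param width_delta_margin Extra bp beyond the 1500 bp width threshold for
#'   planted broader/narrower sites (and the gap kept below it for unchanged
#'   sites).
#' @param height_ratio_margin Extra fold beyond the 2-fold height threshold
#'   for planted higher/lower sites.
#' @param fc_margin Extra fold beyond the 2-fold expression threshold for
#'   planted up/down genes.
#' @param replicates Replicates per condition (default 4).
#' @param depth Sequencing-depth multiplier.
#' @param noise \code{"poisson"} (default) or \code{"none"} for exact
#'   expected counts.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 4L, chrom_length = 15e6,
                             n_genes = 1200L, n_peaks = 2000L,
                             prop_shared = 0.84, prop_control_only = 0.07,
                             prop_mutant_only = 0.087,
                             prop_broader_higher = 0.021,
                             prop_narrower_lower = 0.030,
                             prop_up = 0.043, prop_down = 0.032,
                             promoter_peak_frac = 0.5,
                             width_delta_margin = 500,
                             height_ratio_margin = 0.5,
                             fc_margin = 0.5,
                             replicates = 4L, depth = 1,
                             noise = c("poisson", "none")) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = chrom_length, n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks),
    prop_shared = prop_shared, prop_control_only = prop_control_only,
    prop_mutant_only = prop_mutant_only,
    prop_broader_higher = prop_broader_higher,
    prop_narrower_lower = prop_narrower_lower,
    prop_up = prop_up, prop_down = prop_down,
    promoter_peak_frac = promoter_peak_frac,
    width_delta_margin = width_delta_margin,
    height_ratio_margin = height_ratio_margin,
    fc_margin = fc_margin,
    replicates = as.integer(replicates), depth = depth,
    noise = match.arg(noise),
    slot_pitch = 10000, fragment_len = 100,
    background_height = 0.2
  )
  part <- c(cfg$prop_shared, cfg$prop_control_only, cfg$prop_mutant_only)
  if (any(part < 0) || sum(part) > 1 + 1e-9 || sum(part) <= 0) {
    abort("partition proportions must be nonnegative with sum in (0, 1]")
  }
  if (cfg$prop_broader_higher + cfg$prop_narrower_lower > 1) {
    abort("shape proportions exceed 1")
  }
  if (cfg$prop_up + cfg$prop_down > 1) abort("DE proportions exceed 1")
  if (cfg$width_delta_margin <= 0 || cfg$height_ratio_margin <= 0 ||
      cfg$fc_margin <= 0) {
    abort("planted-effect margins must be positive")
  }
  if (cfg$replicates < 2) abort("need at least 2 replicates per condition")
  if (cfg$depth <= 0) abort("depth must be positive")
  n_slots <- cfg$n_chroms * floor(cfg$chrom_length / cfg$slot_pitch)
  n_prom <- min(round(cfg$promoter_peak_frac * cfg$n_peaks), cfg$n_genes)
  if (cfg$n_genes + (cfg$n_peaks - n_prom) > n_slots) {
    abort("genome too small for the requested gene and peak density")
  }
  structure(cfg, class = "synthetic_config")
}

stage_seed <- function(cfg, stage) {
  cfg$seed + c(genome = 1e6L, peaks = 2e6L, counts = 3e6L,
               expression = 4e6L)[[stage]]
}

#' Generate the toy genome: gene models and chromosome sizes
#'
#' Genes occupy randomly chosen grid slots, one TSS per gene at the slot
#' centre; successive slots are \code{slot_pitch} apart so TSSs are always
#' separated by well over twice the promoter flank. Strands alternate to
#' stay balanced.
#'
#' @param cfg A [synthetic_config()].
#' @return List with \code{genes} (gene-model tibble as from
#'   [read_gene_models()]), \code{chrom_sizes}, and \code{slots} (the full
#'   slot table with \code{gene_id} NA for free slots).
#' @export
sim_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms),
                    paste0("chr", seq_len(cfg$n_chroms)))
  per_chrom <- floor(cfg$chrom_length / cfg$slot_pitch)
  slots <- tibble(
    chrom = rep(names(sizes), each = per_chrom),
    center = rep(as.numeric(seq_len(per_chrom)) * cfg$slot_pitch - cfg$slot_pitch / 2,
                 times = cfg$n_chroms)
  )
  with_private_seed(stage_seed(cfg, "genome"), {
    gene_slots <- sort(sample.int(nrow(slots), cfg$n_genes))
    body_up <- round(runif(cfg$n_genes, 500, 2000))
    body_dn <- round(runif(cfg$n_genes, 500, 2000))
    slots$gene_id <- NA_character_
    if (cfg$n_genes > 0) {
      slots$gene_id[gene_slots] <- sprintf("gene_%05d", seq_len(cfg$n_genes))
      strand <- rep(c("+", "-"), length.out = cfg$n_genes)
      g <- slots[gene_slots, , drop = FALSE]
      genes <- tibble(
        gene_id = g$gene_id,
        symbol = g$gene_id,
        chrom = g$chrom,
        start = as.integer(g$center - body_up),
        end = as.integer(g$center + body_dn),
        strand = strand,
        tss = as.list(as.integer(g$center))
      )
    } else {
      genes <- empty_gene_models()
    }
    list(genes = genes, chrom_sizes = sizes, slots = slots)
  })
}

#' Plant two-condition peak sets with known partition and shape categories
#'
#' Each peak site draws a partition category (shared / control-only /
#' mutant-only) and, when shared, a shape category. Planted width and height
#' deltas sit beyond the classification thresholds by the configured margins
#' for broader+higher and narrower+lower sites, and below the thresholds by
#' the same margins for unchanged sites, so noise-free classification
#' recovers the truth exactly.
#'
#' @param cfg A [synthetic_config()].
#' @param genome From [sim_genome()].
#' @return List with \code{control} and \code{mutant} peak tibbles and
#'   \code{truth} (one row per site: ids, category, planted widths and
#'   heights, promoter gene).
#' @export
sim_peaks <- function(cfg, genome) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_peaks
  slots <- genome$slots
  with_private_seed(stage_seed(cfg, "peaks"), {
    n_prom <- min(round(cfg$promoter_peak_frac * n), sum(!is.na(slots$gene_id)))
    gene_idx <- which(!is.na(slots$gene_id))
    free_idx <- which(is.na(slots$gene_id))
    chosen <- c(gene_idx[sample.int(length(gene_idx), n_prom)],
                free_idx[sample.int(length(free_idx), n - n_prom)])
    site <- slots[chosen, , drop = FALSE]

    part_p <- c(cfg$prop_shared, cfg$prop_control_only, cfg$prop_mutant_only)
    part_p <- part_p / sum(part_p)
    part <- sample(c("shared", "control_only", "mutant_only"), n,
                   replace = TRUE, prob = part_p)
    shape_p <- c(cfg$prop_broader_higher, cfg$prop_narrower_lower,
                 1 - cfg$prop_broader_higher - cfg$prop_narrower_lower)
    shape <- ifelse(
      part == "shared",
      sample(c("broader_higher", "narrower_lower", "unchanged"), n,
             replace = TRUE, prob = shape_p),
      part
    )

    wmarg <- cfg$width_delta_margin
    hmarg <- cfg$height_ratio_margin
    # control widths: narrower sites start wide so the mutant peak stays
    # comfortably positive after shrinking
    cw <- ifelse(shape == "narrower_lower",
                 round(runif(n, 3600, 4400)),
                 round(runif(n, 1600, 2400)))
    dw <- dplyr::case_when(
      shape == "broader_higher" ~ 1500 + wmarg + round(runif(n, 0, 400)),
      shape == "narrower_lower" ~ -(1500 + wmarg + round(runif(n, 0, 400))),
      .default = round(runif(n, -(1500 - wmarg - 100), 1500 - wmarg - 100))
    )
    mw <- cw + dw
    ch <- runif(n, 2.5, 6)
    ratio <- dplyr::case_when(
      shape == "broader_higher" ~ 2 + hmarg + runif(n, 0, 0.8),
      shape == "narrower_lower" ~ 1 / (2 + hmarg + runif(n, 0, 0.8)),
      .default = exp(runif(n, log(1 / (2 - hmarg)), log(2 - hmarg)))
    )
    mh <- ch * ratio

    site_id <- sprintf("site_%05d", seq_len(n))
    truth <- tibble(
      site_id = site_id,
      chrom = site$chrom,
      center = site$center,
      gene_id = site$gene_id,
      category = shape,
      in_control = part != "mutant_only",
      in_mutant = part != "control_only",
      control_width = ifelse(part != "mutant_only", cw, NA_real_),
      mutant_width = ifelse(part != "control_only", mw, NA_real_),
      control_height = ifelse(part != "mutant_only", ch, NA_real_),
      mutant_height = ifelse(part != "control_only", mh, NA_real_),
      control_peak_id = ifelse(part != "mutant_only", paste0("ctrl_", site_id),
                               NA_character_),
      mutant_peak_id = ifelse(part != "control_only", paste0("mut_", site_id),
                              NA_character_)
    )
    mk_peaks <- function(ids, widths, heights, condition) {
      keep <- !is.na(ids)
      tibble(
        chrom = truth$chrom[keep],
        start = as.integer(round(truth$center[keep] - widths[keep] / 2)),
        end = as.integer(round(truth$center[keep] + widths[keep] / 2)),
        peak_id = ids[keep],
        score = heights[keep],
        summit_offset = NA_integer_,
        condition = condition
      ) |> arrange(.data$chrom, .data$start)
    }
    list(
      control = mk_peaks(truth$control_peak_id, truth$control_width,
                         truth$control_height, "control"),
      mutant = mk_peaks(truth$mutant_peak_id, truth$mutant_width,
                        truth$mutant_height, "mutant"),
      truth = truth
    )
  })
}

#' Simulate replicate fragment counts and coverage tracks
#'
#' Expected counts per region and replicate are
#' \code{height * width / fragment_len * depth}; sites absent from a
#' condition contribute background-level counts there. Poisson noise (or
#' none) is applied per replicate. Coverage is a rectangular plateau per
#' region whose mass equals \code{count * fragment_len}, so track mass and
#' counts stay consistent by construction.
#'
#' @param cfg A [synthetic_config()].
#' @param peaks From [sim_peaks()].
#' @param genome From [sim_genome()].
#' @return List with \code{counts} (a \code{count_matrix} over all sites,
#'   region ids = mutant peak id when present, else control peak id) and
#'   \code{tracks} (named list of \code{signal_track}s, conditions in the
#'   track attributes).
#' @export
sim_counts <- function(cfg, peaks, genome) {
  stopifnot(inherits(cfg, "synthetic_config"))
  tr <- peaks$truth
  n <- nrow(tr)
  # region used for counting/coverage per condition: the condition's own
  # peak when present, else the partner region at background height
  reg <- function(width_col) {
    partner <- if (width_col == "control_width") tr$mutant_width else tr$control_width
    w <- ifelse(is.na(tr[[width_col]]), partner, tr[[width_col]])
    tibble(chrom = tr$chrom,
           start = as.integer(round(tr$center - w / 2)),
           end = as.integer(round(tr$center + w / 2)))
  }
  reg_c <- reg("control_width")
  reg_m <- reg("mutant_width")
  h_c <- ifelse(is.na(tr$control_height), cfg$background_height, tr$control_height)
  h_m <- ifelse(is.na(tr$mutant_height), cfg$background_height, tr$mutant_height)
  lam_c <- h_c * (reg_c$end - reg_c$start) / cfg$fragment_len * cfg$depth
  lam_m <- h_m * (reg_m$end - reg_m$start) / cfg$fragment_len * cfg$depth
  reps <- cfg$replicates
  rep_ids <- c(paste0("control_rep", seq_len(reps)), paste0("mutant_rep", seq_len(reps)))
  conditions <- rep(c("control", "mutant"), each = reps)
  counts <- with_private_seed(stage_seed(cfg, "counts"), {
    draw <- function(lam) {
      if (cfg$noise == "none") round(lam) else rpois(length(lam), lam)
    }
    cbind(
      vapply(seq_len(reps), function(r) draw(lam_c), numeric(n)),
      vapply(seq_len(reps), function(r) draw(lam_m), numeric(n))
    )
  })
  colnames(counts) <- rep_ids
  region_id <- ifelse(is.na(tr$mutant_peak_id), tr$control_peak_id, tr$mutant_peak_id)
  rownames(counts) <- region_id
  regions <- bind_cols(tibble(region_id = region_id), reg_m)
  cm <- new_count_matrix(counts, regions, conditions)

  tracks <- setNames(vector("list", length(rep_ids)), rep_ids)
  for (k in seq_along(rep_ids)) {
    cond <- conditions[k]
    rg <- if (cond == "control") reg_c else reg_m
    cnt <- counts[, k]
    keep <- cnt > 0
    df <- tibble(
      chrom = rg$chrom[keep], start = rg$start[keep], end = rg$end[keep],
      value = cnt[keep] * cfg$fragment_len / (rg$end[keep] - rg$start[keep])
    )
    tracks[[k]] <- signal_track(df, genome$chrom_sizes,
                                replicate_id = rep_ids[k], condition = cond)
  }
  list(counts = cm, tracks = tracks)
}

#' Simulate a differential-expression table with planted up/down genes
#'
#' Planted up genes get fold changes above
#' \code{2 + fc_margin}; down genes below \code{1 / (2 + fc_margin)};
#' the rest are log-uniform strictly inside the unchanged band, so
#' [filter_de_genes()] recovers the planted directions exactly.
#'
#' @param cfg A [synthetic_config()].
#' @param genome From [sim_genome()].
#' @return List with \code{table} (tibble \code{gene_id},
#'   \code{fold_change}) and \code{truth} (adds \code{planted_direction}).
#' @export
sim_expression <- function(cfg, genome) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- genome$genes$gene_id
  n <- length(genes)
  with_private_seed(stage_seed(cfg, "expression"), {
    dir <- sample(c("up", "down", "unchanged"), n, replace = TRUE,
                  prob = c(cfg$prop_up, cfg$prop_down,
                           1 - cfg$prop_up - cfg$prop_down))
    hi <- 2 + cfg$fc_margin
    fc <- numeric(n)
    fc[dir == "up"] <- hi * exp(runif(sum(dir == "up"), 0, 1))
    fc[dir == "down"] <- 1 / (hi * exp(runif(sum(dir == "down"), 0, 1)))
    mid <- dir == "unchanged"
    band <- 2 - cfg$fc_margin
    fc[mid] <- exp(runif(sum(mid), log(1 / band), log(band)))
    table <- tibble(gene_id = genes, fold_change = fc)
    list(table = table,
         truth = mutate(table, planted_direction = dir))
  })
}

#' Generate the full synthetic dataset
#' @param cfg A [synthetic_config()].
#' @return List with \code{genome}, \code{peaks}, \code{signal} (counts and
#'   tracks) and \code{expression}; fully determined by the config seed.
#' @export
simulate_dataset <- function(cfg) {
  genome <- sim_genome(cfg)
  peaks <- sim_peaks(cfg, genome)
  signal <- sim_counts(cfg, peaks, genome)
  expression <- sim_expression(cfg, genome)
  list(config = cfg, genome = genome, peaks = peaks, signal = signal,
       expression = expression)
}

#' Naive threshold peak caller (test plumbing)
#'
#' Calls maximal runs of coverage at or above \code{threshold} that are at
#' least \code{min_width} bp long. Contiguous qualifying intervals are
#' merged; sub-threshold gaps split runs. This is deliberately simple test
#' plumbing for end-to-end runs, not a model-based caller.
#'
#' @param track A \code{signal_track}.
#' @param threshold Minimum coverage.
#' @param min_width Minimum run length in bp.
#' @param condition Label for the emitted peaks.
#' @return Peak tibble as from [read_peaks()].
#' @export
call_peaks_threshold <- function(track, threshold, min_width = 100,
                                 condition = "called") {
  df <- as_tibble(track) |>
    filter(.data$value >= threshold) |>
    arrange(.data$chrom, .data$start)
  if (nrow(df) == 0) return(empty_peaks(condition))
  runs <- df |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(.data$start > dplyr::lag(.data$end, default = -1L))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              score = max(.data$value), .groups = "drop") |>
    filter(.data$end - .data$start >= min_width)
  runs |>
    mutate(peak_id = paste0(condition, "_peak_", row_number()),
           summit_offset = NA_integer_, condition = condition) |>
    select("chrom", "start", "end", "peak_id", "score", "summit_offset",
           "condition") |>
    arrange(.data$chrom, .data$start)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits BED6 peak files, bedGraph tracks, a counts TSV with condition map,
#' a DE table, a BED gene annotation, a chrom-sizes TSV and truth tables,
#' mirroring the formats the file-based readers consume.
#'
#' @param dataset From [simulate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, a named list of paths.
#' @export
write_synthetic_files <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  g <- dataset$genome
  readr::write_tsv(tibble(names(g$chrom_sizes), as.integer(g$chrom_sizes)),
                   p("chrom.sizes"), col_names = FALSE)
  genes <- g$genes
  readr::write_tsv(tibble(genes$chrom, genes$start, genes$end, genes$gene_id,
                          0L, genes$strand),
                   p("genes.bed"), col_names = FALSE)
  wb <- function(pk, path) {
    readr::write_tsv(tibble(pk$chrom, pk$start, pk$end, pk$peak_id,
                            round(pk$score, 4), "."), path, col_names = FALSE)
  }
  wb(dataset$peaks$control, p("peaks_control.bed"))
  wb(dataset$peaks$mutant, p("peaks_mutant.bed"))
  for (nm in names(dataset$signal$tracks)) {
    tr <- dataset$signal$tracks[[nm]]
    readr::write_tsv(tibble(tr$chrom, tr$start, tr$end, signif(tr$value, 8)),
                     p(paste0(nm, ".bedGraph")), col_names = FALSE)
  }
  cm <- dataset$signal$counts
  readr::write_tsv(bind_cols(tibble(region_id = rownames(cm$counts)),
                             as_tibble(cm$counts)),
                   p("counts.tsv"))
  readr::write_tsv(tibble(replicate_id = colnames(cm$counts),
                          condition = cm$conditions),
                   p("conditions.tsv"), col_names = FALSE)
  readr::write_tsv(dataset$expression$table, p("expression.tsv"))
  readr::write_tsv(dataset$peaks$truth, p("truth_peaks.tsv"))
  readr::write_tsv(dataset$expression$truth, p("truth_expression.tsv"))
  invisible(list(dir = dir))
}
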