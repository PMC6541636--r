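#' Read a peak file (BED3, BED6 or narrowPeak)
#'
#' Peak coordinates follow the BED convention (0-based half-open). narrowPeak
#' column 10 is mapped to \code{summit_offset} (offset of the summit within
#' the peak; -1 in the file means "no summit" and becomes \code{NA}). Records
#' with \code{start >= end} are rejected with a reported count; peak ids are
#' generated from the condition label when the file carries none.
#'
#' @param file Path to the peak file.
#' @param dialect One of \code{"BED3"}, \code{"BED6"}, \code{"narrowPeak"}.
#' @param condition Condition label attached to every peak (e.g.
#'   \code{"control"} or \code{"mutant"}).
#' @return Tibble with columns \code{chrom}, \code{start}, \code{end},
#'   \code{peak_id}, \code{score}, \code{summit_offset}, \code{condition},
#'   sorted by (chrom, start).
#' @export
read_peaks <- function(file, dialect = c("BED6", "BED3", "narrowPeak"),
                       condition = "condition") {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(
    file, col_names = FALSE, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0) {
    warn(sprintf("empty peak file: %s", file))
    return(empty_peaks(condition))
  }
  min_cols <- c(BED3 = 3L, BED6 = 4L, narrowPeak = 10L)[[dialect]]
  if (ncol(raw) < min_cols) {
    abort(sprintf("%s requires >= %d columns, found %d", dialect, min_cols, ncol(raw)))
  }
  df <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    peak_id = if (dialect != "BED3" && ncol(raw) >= 4) raw[[4]] else NA_character_,
    score = if (dialect != "BED3" && ncol(raw) >= 5) as.numeric(raw[[5]]) else 0,
    summit_offset = if (dialect == "narrowPeak") as.integer(raw[[10]]) else NA_integer_
  )
  bad <- is.na(df$start) | is.na(df$end) | df$start >= df$end | df$start < 0
  if (any(bad)) {
    warn(sprintf("rejected %d invalid peak record(s) in %s", sum(bad), file))
    df <- df[!bad, , drop = FALSE]
  }
  df$score[is.na(df$score)] <- 0
  df$summit_offset[!is.na(df$summit_offset) & df$summit_offset < 0] <- NA_integer_
  if (anyNA(df$peak_id)) {
    df$peak_id <- paste0(condition, "_peak_", seq_len(nrow(df)))
  }
  df |>
    mutate(condition = condition) |>
    arrange(.data$chrom, .data$start)
}

empty_peaks <- function(condition = "condition") {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    peak_id = character(), score = numeric(), summit_offset = integer(),
    condition = rep(condition, 0)
  )
}

peak_summit <- function(peaks) {
  ifelse(
    is.na(peaks$summit_offset),
    (peaks$start + peaks$end) / 2,
    peaks$start + peaks$summit_offset
  )
}

#' Partition two-condition peak sets into shared and condition-specific peaks
#'
#' A peak is shared when it overlaps a peak of the other condition by at
#' least \code{min_overlap} bp. Shared peaks are matched one-to-one by greedy
#' mutual maximal overlap: candidate pairs are ranked by overlap (largest
#' first), ties broken by smaller summit distance (midpoint when no summit is
#' recorded), then by leftmost coordinates; each peak joins at most one pair.
#' Overlapping peaks left unmatched after pairing fall to the
#' condition-specific sets.
#'
#' @param control,mutant Peak tibbles from [read_peaks()].
#' @param min_overlap Minimum overlap in bp to call two peaks shared
#'   (default 1).
#' @return An object of class \code{peak_partition}: a list with
#'   \code{shared} (tibble of pairs, columns prefixed \code{control_} /
#'   \code{mutant_} plus \code{overlap_bp}), \code{control_only} and
#'   \code{mutant_only} (peak tibbles).
#' @export
partition_peak_sets <- function(control, mutant, min_overlap = 1L) {
  if (min_overlap < 1) abort("min_overlap must be >= 1")
  for (pk in list(control, mutant)) {
    if (nrow(pk) > 0 && anyDuplicated(pk$peak_id)) {
      abort("duplicated peak ids within a condition")
    }
  }
  cand <- interval_overlaps(control, mutant, min_overlap = min_overlap)
  if (nrow(cand) > 0) {
    sc <- peak_summit(control)[cand$idx_a]
    sm <- peak_summit(mutant)[cand$idx_b]
    ord <- order(
      -cand$overlap_bp, abs(sc - sm),
      control$start[cand$idx_a], mutant$start[cand$idx_b]
    )
    cand <- cand[ord, , drop = FALSE]
    taken_c <- rep(FALSE, nrow(control))
    taken_m <- rep(FALSE, nrow(mutant))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$idx_a[k]; j <- cand$idx_b[k]
      if (!taken_c[i] && !taken_m[j]) {
        keep[k] <- TRUE
        taken_c[i] <- TRUE
        taken_m[j] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  } else {
    pairs <- cand
    taken_c <- rep(FALSE, nrow(control))
    taken_m <- rep(FALSE, nrow(mutant))
  }
  shared <- bind_cols(
    control[pairs$idx_a, , drop = FALSE] |>
      select(-"condition") |>
      rename_with_prefix("control_"),
    mutant[pairs$idx_b, , drop = FALSE] |>
      select(-"condition") |>
      rename_with_prefix("mutant_"),
    tibble(overlap_bp = pairs$overlap_bp)
  ) |>
    arrange(.data$control_chrom, .data$control_start)
  out <- list(
    shared = shared,
    control_only = control[!taken_c, , drop = FALSE],
    mutant_only = mutant[!taken_m, , drop = FALSE]
  )
  structure(out, class = "peak_partition")
}

rename_with_prefix <- function(df, prefix) {
  names(df) <- paste0(prefix, names(df))
  df
}

#' @export
print.peak_partition <- function(x, ...) {
  n_sh <- nrow(x$shared); n_c <- nrow(x$control_only); n_m <- nrow(x$mutant_only)
  tot <- n_sh + n_c + n_m
  cat(sprintf(
    "<peak_partition> %d shared pair(s), %d control-only, %d mutant-only (%d peak sites)\n",
    n_sh, n_c, n_m, tot
  ))
  invisible(x)
}

#' Assign peaks to genes through promoter windows
#'
#' A gene is assigned to a peak when the peak overlaps one of the gene's
#' promoter windows by at least 1 bp (the interval join of peak calls with
#' the genome-wide promoter list). Peaks overlapping no window are retained
#' with \code{gene_id = NA} so the mapping covers every input peak.
#'
#' @param peaks Peak tibble.
#' @param gwpl Promoter-window tibble from [build_gwpl()].
#' @return Tibble with columns \code{peak_id}, \code{gene_id} (one row per
#'   peak-gene assignment; \code{NA} gene for unassigned peaks).
#' @export
assign_peaks_to_genes <- function(peaks, gwpl) {
  if (nrow(peaks) == 0) return(tibble(peak_id = character(), gene_id = character()))
  hits <- interval_overlaps(peaks, gwpl, min_overlap = 1L)
  assigned <- tibble(
    peak_id = peaks$peak_id[hits$idx_a],
    gene_id = gwpl$gene_id[hits$idx_b]
  ) |> distinct()
  unassigned <- tibble(
    peak_id = setdiff(peaks$peak_id, assigned$peak_id),
    gene_id = NA_character_
  )
  bind_rows(assigned, unassigned) |> arrange(.data$peak_id)
}

#' Genes hit by a set of peaks
#' @param peaks Peak tibble.
#' @param gwpl Promoter-window tibble.
#' @return Character vector of distinct gene ids.
#' @export
peak_gene_set <- function(peaks, gwpl) {
  m <- assign_peaks_to_genes(peaks, gwpl)
  sort(unique(m$gene_id[!is.na(m$gene_id)]))
}

#' Write the components of a peak partition as BED6 files
#' @param partition A \code{peak_partition}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_partition_beds <- function(partition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed6 <- function(pk, path) {
    readr::write_tsv(
      tibble(pk$chrom, pk$start, pk$end, pk$peak_id, pk$score, "."),
      path, col_names = FALSE
    )
  }
  paths <- file.path(dir, c("shared_control.bed", "shared_mutant.bed",
                            "control_only.bed", "mutant_only.bed", "pairs.tsv"))
  sh <- partition$shared
  write_bed6(tibble(chrom = sh$control_chrom, start = sh$control_start,
                    end = sh$control_end, peak_id = sh$control_peak_id,
                    score = sh$control_score), paths[1])
  write_bed6(tibble(chrom = sh$mutant_chrom, start = sh$mutant_start,
                    end = sh$mutant_end, peak_id = sh$mutant_peak_id,
                    score = sh$mutant_score), paths[2])
  write_bed6(partition$control_only, paths[3])
  write_bed6(partition$mutant_only, paths[4])
  readr::write_tsv(
    sh |> select("control_peak_id", "mutant_peak_id", "overlap_bp"), paths[5]
  )
  invisible(paths)
}
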