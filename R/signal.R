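#' Load a replicate coverage track
#'
#' Reads per-base fragment coverage as a step function stored sparsely: a
#' tibble of non-overlapping intervals with a nonnegative \code{value};
#' positions not covered by any interval are implicitly zero. bedGraph is the
#' native text format; bigWig is routed through \pkg{rtracklayer} when
#' available.
#'
#' @param file Path to the coverage file.
#' @param chrom_sizes Named vector or two-column tibble of chromosome sizes.
#' @param dialect \code{"bedGraph"} or \code{"bigWig"}.
#' @param replicate_id,condition Labels stored as attributes on the track.
#' @return A \code{signal_track}: tibble (\code{chrom}, \code{start},
#'   \code{end}, \code{value}) with attributes \code{chrom_sizes},
#'   \code{replicate_id}, \code{condition}.
#' @export
load_coverage <- function(file, chrom_sizes, dialect = c("bedGraph", "bigWig"),
                          replicate_id = NA_character_, condition = NA_character_) {
  dialect <- match.arg(dialect)
  sizes <- as_chrom_sizes(chrom_sizes)
  if (dialect == "bigWig") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("rtracklayer is required to read bigWig")
    }
    gr <- as.data.frame(rtracklayer::import(file, format = "BigWig"))
    df <- tibble(
      chrom = as.character(gr$seqnames),
      start = as.integer(gr$start) - 1L,
      end = as.integer(gr$end),
      value = as.numeric(gr$score)
    )
  } else {
    raw <- readr::read_tsv(
      file, col_names = c("chrom", "start", "end", "value"),
      col_types = "ciid", comment = "#", show_col_types = FALSE
    )
    raw <- raw[!grepl("^track", raw$chrom), , drop = FALSE]
    df <- raw
  }
  if (nrow(df) == 0) {
    warn(sprintf("empty coverage file: %s", file))
    return(new_signal_track(df[0, ], sizes, replicate_id, condition))
  }
  if (any(is.na(df$start) | is.na(df$end) | df$start >= df$end | df$start < 0)) {
    abort("invalid coverage interval (need 0 <= start < end)")
  }
  if (any(df$value < 0)) abort("negative coverage value")
  unknown <- !(df$chrom %in% names(sizes))
  if (any(unknown)) {
    warn(sprintf("dropped %d coverage interval(s) on unknown chromosomes", sum(unknown)))
    df <- df[!unknown, , drop = FALSE]
  }
  if (any(df$end > sizes[df$chrom])) abort("coverage interval beyond chromosome end")
  df <- arrange(df, .data$chrom, .data$start)
  overl <- df |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start < dplyr::lag(.data$end, default = -1L)),
              .groups = "drop")
  if (any(overl$bad)) abort("overlapping bedGraph intervals")
  new_signal_track(df, sizes, replicate_id, condition)
}

new_signal_track <- function(df, sizes, replicate_id = NA_character_,
                             condition = NA_character_) {
  df <- as_tibble(df[, c("chrom", "start", "end", "value")])
  structure(df, class = c("signal_track", class(tibble())),
            chrom_sizes = sizes, replicate_id = replicate_id,
            condition = condition)
}

#' Build a signal track from an in-memory interval tibble
#' @param df Tibble with \code{chrom}, \code{start}, \code{end}, \code{value}.
#' @inheritParams load_coverage
#' @export
signal_track <- function(df, chrom_sizes, replicate_id = NA_character_,
                         condition = NA_character_) {
  sizes <- as_chrom_sizes(chrom_sizes)
  assert_intervals(df, "signal track")
  if (any(df$value < 0)) abort("negative coverage value")
  new_signal_track(arrange(df, .data$chrom, .data$start), sizes,
                   replicate_id, condition)
}

#' Total coverage mass of a track
#' @param track A \code{signal_track}.
#' @return Sum of \code{value * width} over all intervals.
#' @export
track_mass <- function(track) {
  sum(track$value * (track$end - track$start))
}

#' Scale a coverage track to 1x genome-wide mean coverage
#'
#' Multiplies coverage by \code{effective_genome_size / total_mass} so that
#' the mean coverage over the effective genome equals 1. Idempotent and
#' linear: normalizing an already-normalized track (or any scalar multiple of
#' it) returns the same track.
#'
#' @param track A \code{signal_track}.
#' @param effective_genome_size Effective genome size in bp; defaults to the
#'   sum of the track's chromosome sizes.
#' @return The normalized \code{signal_track}.
#' @export
normalize_to_1x <- function(track, effective_genome_size = NULL) {
  sizes <- attr(track, "chrom_sizes")
  if (is.null(effective_genome_size)) effective_genome_size <- sum(sizes)
  if (effective_genome_size <= 0) abort("effective_genome_size must be positive")
  mass <- track_mass(track)
  if (mass == 0) abort("empty track cannot be normalized")
  out <- mutate(as_tibble(track), value = .data$value * (effective_genome_size / mass))
  new_signal_track(out, sizes, attr(track, "replicate_id"), attr(track, "condition"))
}

# Mean coverage (and max) of a step-function track over query regions.
# Gaps count as zero; the mean divides by the full region width.
region_signal_stats <- function(track, regions) {
  assert_intervals(regions, "regions")
  n <- nrow(regions)
  mean_v <- numeric(n)
  max_v <- numeric(n)
  covered <- numeric(n)
  if (nrow(track) > 0 && n > 0) {
    hits <- interval_overlaps(regions, as_tibble(track), min_overlap = 1L)
    if (nrow(hits) > 0) {
      w <- hits$overlap_bp
      v <- track$value[hits$idx_b]
      mean_v <- as.numeric(tapply(w * v, factor(hits$idx_a, levels = seq_len(n)),
                                  sum, default = 0))
      max_v <- as.numeric(tapply(v, factor(hits$idx_a, levels = seq_len(n)),
                                 max, default = 0))
      covered <- as.numeric(tapply(w, factor(hits$idx_a, levels = seq_len(n)),
                                   sum, default = 0))
    }
  }
  width <- regions$end - regions$start
  tibble(
    mean = mean_v / width,
    max = ifelse(covered < width, pmax(max_v, 0), max_v)
  )
}

#' Summarize peak width and height from replicate coverage tracks
#'
#' Height is the across-replicate mean of a per-replicate summary of
#' 1x-normalized coverage over the peak: the mean coverage
#' (\code{height_stat = "mean"}, default) or the maximum
#' (\code{height_stat = "max"}).
#'
#' @param tracks A \code{signal_track} or list of replicate
#'   \code{signal_track}s of the same condition.
#' @param peaks Peak tibble.
#' @param height_stat \code{"mean"} or \code{"max"}.
#' @return Tibble with \code{peak_id}, \code{width}, \code{height},
#'   \code{height_stat}.
#' @export
summarize_peak_signal <- function(tracks, peaks, height_stat = c("mean", "max")) {
  height_stat <- match.arg(height_stat)
  if (inherits(tracks, "signal_track")) tracks <- list(tracks)
  if (length(tracks) == 0) abort("no tracks given")
  for (tr in tracks) {
    sizes <- attr(tr, "chrom_sizes")
    bad <- !(peaks$chrom %in% names(sizes)) | peaks$end > sizes[peaks$chrom]
    if (any(bad, na.rm = TRUE)) abort("peak outside track bounds")
  }
  per_rep <- map(tracks, function(tr) region_signal_stats(tr, peaks)[[height_stat]])
  height <- Reduce(`+`, per_rep) / length(per_rep)
  tibble(
    peak_id = peaks$peak_id,
    width = peaks$end - peaks$start,
    height = height,
    height_stat = height_stat
  )
}

#' TSS-centred signal matrix and metaprofile
#'
#' Bins the window \code{[tss - flank, tss + flank)} around every TSS into
#' \code{2 * flank / bin} fixed-width bins and fills each bin with the mean
#' normalized coverage. Rows for minus-strand TSSs are reversed so upstream
#' is always on the left. Windows clipped at chromosome edges are padded with
#' zeros and flagged.
#'
#' @param track A \code{signal_track} (normalized to 1x for comparability).
#' @param tss TSS tibble from [tss_table()].
#' @param flank Half-window in bp (default 2500).
#' @param bin Bin width in bp (default 50); must divide \code{flank}.
#' @return A \code{tss_matrix}: numeric matrix (rows = TSS, in input order)
#'   with attributes \code{profile} (column means), \code{bin_mid} (bin
#'   centre offsets), \code{clipped} (logical per row), \code{tss} (the input
#'   tibble).
#' @export
tss_matrix <- function(track, tss, flank = 2500L, bin = 50L) {
  if (flank %% bin != 0) abort("flank must be divisible by bin")
  nb <- as.integer(2L * flank / bin)
  n <- nrow(tss)
  sizes <- attr(track, "chrom_sizes")
  offsets <- seq(-flank, flank - bin, by = bin)
  # one query interval per (tss, bin), clipped to the chromosome
  grid <- tibble(
    row = rep(seq_len(n), each = nb),
    chrom = rep(tss$chrom, each = nb),
    raw_start = rep(tss$pos, each = nb) + rep(offsets, times = n),
    raw_end = rep(tss$pos, each = nb) + rep(offsets + bin, times = n)
  ) |>
    mutate(
      start = pmax(.data$raw_start, 0),
      end = pmin(.data$raw_end, as.numeric(sizes[.data$chrom]))
    )
  vals <- numeric(nrow(grid))
  ok <- grid$start < grid$end
  if (any(ok)) {
    st <- region_signal_stats(track, grid[ok, c("chrom", "start", "end")])
    # zero-pad clipped bins: mean over the full bin width
    vals[ok] <- st$mean * (grid$end[ok] - grid$start[ok]) / bin
  }
  m <- matrix(vals, nrow = n, ncol = nb, byrow = TRUE)
  neg <- tss$strand == "-"
  if (any(neg)) m[neg, ] <- m[neg, nb:1, drop = FALSE]
  clipped <- tapply(!ok | grid$start != grid$raw_start | grid$end != grid$raw_end,
                    grid$row, any)
  structure(
    m,
    class = c("tss_matrix", "matrix", "array"),
    profile = colMeans(m),
    bin_mid = offsets + bin / 2,
    clipped = as.logical(clipped),
    tss = tss
  )
}

#' Column-mean metaprofile of a TSS matrix
#' @param m A \code{tss_matrix}.
#' @return Tibble with \code{offset} (bin centre relative to the TSS) and
#'   \code{signal}.
#' @export
tss_profile <- function(m) {
  tibble(offset = attr(m, "bin_mid"), signal = attr(m, "profile"))
}

#' Order heatmap rows by decreasing total signal
#' @param m A \code{tss_matrix}.
#' @return Integer row order (strongest signal first), matching the
#'   strongest-at-top heatmap convention.
#' @export
tss_row_order <- function(m) {
  order(rowSums(m), decreasing = TRUE)
}

#' Write a TSS matrix (with its metaprofile) as TSV
#' @param m A \code{tss_matrix}.
#' @param file Output path; the profile goes to \code{<file>.profile.tsv}.
#' @export
write_tss_matrix <- function(m, file) {
  df <- as_tibble(unclass(m)[, , drop = FALSE], .name_repair = "minimal")
  names(df) <- paste0("bin_", attr(m, "bin_mid"))
  readr::write_tsv(bind_cols(attr(m, "tss"), df), file)
  readr::write_tsv(tss_profile(m), paste0(file, ".profile.tsv"))
  invisible(file)
}
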