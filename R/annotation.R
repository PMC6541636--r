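#' Read gene models from a GTF, GFF3 or BED12 file
#'
#' Parses a gene annotation into a tibble of gene models with one row per
#' gene, carrying the gene body and every distinct transcription start site
#' (TSS) of the gene. Coordinates are converted to the package-wide 0-based
#' half-open convention (GTF/GFF3 input is 1-based inclusive, BED12 already
#' 0-based half-open).
#'
#' The TSS of a plus-strand transcript is its leftmost base; for a
#' minus-strand transcript it is the last base of the interval (\code{end - 1}
#' in half-open coordinates). Records without a strand cannot anchor a TSS and
#' are dropped with a warning.
#'
#' @param file Path to the annotation file.
#' @param dialect One of \code{"GTF"}, \code{"GFF3"}, \code{"BED12"}.
#' @return A tibble with columns \code{gene_id}, \code{symbol}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} and a list-column \code{tss}
#'   of sorted distinct TSS positions.
#' @export
read_gene_models <- function(file, dialect = c("GTF", "GFF3", "BED12")) {
  dialect <- match.arg(dialect)
  if (dialect == "BED12") {
    cols <- readr::read_tsv(
      file,
      col_names = FALSE, comment = "#", show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    if (nrow(cols) == 0) {
      warn("empty annotation file")
      return(empty_gene_models())
    }
    if (ncol(cols) < 6) abort("BED12 requires at least 6 columns (strand needed)")
    df <- tibble(
      chrom = cols[[1]],
      start = as.integer(cols[[2]]),
      end = as.integer(cols[[3]]),
      gene_id = cols[[4]],
      strand = cols[[6]],
      symbol = cols[[4]]
    )
    if (anyNA(df$start) || anyNA(df$end)) {
      abort(sprintf(
        "unparseable BED12 coordinates at line %d",
        which(is.na(df$start) | is.na(df$end))[1]
      ))
    }
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("rtracklayer is required to read GTF/GFF3")
    }
    gr <- rtracklayer::import(file, format = if (dialect == "GTF") "gtf" else "gff3")
    meta <- as.data.frame(gr)
    keep_types <- c("transcript", "mRNA")
    if ("type" %in% names(meta) && any(meta$type %in% keep_types)) {
      meta <- meta[meta$type %in% keep_types, , drop = FALSE]
    } else if ("type" %in% names(meta) && any(meta$type == "gene")) {
      meta <- meta[meta$type == "gene", , drop = FALSE]
    }
    gene_col <- intersect(c("gene_id", "ID", "Parent"), names(meta))[1]
    if (is.na(gene_col)) abort("annotation lacks a gene identifier attribute")
    sym_col <- intersect(c("gene_name", "Name"), names(meta))[1]
    df <- tibble(
      chrom = as.character(meta$seqnames),
      start = as.integer(meta$start) - 1L,  # to 0-based half-open
      end = as.integer(meta$end),
      gene_id = as.character(unlist(meta[[gene_col]])),
      strand = as.character(meta$strand),
      symbol = if (!is.na(sym_col)) as.character(meta[[sym_col]]) else
        as.character(unlist(meta[[gene_col]]))
    )
  }

  unstranded <- df$strand %in% c("*", ".", "")
  if (any(unstranded)) {
    warn(sprintf("dropped %d record(s) without strand", sum(unstranded)))
    df <- df[!unstranded, , drop = FALSE]
  }
  if (nrow(df) == 0) return(empty_gene_models())
  assert_intervals(df, "gene annotation")

  df |>
    mutate(tss_pos = if_else(.data$strand == "+", .data$start, .data$end - 1L)) |>
    group_by(.data$gene_id) |>
    summarise(
      symbol = .data$symbol[1],
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      tss = list(sort(unique(.data$tss_pos))),
      .groups = "drop"
    )
}

empty_gene_models <- function() {
  tibble(
    gene_id = character(), symbol = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(), tss = list()
  )
}

#' Flatten gene models to one row per TSS
#'
#' @param genes A gene-model tibble from [read_gene_models()].
#' @param tss_mode \code{"all"} keeps every distinct TSS; \code{"first"}
#'   keeps only the most upstream TSS in transcription direction.
#' @return Tibble with columns \code{gene_id}, \code{chrom}, \code{pos},
#'   \code{strand}, one row per TSS.
#' @export
tss_table <- function(genes, tss_mode = c("all", "first")) {
  tss_mode <- match.arg(tss_mode)
  out <- genes |>
    select("gene_id", "chrom", "strand", "tss") |>
    tidyr::unnest_longer("tss", values_to = "pos") |>
    select("gene_id", "chrom", "pos", "strand")
  if (tss_mode == "first") {
    out <- out |>
      group_by(.data$gene_id) |>
      filter(if (.data$strand[1] == "+") .data$pos == min(.data$pos)
             else .data$pos == max(.data$pos)) |>
      ungroup()
  }
  arrange(out, .data$chrom, .data$pos)
}

#' Build the genome-wide promoter list (GWPL)
#'
#' One promoter window of \code{[tss - flank, tss + flank)} per distinct TSS,
#' clipped to chromosome bounds. Overlapping windows of the same gene are
#' merged; windows of different genes are kept separate even when they
#' overlap.
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param chrom_sizes Named numeric vector or two-column tibble
#'   (\code{chrom}, \code{size}).
#' @param flank Half-width of the promoter window in bp (default 1500, giving
#'   3 kb windows).
#' @param tss_mode Passed to [tss_table()].
#' @return Tibble with columns \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}, \code{strand}, \code{clipped}.
#' @export
build_gwpl <- function(genes, chrom_sizes, flank = 1500L, tss_mode = c("all", "first")) {
  if (flank <= 0) abort("flank must be positive")
  sizes <- as_chrom_sizes(chrom_sizes)
  tss <- tss_table(genes, tss_mode = match.arg(tss_mode))
  unknown <- !(tss$chrom %in% names(sizes))
  if (any(unknown)) {
    warn(sprintf("dropped %d TSS record(s) on chromosomes absent from chrom_sizes",
                 sum(unknown)))
    tss <- tss[!unknown, , drop = FALSE]
  }
  if (nrow(tss) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character(), strand = character(), clipped = logical()))
  }
  win <- tss |>
    mutate(
      raw_start = .data$pos - as.integer(flank),
      raw_end = .data$pos + as.integer(flank),
      start = pmax(.data$raw_start, 0L),
      end = pmin(.data$raw_end, as.integer(sizes[.data$chrom])),
      clipped = .data$start != .data$raw_start | .data$end != .data$raw_end
    )
  # merge overlapping/adjacent windows of the same gene
  win |>
    arrange(.data$gene_id, .data$chrom, .data$start) |>
    group_by(.data$gene_id, .data$chrom) |>
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -1L))) |>
    group_by(.data$gene_id, .data$chrom, .data$grp) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      strand = .data$strand[1], clipped = any(.data$clipped),
      .groups = "drop"
    ) |>
    select("chrom", "start", "end", "gene_id", "strand", "clipped") |>
    arrange(.data$chrom, .data$start)
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else if (!is.null(names(chrom_sizes))) {
    chrom_sizes
  } else {
    abort("chrom_sizes must be a named vector or two-column table")
  }
}

#' Read a two-column chrom-sizes file
#' @param file Path to a TSV with chromosome name and length.
#' @return Named numeric vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(file) {
  df <- readr::read_tsv(file, col_names = c("chrom", "size"),
                        col_types = "cd", comment = "#")
  setNames(df$size, df$chrom)
}

#' Label regions as promoter or enhancer by distance to the nearest TSS
#'
#' The distance of a region to a TSS is 0 when the TSS lies inside the
#' region, otherwise the gap between the TSS and the nearest region edge
#' (\code{mode = "edge"}, default) or the distance from the region midpoint
#' (\code{mode = "midpoint"}). A region is a promoter when the distance to
#' its nearest TSS is at most \code{promoter_cutoff}, otherwise an enhancer.
#' Regions on chromosomes with no TSS get infinite distance (enhancer) and a
#' warning.
#'
#' @param regions Interval tibble (\code{chrom}, \code{start}, \code{end}).
#' @param tss TSS tibble from [tss_table()] (needs \code{chrom}, \code{pos}).
#' @param promoter_cutoff Maximum promoter distance in bp (default 1500).
#' @param mode Distance convention, \code{"edge"} or \code{"midpoint"}.
#' @return The input tibble with added \code{nearest_tss_distance} and
#'   \code{label} (\code{"promoter"} / \code{"enhancer"}) columns.
#' @export
categorize_regions <- function(regions, tss, promoter_cutoff = 1500L,
                               mode = c("edge", "midpoint")) {
  mode <- match.arg(mode)
  assert_intervals(regions, "regions")
  if (nrow(tss) == 0) abort("TSS table is empty")
  dist <- rep(Inf, nrow(regions))
  for (ch in unique(regions$chrom)) {
    pos <- sort(tss$pos[tss$chrom == ch])
    ir <- which(regions$chrom == ch)
    if (length(pos) == 0) next
    if (mode == "edge") {
      lo <- regions$start[ir]
      hi <- regions$end[ir] - 1L   # last base inside the region
    } else {
      mid <- (regions$start[ir] + regions$end[ir] - 1L) %/% 2L
      lo <- mid
      hi <- mid
    }
    # nearest TSS to the interval [lo, hi] of candidate anchor bases
    idx <- findInterval(hi, pos)
    d_right <- ifelse(idx < length(pos), pos[pmin(idx + 1L, length(pos))] - hi, Inf)
    idx2 <- findInterval(lo - 1L, pos)
    d_left <- ifelse(idx2 >= 1L, lo - pos[pmax(idx2, 1L)], Inf)
    inside <- idx > idx2   # some TSS falls within [lo, hi]
    dist[ir] <- ifelse(inside, 0, pmin(d_left, d_right))
  }
  no_tss <- !(regions$chrom %in% unique(tss$chrom))
  if (any(no_tss)) {
    warn(sprintf("%d region(s) on chromosomes with no TSS labeled enhancer (distance Inf)",
                 sum(no_tss)))
  }
  regions |>
    mutate(
      nearest_tss_distance = dist,
      label = if_else(dist <= promoter_cutoff, "promoter", "enhancer")
    )
}

#' Write a GWPL (or any gene-labelled interval tibble) as BED6
#' @param gwpl Tibble from [build_gwpl()].
#' @param file Output path.
#' @export
write_gwpl_bed <- function(gwpl, file) {
  readr::write_tsv(
    tibble(gwpl$chrom, gwpl$start, gwpl$end, gwpl$gene_id, 0L, gwpl$strand),
    file, col_names = FALSE
  )
  invisible(file)
}
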