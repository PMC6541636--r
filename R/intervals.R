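#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols distinct rename n
#'   row_number across all_of if_else pull count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 map_dfr map_int map_dbl pmap imap list_rbind
#' @importFrom stats p.adjust phyper rpois rnorm runif rbinom setNames
#' @importFrom utils head combn
NULL

# Interval tables are plain tibbles with at least chrom/start/end, 0-based
# half-open. These helpers centralise validation and overlap detection so
# every module shares one coordinate convention.

assert_intervals <- function(x, what = "interval table") {
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s lacks column(s): %s", what, paste(missing, collapse = ", ")))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s has %d invalid interval(s) (need 0 <= start < end), first at row %d",
      what, length(bad), bad[1]
    ))
  }
  invisible(x)
}

# All overlapping pairs between two interval tibbles, per chromosome.
# Returns tibble(idx_a, idx_b, overlap_bp) of row indices into a and b.
interval_overlaps <- function(a, b, min_overlap = 1L) {
  assert_intervals(a, "first interval table")
  assert_intervals(b, "second interval table")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(idx_a = integer(), idx_b = integer(), overlap_bp = integer()))
  }
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- map(chroms, function(ch) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    # IRanges is 1-based inclusive; [start, end) maps to IRanges(start+1, end)
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, minoverlap = as.integer(min_overlap))
    qa <- S4Vectors::queryHits(hits)
    qb <- S4Vectors::subjectHits(hits)
    ov <- pmin(a$end[ia][qa], b$end[ib][qb]) - pmax(a$start[ia][qa], b$start[ib][qb])
    tibble(idx_a = ia[qa], idx_b = ib[qb], overlap_bp = as.integer(ov))
  })
  out <- list_rbind(out)
  out[out$overlap_bp >= min_overlap, , drop = FALSE]
}

# Brute-force all-pairs overlap scan: the independent oracle used in tests.
interval_overlaps_bruteforce <- function(a, b, min_overlap = 1L) {
  res <- list()
  k <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        k <- k + 1L
        res[[k]] <- c(i, j, ov)
      }
    }
  }
  if (k == 0L) {
    return(tibble(idx_a = integer(), idx_b = integer(), overlap_bp = integer()))
  }
  m <- do.call(rbind, res)
  tibble(idx_a = m[, 1], idx_b = m[, 2], overlap_bp = as.integer(m[, 3]))
}
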