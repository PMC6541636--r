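# Fixtures are built in code at test time; no binary files.

peak_row <- function(chrom, start, end, id, score = 0, summit = NA_integer_,
                     condition = "control") {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 peak_id = id, score = score,
                 summit_offset = as.integer(summit), condition = condition)
}

make_peaks <- function(starts, ends, ids = NULL, chrom = "chr1",
                       condition = "control") {
  n <- length(starts)
  tibble::tibble(
    chrom = rep(chrom, length.out = n), start = as.integer(starts),
    end = as.integer(ends),
    peak_id = ids %||% paste0(condition, "_p", seq_len(n)),
    score = 0, summit_offset = NA_integer_, condition = condition
  )
}

`%||%` <- rlang::`%||%`

constant_track <- function(value, chrom_len = 1e4, chrom = "chr1", ...) {
  signal_track(
    tibble::tibble(chrom = chrom, start = 0L, end = as.integer(chrom_len),
                   value = value),
    stats::setNames(chrom_len, chrom), ...
  )
}

# per-base step track from a value vector (base i has value v[i], 0-based)
per_base_track <- function(v, chrom = "chr1") {
  df <- tibble::tibble(chrom = chrom, start = seq_along(v) - 1L,
                       end = seq_along(v), value = v)
  signal_track(df[df$value != 0, ], stats::setNames(length(v), chrom))
}

# Independent per-base summation oracle for region mean/max.
per_base_oracle <- function(track, chrom, start, end) {
  vals <- numeric(end - start)
  for (b in start:(end - 1)) {
    hit <- which(track$chrom == chrom & track$start <= b & track$end > b)
    vals[b - start + 1] <- if (length(hit) > 0) track$value[hit[1]] else 0
  }
  list(mean = mean(vals), max = max(vals))
}

# Exhaustive hypergeometric oracle: probability that a uniform draw of n
# from N (of which K are marked) overlaps the marked set by >= k.
enum_hyper_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# Brute-force nearest-TSS distance (edge convention) for one region.
brute_tss_distance <- function(chrom, start, end, tss) {
  pos <- tss$pos[tss$chrom == chrom]
  if (length(pos) == 0) return(Inf)
  d <- vapply(pos, function(t) {
    if (t >= start && t < end) 0 else min(abs(start - t), abs(t - (end - 1)))
  }, numeric(1))
  min(d)
}

write_bed6_file <- function(peaks, path) {
  readr::write_tsv(
    tibble::tibble(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   peaks$score, "."),
    path, col_names = FALSE
  )
  path
}
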