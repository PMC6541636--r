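#' Thresholds for shared-peak shape classification
#'
#' \code{width_delta_bp} is the minimum absolute width change (mutant minus
#' control) for the broader/narrower criterion. \code{height_fold_delta} is
#' the minimum fold increase for the higher/lower criterion: the default 1
#' (a 1-fold, i.e. 100 percent, increase) means the mutant/control height
#' ratio must reach \code{1 + height_fold_delta = 2} for "higher" and fall to
#' \code{1 / (1 + height_fold_delta) = 0.5} for "lower".
#'
#' @param width_delta_bp Width-change threshold in bp (default 1500).
#' @param height_fold_delta Fold-change threshold (default 1).
#' @param height_stat Height summary the thresholds refer to.
#' @export
shape_thresholds <- function(width_delta_bp = 1500, height_fold_delta = 1,
                             height_stat = c("mean", "max")) {
  if (width_delta_bp <= 0) abort("width_delta_bp must be positive")
  if (height_fold_delta <= 0) abort("height_fold_delta must be positive")
  list(width_delta_bp = width_delta_bp,
       height_fold_delta = height_fold_delta,
       height_stat = match.arg(height_stat))
}

#' Classify shared peaks as broader+higher, narrower+lower or unchanged
#'
#' A shared pair is \emph{broader} when the mutant peak is at least
#' \code{width_delta_bp} wider than its control partner, \emph{higher} when
#' the mutant/control height ratio is at least \code{1 + height_fold_delta};
#' \emph{narrower}/\emph{lower} are symmetric. A pair is
#' \code{broader_higher} when it is broader or higher and neither narrower
#' nor lower; \code{narrower_lower} symmetrically; pairs meeting neither or
#' conflicting criteria are \code{unchanged}.
#'
#' Heights must come from 1x-normalized tracks with a common summary
#' statistic. A zero control height with positive mutant height gives an
#' infinite ratio (higher); two zero heights give ratio 1.
#'
#' @param pairs Shared-pair tibble from [partition_peak_sets()] (needs
#'   \code{control_peak_id}, \code{mutant_peak_id}).
#' @param control_summary,mutant_summary Tibbles from
#'   [summarize_peak_signal()] covering the paired peaks.
#' @param thresholds From [shape_thresholds()].
#' @return Tibble with \code{control_peak_id}, \code{mutant_peak_id},
#'   \code{width_delta}, \code{height_ratio}, \code{category}.
#' @export
classify_shared_peaks <- function(pairs, control_summary, mutant_summary,
                                  thresholds = shape_thresholds()) {
  df <- pairs |>
    left_join(control_summary |> select("peak_id", cw = "width", ch = "height"),
              by = c(control_peak_id = "peak_id")) |>
    left_join(mutant_summary |> select("peak_id", mw = "width", mh = "height"),
              by = c(mutant_peak_id = "peak_id"))
  if (anyNA(df$cw) || anyNA(df$mw)) {
    abort("signal summaries do not cover all shared peaks")
  }
  ratio <- ifelse(df$ch == 0 & df$mh == 0, 1, df$mh / df$ch)
  if (any(df$ch == 0 & df$mh > 0)) {
    warn(sprintf("%d pair(s) with zero control height: ratio set to Inf",
                 sum(df$ch == 0 & df$mh > 0)))
  }
  wd <- df$mw - df$cw
  hi_cut <- 1 + thresholds$height_fold_delta
  broader <- wd >= thresholds$width_delta_bp
  narrower <- -wd >= thresholds$width_delta_bp
  higher <- ratio >= hi_cut
  lower <- ratio <= 1 / hi_cut
  category <- dplyr::case_when(
    (broader | higher) & !(narrower | lower) ~ "broader_higher",
    (narrower | lower) & !(broader | higher) ~ "narrower_lower",
    .default = "unchanged"
  )
  tibble(
    control_peak_id = df$control_peak_id,
    mutant_peak_id = df$mutant_peak_id,
    width_delta = wd,
    height_ratio = ratio,
    category = category
  )
}

#' Merge shape classification and differential calls into final gene lists
#'
#' The broader+higher gene list is the union of genes carrying a shared peak
#' classified broader+higher and genes carrying a region called enriched in
#' the mutant; the narrower+lower list is the symmetric union with depleted
#' calls. Condition-specific lists come from the partition; shared genes in
#' neither merged list are unchanged. Genes reached by several peaks may
#' appear in more than one list and are flagged.
#'
#' @param calls Shape-call tibble from [classify_shared_peaks()].
#' @param diff A \code{diff_occupancy} (or its [tidy()] tibble) whose
#'   \code{region_id}s are mutant peak ids of the shared pairs.
#' @param partition A \code{peak_partition}.
#' @param gwpl Promoter-window tibble used for the gene join.
#' @return A list of class \code{merged_gene_lists} with character-vector
#'   elements \code{broader_higher_genes}, \code{narrower_lower_genes},
#'   \code{control_only_genes}, \code{mutant_only_genes},
#'   \code{unchanged_genes}, plus \code{multi_list_genes} (genes in more
#'   than one list).
#' @export
merge_with_differential <- function(calls, diff, partition, gwpl) {
  dtab <- if (inherits(diff, "diff_occupancy")) tidy(diff) else as_tibble(diff)
  sh <- partition$shared
  shared_mutant <- tibble(
    chrom = sh$mutant_chrom, start = sh$mutant_start, end = sh$mutant_end,
    peak_id = sh$mutant_peak_id
  )
  orphan <- setdiff(dtab$region_id, shared_mutant$peak_id)
  if (length(orphan) > 0) {
    inform(sprintf("%d differential region(s) not in the shared partition ignored",
                   length(orphan)))
  }
  genes_of <- function(ids) {
    if (length(ids) == 0) return(character())
    peak_gene_set(shared_mutant[shared_mutant$peak_id %in% ids, , drop = FALSE], gwpl)
  }
  bh_shape <- genes_of(calls$mutant_peak_id[calls$category == "broader_higher"])
  nl_shape <- genes_of(calls$mutant_peak_id[calls$category == "narrower_lower"])
  enr <- genes_of(intersect(dtab$region_id[dtab$call == "enriched"],
                            shared_mutant$peak_id))
  dep <- genes_of(intersect(dtab$region_id[dtab$call == "depleted"],
                            shared_mutant$peak_id))
  bh <- sort(union(bh_shape, enr))
  nl <- sort(union(nl_shape, dep))
  shared_genes <- peak_gene_set(shared_mutant, gwpl)
  out <- list(
    broader_higher_genes = bh,
    narrower_lower_genes = nl,
    control_only_genes = peak_gene_set(partition$control_only, gwpl),
    mutant_only_genes = peak_gene_set(partition$mutant_only, gwpl),
    unchanged_genes = setdiff(shared_genes, union(bh, nl))
  )
  all_genes <- unlist(out, use.names = FALSE)
  out$multi_list_genes <- sort(unique(all_genes[duplicated(all_genes)]))
  structure(out, class = "merged_gene_lists")
}

#' @export
print.merged_gene_lists <- function(x, ...) {
  cat("<merged_gene_lists>\n")
  for (nm in setdiff(names(x), "multi_list_genes")) {
    cat(sprintf("  %-22s %d gene(s)\n", nm, length(x[[nm]])))
  }
  cat(sprintf("  %-22s %d gene(s)\n", "in multiple lists", length(x$multi_list_genes)))
  invisible(x)
}

#' Fractions of the peak partition and of shared-peak shape categories
#'
#' @param partition A \code{peak_partition}.
#' @param calls Shape-call tibble covering all shared pairs (optional; omit
#'   to summarize only the partition level).
#' @return Tibble with columns \code{level} (\code{"partition"} or
#'   \code{"shape"}), \code{component}, \code{n}, \code{fraction}. Fractions
#'   sum to 1 within each level.
#' @export
summarize_partition <- function(partition, calls = NULL) {
  n_sh <- nrow(partition$shared)
  n_c <- nrow(partition$control_only)
  n_m <- nrow(partition$mutant_only)
  tot <- n_sh + n_c + n_m
  if (tot == 0) abort("empty partition")
  out <- tibble(
    level = "partition",
    component = c("shared", "control_only", "mutant_only"),
    n = c(n_sh, n_c, n_m),
    fraction = c(n_sh, n_c, n_m) / tot
  )
  if (!is.null(calls)) {
    if (nrow(calls) != n_sh) abort("shape calls must cover all shared pairs")
    cats <- c("broader_higher", "narrower_lower", "unchanged")
    cnt <- vapply(cats, function(k) sum(calls$category == k), numeric(1))
    out <- bind_rows(out, tibble(
      level = "shape", component = cats, n = as.integer(unname(cnt)),
      fraction = if (n_sh > 0) unname(cnt) / n_sh else rep(NA_real_, 3)
    ))
  }
  out
}
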