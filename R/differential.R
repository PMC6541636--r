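#' Build a count matrix from per-replicate fragment interval lists
#'
#' Each fragment is counted once in every region it overlaps by at least
#' 1 bp; a fragment spanning two regions contributes to both. Library size is
#' the total number of fragments in the replicate (not the column sum, so
#' fragments outside all regions still contribute to depth).
#'
#' @param fragments Named list of interval tibbles (\code{chrom},
#'   \code{start}, \code{end}), one per replicate.
#' @param regions Interval tibble with a \code{region_id} column (generated
#'   if absent).
#' @param conditions Character vector (same length/names as
#'   \code{fragments}) of condition labels.
#' @return A \code{count_matrix}: list with \code{counts} (regions x
#'   replicates integer matrix), \code{regions} (tibble),
#'   \code{conditions}, \code{library_sizes}.
#' @export
count_fragments_in_regions <- function(fragments, regions, conditions) {
  if (is.null(names(fragments))) {
    names(fragments) <- paste0("rep", seq_along(fragments))
  }
  if (length(conditions) != length(fragments)) {
    abort("conditions must have one label per replicate")
  }
  if (!("region_id" %in% names(regions))) {
    regions <- mutate(regions, region_id = paste0("region_", row_number()))
  }
  n <- nrow(regions)
  counts <- vapply(fragments, function(fr) {
    if (nrow(fr) == 0) return(integer(n))
    hits <- interval_overlaps(regions, fr, min_overlap = 1L)
    tab <- tabulate(hits$idx_a, nbins = n)
    as.integer(tab)
  }, integer(n))
  counts <- matrix(counts, nrow = n,
                   dimnames = list(regions$region_id, names(fragments)))
  new_count_matrix(counts, regions, conditions,
                   library_sizes = vapply(fragments, nrow, integer(1)))
}

#' Construct a count matrix from an existing counts table
#' @param counts Integer matrix (regions x replicates) with dimnames.
#' @param regions Tibble with a \code{region_id} column matching the rows.
#' @param conditions Condition label per column.
#' @param library_sizes Total fragments per replicate; defaults to column
#'   sums.
#' @export
new_count_matrix <- function(counts, regions, conditions, library_sizes = NULL) {
  if (any(counts < 0)) abort("counts must be nonnegative")
  # NB: with overlapping regions a fragment may be counted in several rows,
  # so column sums can exceed the library size; no cross-check is enforced.
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  structure(
    list(counts = counts, regions = regions,
         conditions = as.character(conditions),
         library_sizes = as.numeric(library_sizes)),
    class = "count_matrix"
  )
}

#' Read a counts TSV plus condition map into a count matrix
#' @param counts_file TSV: first column region_id, remaining columns one per
#'   replicate.
#' @param condition_file Two-column TSV (replicate_id, condition).
#' @export
read_count_matrix <- function(counts_file, condition_file) {
  df <- readr::read_tsv(counts_file, show_col_types = FALSE)
  cmap <- readr::read_tsv(condition_file, col_names = c("replicate_id", "condition"),
                          col_types = "cc")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cond <- cmap$condition[match(colnames(m), cmap$replicate_id)]
  if (anyNA(cond)) abort("condition map missing replicate(s)")
  new_count_matrix(m, tibble(region_id = df[[1]]), cond)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d region(s) x %d replicate(s) [%s]\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$conditions)),
                            as.integer(table(x$conditions))), collapse = ", ")))
  invisible(x)
}

# Weight matrices for the permutation distribution of a difference of
# condition means: columns are label reassignments; W[i, k] is the signed
# weight of replicate i in arrangement k.
permutation_weights <- function(n_total, n_mutant, max_exact, n_perm, seed) {
  n_arr <- choose(n_total, n_mutant)
  if (n_arr <= max_exact) {
    sel <- combn(n_total, n_mutant)
    exact <- TRUE
  } else {
    sel <- with_private_seed(seed, {
      vapply(seq_len(n_perm), function(k) sort(sample.int(n_total, n_mutant)),
             integer(n_mutant))
    })
    exact <- FALSE
  }
  W <- matrix(-1 / (n_total - n_mutant), nrow = n_total, ncol = ncol(sel))
  for (k in seq_len(ncol(sel))) W[sel[, k], k] <- 1 / n_mutant
  list(W = W, exact = exact)
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# state.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Permutation test for differential occupancy on log CPM
#'
#' For every region, counts are scaled to counts per million of the
#' replicate's library size, shifted by a pseudo-count and log2-transformed:
#' \code{y = log2(count / library_size * 1e6 + pseudo)}. The statistic is the
#' difference of condition means of \code{y} (mutant minus control), which is
#' also the reported \code{log2_fold_change}. Two-sided p-values come from
#' the exact permutation distribution over all condition-label reassignments
#' when their number is at most \code{max_exact} (4 vs 4 gives 70), otherwise
#' from \code{n_perm} Monte-Carlo permutations drawn from a fixed seed.
#' Benjamini-Hochberg adjustment is applied across all tested regions; calls
#' threshold the unadjusted p-value by default (set
#' \code{call_on = "adjusted"} to threshold the BH-adjusted one).
#'
#' @param x A \code{count_matrix}.
#' @param control,mutant Condition labels identifying the two groups
#'   (defaults: \code{"control"}, \code{"mutant"}).
#' @param alpha Call threshold on the p-value (default 0.05).
#' @param pseudo Pseudo-count on the CPM scale (default 0.5).
#' @param max_exact Largest number of arrangements enumerated exactly
#'   (default 10000).
#' @param n_perm Monte-Carlo permutations when enumeration is too large.
#' @param seed Seed for Monte-Carlo permutations (default 1).
#' @param call_on \code{"raw"} or \code{"adjusted"} p for the call threshold.
#' @return A \code{diff_occupancy} object; use [tidy()] for the per-region
#'   table and [glance()] for the one-row summary.
#' @export
differential_test <- function(x, control = "control", mutant = "mutant",
                              alpha = 0.05, pseudo = 0.5,
                              max_exact = 10000L, n_perm = 10000L, seed = 1L,
                              call_on = c("raw", "adjusted")) {
  call_on <- match.arg(call_on)
  stopifnot(inherits(x, "count_matrix"))
  ic <- which(x$conditions == control)
  im <- which(x$conditions == mutant)
  if (length(ic) < 2 || length(im) < 2) {
    abort("need at least 2 replicates per condition")
  }
  cols <- c(ic, im)
  cpm <- sweep(x$counts[, cols, drop = FALSE], 2,
               x$library_sizes[cols] / 1e6, "/")
  y <- log2(cpm + pseudo)
  n_total <- length(cols)
  n_mut <- length(im)
  is_mut <- c(rep(FALSE, length(ic)), rep(TRUE, length(im)))
  obs <- rowMeans(y[, is_mut, drop = FALSE]) - rowMeans(y[, !is_mut, drop = FALSE])
  pw <- permutation_weights(n_total, n_mut, max_exact, n_perm, seed)
  perm_stats <- y %*% pw$W   # regions x arrangements
  tol <- 1e-12
  extreme <- rowSums(abs(perm_stats) >= abs(obs) - tol)
  if (pw$exact) {
    p <- extreme / ncol(pw$W)
  } else {
    # add-one correction counting the observed labelling itself
    p <- (extreme + 1) / (ncol(pw$W) + 1)
  }
  p <- pmin(p, 1)
  adj <- p.adjust(p, method = "BH")
  p_call <- if (call_on == "raw") p else adj
  call <- unname(ifelse(p_call < alpha & obs > 0, "enriched",
                        ifelse(p_call < alpha & obs < 0, "depleted",
                               "not_significant")))
  res <- tibble(
    region_id = rownames(x$counts) %||% paste0("region_", seq_along(obs)),
    log2_fold_change = as.numeric(obs),
    p_value = as.numeric(p),
    adjusted_p = as.numeric(adj),
    call = call
  )
  structure(
    list(results = res, alpha = alpha, pseudo = pseudo,
         exact = pw$exact, n_arrangements = ncol(pw$W),
         n_control = length(ic), n_mutant = length(im), call_on = call_on),
    class = "diff_occupancy"
  )
}

#' @export
print.diff_occupancy <- function(x, ...) {
  cat(sprintf(
    "<diff_occupancy> %d region(s), %d vs %d replicates, %s permutation (%d arrangements)\n",
    nrow(x$results), x$n_control, x$n_mutant,
    if (x$exact) "exact" else "Monte-Carlo", x$n_arrangements
  ))
  print(dplyr::count(x$results, .data$call))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-region differential-occupancy results
#' @param x A \code{diff_occupancy} object.
#' @param ... Unused.
#' @return Tibble with \code{region_id}, \code{log2_fold_change},
#'   \code{p_value}, \code{adjusted_p}, \code{call}.
#' @method tidy diff_occupancy
#' @export
tidy.diff_occupancy <- function(x, ...) {
  x$results
}

#' One-row summary of a differential-occupancy fit
#' @param x A \code{diff_occupancy} object.
#' @param ... Unused.
#' @method glance diff_occupancy
#' @export
glance.diff_occupancy <- function(x, ...) {
  tibble(
    n_regions = nrow(x$results),
    n_enriched = sum(x$results$call == "enriched"),
    n_depleted = sum(x$results$call == "depleted"),
    alpha = x$alpha,
    exact = x$exact,
    n_arrangements = x$n_arrangements
  )
}

#' Write differential results as TSV
#' @param x A \code{diff_occupancy}.
#' @param file Output path.
#' @export
write_differential_tsv <- function(x, file) {
  readr::write_tsv(tidy(x), file)
  invisible(file)
}
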