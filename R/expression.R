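#' Threshold a differential-expression table by fold change
#'
#' Directions use strict inequalities ("more than two-fold"): a gene is
#' \code{up} when \code{fold_change > fc_threshold}, \code{down} when
#' \code{fold_change < 1 / fc_threshold}, otherwise \code{unchanged}. A gene
#' exactly at the threshold is unchanged. Rows with missing or nonpositive
#' fold changes are rejected with a warning.
#'
#' @param table Tibble (or TSV path) with columns \code{gene_id} and
#'   \code{fold_change} (mutant/control expression ratio); extra columns such
#'   as annotation flags are carried through.
#' @param fc_threshold Fold-change threshold (default 2).
#' @return The table with an added \code{direction} column.
#' @export
filter_de_genes <- function(table, fc_threshold = 2) {
  if (is.character(table) && length(table) == 1) {
    table <- readr::read_tsv(table, show_col_types = FALSE)
  }
  if (!all(c("gene_id", "fold_change") %in% names(table))) {
    abort("DE table needs gene_id and fold_change columns")
  }
  bad <- is.na(table$fold_change) | table$fold_change <= 0
  if (any(bad)) {
    warn(sprintf("rejected %d DE record(s) with missing or nonpositive fold change",
                 sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  table |>
    mutate(direction = dplyr::case_when(
      .data$fold_change > fc_threshold ~ "up",
      .data$fold_change < 1 / fc_threshold ~ "down",
      .default = "unchanged"
    ))
}

#' Intersect two gene lists
#' @param a,b Character vectors of gene ids.
#' @return List with \code{overlap} (sorted intersection), \code{n_a},
#'   \code{n_b}, \code{n_overlap}.
#' @export
intersect_gene_lists <- function(a, b) {
  ov <- sort(intersect(unique(a), unique(b)))
  list(overlap = ov, n_a = length(unique(a)), n_b = length(unique(b)),
       n_overlap = length(ov))
}

#' Cross-tabulate promoter H2A.Z gains against H3K27ac status
#'
#' Splits the genes that gained the primary mark at their promoter into
#' three exclusive groups by the status of the activity co-mark: those that
#' also gained it, those already positive before, and those that remained
#' negative. The two co-mark sets must be disjoint.
#'
#' @param gained_primary Genes that gained the primary mark at the promoter.
#' @param comark_gained Genes that gained the co-mark.
#' @param comark_positive_before Genes positive for the co-mark beforehand.
#' @return Tibble with \code{status}, \code{n}, \code{fraction} (fractions
#'   \code{NA} on empty input); the three rows partition the input set.
#' @export
crosstab_promoter_marks <- function(gained_primary, comark_gained,
                                    comark_positive_before) {
  if (length(intersect(comark_gained, comark_positive_before)) > 0) {
    abort("co-mark gained and positive-before sets must be disjoint")
  }
  g <- unique(gained_primary)
  n_gain <- sum(g %in% comark_gained)
  n_pos <- sum(g %in% comark_positive_before)
  n_neg <- length(g) - n_gain - n_pos
  n <- c(gained = n_gain, already_positive = n_pos, negative = n_neg)
  tibble(
    status = names(n),
    n = as.integer(n),
    fraction = if (length(g) > 0) as.numeric(n) / length(g) else NA_real_
  )
}

#' Hypergeometric term enrichment over a gene universe
#'
#' For every term, tests over-representation of the query list among the
#' term's genes with the hypergeometric upper tail
#' \code{P(X >= k)} where \code{k} is the observed overlap, followed by
#' Benjamini-Hochberg adjustment across terms. Term gene sets are first
#' intersected with the universe; the query list must be a subset of the
#' universe.
#'
#' @param genes Query gene list.
#' @param universe Background gene set.
#' @param term_map Named list of term gene sets, or a GMT file path.
#' @return Tibble with \code{term_id}, \code{k} (overlap), \code{n} (list
#'   size), \code{K} (term size in universe), \code{N} (universe size),
#'   \code{p_value}, \code{adjusted_p}, sorted by p-value.
#' @export
term_enrichment <- function(genes, universe, term_map) {
  if (is.character(term_map) && length(term_map) == 1 && file.exists(term_map)) {
    term_map <- read_gmt(term_map)
  }
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  genes <- unique(genes)
  if (!all(genes %in% universe)) abort("query genes must be a subset of the universe")
  n <- length(genes)
  N <- length(universe)
  res <- imap(term_map, function(term_genes, term_id) {
    tg <- intersect(unique(term_genes), universe)
    K <- length(tg)
    k <- length(intersect(genes, tg))
    tibble(
      term_id = term_id, k = k, n = n, K = K, N = N,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  }) |> list_rbind()
  res |>
    mutate(adjusted_p = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value)
}

#' Read a GMT gene-set file
#' @param file Path to a GMT file (term, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readr::read_lines(file)
  lines <- lines[nzchar(lines)]
  out <- map(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
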