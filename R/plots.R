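#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_point scale_fill_viridis_c labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Heatmap of a TSS-centred signal matrix
#'
#' Rows are ordered by total signal (strongest at the top), matching the
#' usual TSS heatmap convention.
#'
#' @param object A \code{tss_matrix}.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tss_matrix
#' @export
autoplot.tss_matrix <- function(object, ...) {
  ord <- tss_row_order(object)
  m <- unclass(object)[ord, , drop = FALSE]
  df <- tidyr::expand_grid(
    row = seq_len(nrow(m)),
    offset = attr(object, "bin_mid")
  )
  df$signal <- as.vector(t(m))
  ggplot(df, aes(x = .data$offset, y = -.data$row, fill = .data$signal)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "distance to TSS (bp)", y = "TSS (ranked by signal)",
         fill = "coverage") +
    theme_minimal()
}

#' Metaprofile line plot for one or more TSS matrices
#' @param ... Named \code{tss_matrix} objects (names become the legend).
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(...) {
  mats <- list(...)
  if (length(mats) == 1 && is.list(mats[[1]]) && !inherits(mats[[1]], "tss_matrix")) {
    mats <- mats[[1]]
  }
  if (is.null(names(mats)) || any(!nzchar(names(mats)))) {
    names(mats) <- paste0("track_", seq_along(mats))
  }
  df <- imap(mats, function(m, nm) mutate(tss_profile(m), track = nm)) |>
    list_rbind()
  ggplot(df, aes(x = .data$offset, y = .data$signal, colour = .data$track)) +
    geom_line() +
    labs(x = "distance to TSS (bp)", y = "mean normalized coverage",
         colour = NULL) +
    theme_minimal()
}

#' Bar chart of a peak partition (and shape fractions)
#' @param object A \code{peak_partition}.
#' @param calls Optional shape calls to add the shared-peak shape level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_partition
#' @export
autoplot.peak_partition <- function(object, calls = NULL, ...) {
  df <- summarize_partition(object, calls)
  ggplot(df, aes(x = .data$component, y = .data$fraction)) +
    geom_col(fill = "grey35") +
    facet_wrap(~.data$level, scales = "free_x") +
    labs(x = NULL, y = "fraction") +
    theme_minimal()
}

#' Volcano-style plot of differential-occupancy results
#' @param object A \code{diff_occupancy}.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diff_occupancy
#' @export
autoplot.diff_occupancy <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$log2_fold_change, y = -log10(.data$p_value),
                 colour = .data$call)) +
    geom_point(alpha = 0.6) +
    labs(x = "log2 fold change (mutant / control)", y = "-log10 p") +
    theme_minimal()
}
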