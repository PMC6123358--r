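#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Venn partition into region sizes
#'
#' @param x A [partition_otus()] result.
#' @param ... Unused.
#' @return A tibble with columns `region` and `n_otus`, one row per disjoint
#'   region.
#' @method tidy venn_partition
#' @export
tidy.venn_partition <- function(x, ...) {
  tibble(region = venn_regions,
         n_otus = unname(vapply(venn_regions, function(r) length(x[[r]]),
                                integer(1))))
}

#' One-row summary of a Venn partition
#'
#' @inheritParams tidy.venn_partition
#' @return A tibble with `n_rumen`, `n_plates`, `n_shared`, `n_plate_only`,
#'   `cultivable_fraction`, and the medium gains in both directions.
#' @method glance venn_partition
#' @export
glance.venn_partition <- function(x, ...) {
  tibble(
    n_rumen = length(x$rumen_all),
    n_plates = length(x$plates_all),
    n_shared = length(x$shared),
    n_plate_only = length(x$plate_only),
    cultivable_fraction = cultivable_fraction(x),
    medium_gain_defined_added = medium_gain(x, "defined"),
    medium_gain_undefined_added = medium_gain(x, "undefined"))
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("OTU Venn partition (rumen / defined / undefined)\n")
  print(tidy(x))
  cat(sprintf("shared %d / rumen %d (cultivable fraction %.4f); plate-only %d\n",
              length(x$shared), length(x$rumen_all), cultivable_fraction(x),
              length(x$plate_only)))
  invisible(x)
}

#' Tidy a phylogenetic-cohesion permutation result
#'
#' @param x A [phylo_permutation_test()] result.
#' @param ... Unused.
#' @return A one-row tibble with the observed MPD, null summary, percentile
#'   rank and both tail p-values.
#' @method tidy phylo_permutation
#' @export
tidy.phylo_permutation <- function(x, ...) {
  tibble(group = x$group_label, observed_mean = x$observed_mean,
         null_mean = mean(x$null_means), null_sd = stats::sd(x$null_means),
         percentile_rank = x$percentile_rank, p_lesser = x$p_lesser,
         p_greater = x$p_greater, subset_size = x$subset_size, B = x$B)
}

#' Tidy PCoA coordinates
#'
#' @param x A [pcoa()] result.
#' @param ... Unused.
#' @return The coordinates tibble (`sample_id`, `Axis1..k`).
#' @method tidy rumen_pcoa
#' @export
tidy.rumen_pcoa <- function(x, ...) x$coordinates

#' Per-axis PCoA summary
#'
#' @inheritParams tidy.rumen_pcoa
#' @return A tibble with `axis`, `eigenvalue`, `proportion_explained` for the
#'   returned axes.
#' @method glance rumen_pcoa
#' @export
glance.rumen_pcoa <- function(x, ...) {
  k <- ncol(x$coordinates) - 1
  tibble(axis = seq_len(k), eigenvalue = x$eigenvalues[seq_len(k)],
         proportion_explained = x$proportion_explained[seq_len(k)])
}

#' Plot a PCoA ordination
#'
#' Scatter of the first two axes with percent variance in the axis labels;
#' points can be coloured and shaped by metadata columns.
#'
#' @param object A [pcoa()] result.
#' @param metadata Optional metadata tibble joined on `sample_id`.
#' @param colour,shape Optional metadata column names (strings).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rumen_pcoa
#' @export
autoplot.rumen_pcoa <- function(object, metadata = NULL, colour = NULL,
                                shape = NULL, ...) {
  df <- object$coordinates
  if (!is.null(metadata)) df <- left_join(df, metadata, by = "sample_id")
  pe <- 100 * object$proportion_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::geom_point(ggplot2::aes(
      colour = if (is.null(colour)) NULL else .data[[colour]],
      shape = if (is.null(shape)) NULL else .data[[shape]]), size = 2) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pe[1]),
                  y = sprintf("PCo2 (%.1f%%)", pe[2]),
                  colour = colour, shape = shape) +
    ggplot2::theme_minimal()
  p
}

#' Plot a permutation null distribution against the observed MPD
#'
#' Histogram of the null mean pairwise distances with the observed value as a
#' vertical line; a line far into the lower tail indicates phylogenetic
#' cohesion of the focal set.
#'
#' @param object A [phylo_permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phylo_permutation
#' @export
autoplot.phylo_permutation <- function(object, ...) {
  df <- tibble(null_mean = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_mean)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_mean, colour = "orange",
                        linewidth = 1) +
    ggplot2::labs(
      x = "null mean pairwise distance", y = "permutations",
      title = sprintf("%s: observed MPD at percentile %.1f (p lesser = %.3g)",
                      object$group_label, object$percentile_rank,
                      object$p_lesser)) +
    ggplot2::theme_minimal()
}

#' Plot abundance-cultivability correlations by dilution
#'
#' One line per cultured subset, Pearson r against dilution exponent, with
#' the significance threshold band at +/- `r_threshold`.
#'
#' @param corr A [cultivability_correlation()] tibble.
#' @param r_threshold Threshold drawn as horizontal lines (default 0.3).
#' @return A ggplot object.
#' @export
plot_cultivability_correlation <- function(corr, r_threshold = 0.3) {
  ggplot2::ggplot(corr, ggplot2::aes(.data$dilution_exponent, .data$r,
                                     colour = .data$subset)) +
    ggplot2::geom_hline(yintercept = c(-r_threshold, r_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$significant), alpha = 0.8) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 3, `FALSE` = 1.5)) +
    ggplot2::labs(x = "dilution exponent (10^-d)", y = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
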