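#' Manhattan plot of an association scan
#'
#' @param object an `emmer_assoc` tibble (significance-annotated).
#' @param gap inter-chromosome gap passed to [manhattan_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.emmer_assoc <- function(object, gap = 5e6, ...) {
  tab <- manhattan_table(object, gap = gap)
  thr <- attr(object, "threshold")
  chrom_f <- factor(tab$chrom, levels = unique(tab$chrom[order(chrom_rank(tab$chrom))]))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$cum_pos, y = .data$neglog10p,
                                         colour = chrom_f)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr$neglog10,
                                 colour = "blue", linetype = "dashed")
  }
  p
}

#' PCA score plot
#'
#' @param object an `emmer_pca`.
#' @param frame optional sample metadata; points are coloured by `taxon`
#'   (or `group` if present).
#' @param components which two PCs to display.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.emmer_pca <- function(object, frame = NULL, components = c(1L, 2L), ...) {
  sc <- object$scores
  xc <- paste0("PC", components[1]); yc <- paste0("PC", components[2])
  if (!is.null(frame)) {
    sc <- dplyr::left_join(sc, frame, by = "accession_id")
    col <- if ("group" %in% names(sc)) "group" else "taxon"
    aes <- ggplot2::aes(x = .data[[xc]], y = .data[[yc]], colour = .data[[col]])
  } else {
    aes <- ggplot2::aes(x = .data[[xc]], y = .data[[yc]])
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xc, 100 * object$explained[components[1]]),
      y = sprintf("%s (%.1f%%)", yc, 100 * object$explained[components[2]])) +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn class fractions
#'
#' @param venn output of [venn_counts()].
#' @return a ggplot object.
#' @export
plot_venn_counts <- function(venn) {
  venn$class <- factor(venn$class, levels = VENN_CLASSES)
  ggplot2::ggplot(venn, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "allele sharing class", y = "fraction of alleles") +
    ggplot2::theme_minimal()
}

#' Histogram of fixed-allele frequency differentials
#'
#' The left side holds alleles more frequent in the 'other' wild
#' population, the right side those more frequent in the south population.
#'
#' @param report a `fixed_set_report` from [fixed_in_domesticates()].
#' @return a ggplot object.
#' @export
plot_differential_histogram <- function(report) {
  h <- report$histogram
  h$mid <- (h$bin_low + h$bin_high) / 2
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$n)) +
    ggplot2::geom_col(width = min(h$bin_high - h$bin_low), fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "f(south) - f('other')", y = "alleles") +
    ggplot2::theme_minimal()
}
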