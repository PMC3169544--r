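# ggplot2 displays for the three headline result types: the per-individual
# genotype mosaic, stacked admixture bars, and the bootstrap NJ tree (drawn
# through ape, the field's standard tree renderer).

#' Heatmap of per-individual genotype classes
#'
#' Individuals (grouped by population) against strongly differentiated
#' sites; colors mark parent-A-like and parent-B-like genotypes,
#' heterozygotes, and missing data — the genomic-mosaic display in which a
#' hybrid species shows blocks of each parent's ancestry.
#'
#' @param x A [classify_sequence_genotypes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_classes <- function(x, ...) {
  df <- mutate(as_tibble(x),
               sample_id = factor(.data$sample_id,
                                  levels = unique(.data$sample_id[order(.data$population)])),
               site_id = factor(.data$site_id, levels = unique(.data$site_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_id, y = .data$sample_id,
                                   fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      A_like = "#7b3294", B_like = "#92c5de",
      heterozygote = "black", missing = "grey70")) +
    ggplot2::facet_grid(.data$population ~ .data$locus,
                        scales = "free", space = "free") +
    ggplot2::labs(x = "site", y = "individual", fill = "genotype") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Stacked-bar plot of admixture proportions
#'
#' One bar per individual, stacked by cluster, grouped by population.
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.admixture_fit <- function(x, ...) {
  td <- tidy.admixture_fit(x)
  td <- mutate(td, sample_id = factor(.data$sample_id,
                                      levels = unique(.data$sample_id[order(.data$population)])))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$sample_id, y = .data$q,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~ .data$population, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "admixture proportion q",
                  title = sprintf("K = %d", x$K)) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(1, "pt"))
}

#' Plot a bootstrap-labelled NJ tree
#'
#' @param tree A `phylo` tree, e.g. from [bootstrap_support()].
#' @param ... Passed to `ape::plot.phylo`.
#' @return The tree, invisibly (draws on the active device).
#' @export
plot_nj_tree <- function(tree, ...) {
  ape::plot.phylo(tree, cex = 0.6, ...)
  if (!is.null(tree$node.label)) {
    ape::nodelabels(text = tree$node.label, frame = "none", cex = 0.5, adj = c(1.2, -0.3))
  }
  invisible(tree)
}
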