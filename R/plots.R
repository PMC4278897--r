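#' Bar chart of the category census
#'
#' @param classes Classification tibble from [classify_tissue_specificity()].
#' @return A ggplot object.
#' @export
plot_category_census <- function(classes) {
  cen <- category_census(classes)
  ggplot2::ggplot(cen, ggplot2::aes(x = .data$category, y = .data$n_genes,
                                    fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = paste0("Specificity categories",
                                 if (!is.null(attr(classes, "target")))
                                   paste0(" (target: ", attr(classes, "target"), ")"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' mRNA pool composition plot
#'
#' Share of the target tissue's mRNA pool carried by each specificity
#' category.
#'
#' @param pool A [mrna_pool_fractions()] result.
#' @return A ggplot object.
#' @export
plot_mrna_pool <- function(pool) {
  df <- as_tibble(pool)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$mrna_fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "category",
                  title = paste0("mRNA pool composition (",
                                 attr(pool, "target"), ")")) +
    ggplot2::theme_void()
}

#' @exportS3Method ggplot2::autoplot
autoplot.spearman_cor <- function(object, ...) {
  ids <- rownames(object)
  df <- tidy.spearman_cor(object)
  df_full <- bind_rows(
    df,
    tibble(sample_a = df$sample_b, sample_b = df$sample_a, rho = df$rho),
    tibble(sample_a = ids, sample_b = ids, rho = 1)
  )
  ggplot2::ggplot(df_full, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                        fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(limits = c(-1, 1), low = "white", high = "darkblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sharing-network summary plot
#'
#' Per-tissue tally of group-enriched genes shared with the target tissue.
#'
#' @param network A [build_sharing_network()] result.
#' @return A ggplot object.
#' @export
plot_sharing_tally <- function(network) {
  df <- network$tissue_tally
  df$tissue <- factor(df$tissue, levels = rev(df$tissue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_genes, y = .data$tissue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "shared group-enriched genes", y = NULL,
                  title = paste0("Tissues sharing enrichment with ",
                                 attr(network, "target"))) +
    ggplot2::theme_minimal()
}
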