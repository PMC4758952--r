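#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_errorbar geom_vline scale_fill_gradient2 labs theme_minimal
#'   element_text theme scale_x_log10 facet_wrap geom_raster
#' @export
ggplot2::autoplot

#' Plot a metagene profile
#'
#' @param profile Tibble from [metagene_profile()] (optionally several,
#'   bound with a `mark` column).
#' @return A ggplot.
#' @export
plot_metagene <- function(profile) {
  p <- ggplot(profile, aes(x = .data$offset, y = .data$depth))
  if ("mark" %in% names(profile)) {
    p <- p + geom_line(aes(colour = .data$mark))
  } else {
    p <- p + geom_line()
  }
  p + geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = "distance from anchor (bp)", y = "mean tags per bin") +
    theme_minimal()
}

#' @export
autoplot.spearman_matrix <- function(object, ...) {
  df <- as_tibble(unclass(object), rownames = "row") %>%
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "rho")
  ord <- rownames(object)
  df$row <- factor(df$row, levels = ord)
  df$col <- factor(df$col, levels = ord)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman rho") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- as_tibble(object$values, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "offset",
                        values_to = "z") %>%
    mutate(offset = as.numeric(.data$offset),
           gene_id = factor(.data$gene_id,
                            levels = rev(rownames(object$values))))
  ggplot(df, aes(x = .data$offset, y = .data$gene_id, fill = .data$z)) +
    geom_raster() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = sprintf("distance from %s (bp)", object$anchor), y = NULL,
         fill = "z") +
    theme_minimal() +
    theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.lasso_fit <- function(object, ...) {
  ggplot(object$cv_curve, aes(x = .data$lambda, y = .data$cvm)) +
    geom_errorbar(aes(ymin = .data$cvm - .data$cvsd,
                      ymax = .data$cvm + .data$cvsd),
                  colour = "grey70", width = 0) +
    geom_point() +
    geom_vline(xintercept = object$lambda_min, linetype = "dashed",
               colour = "red") +
    geom_vline(xintercept = object$lambda_1se, linetype = "dashed",
               colour = "blue") +
    scale_x_log10() +
    labs(x = "penalty (log scale)", y = "cross-validated MSE") +
    theme_minimal()
}
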