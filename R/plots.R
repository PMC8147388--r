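#' Bar chart of DE transcript counts per exposure
#'
#' @param counts tibble from [de_count_table()].
#' @return A ggplot object.
#' @export
plot_de_counts <- function(counts) {
  assert_cols(counts, c("group", "n_lnc", "n_mrna"), "count table")
  long <- counts |>
    tidyr::pivot_longer(c("n_lnc", "n_mrna"), names_to = "biotype", values_to = "n") |>
    mutate(biotype = ifelse(.data$biotype == "n_lnc", "lncRNA", "mRNA"))
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$group, -.data$n),
                                     y = .data$n, fill = .data$biotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DE transcripts", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heatmap of the bi-clustered lncRNA x mRNA correlation matrix
#'
#' Rows and columns follow the dendrogram orders; tiles show the Pearson
#' coefficient of surviving edges (0 elsewhere).
#'
#' @param object a `conet_biclust`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot conet_biclust
#' @export
autoplot.conet_biclust <- function(object, ...) {
  r <- object$r_matrix[object$hc_lnc$order, object$hc_mrna$order, drop = FALSE]
  df <- tibble(lnc_id = rep(rownames(r), times = ncol(r)),
               mrna_id = rep(colnames(r), each = nrow(r)),
               r = as.vector(r)) |>
    mutate(lnc_id = factor(.data$lnc_id, levels = rownames(r)),
           mrna_id = factor(.data$mrna_id, levels = colnames(r)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mrna_id, y = .data$lnc_id, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = "mRNA", y = "lncRNA", fill = "Pearson R") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Heatmap of group-level panel Z-scores, annotated with tiers
#'
#' @param object a `tox_ranking`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tox_ranking
#' @export
autoplot.tox_ranking <- function(object, ...) {
  z <- attr(object, "z")
  ord <- object$group
  df <- tibble(group = rep(rownames(z), times = ncol(z)),
               probe_id = rep(colnames(z), each = nrow(z)),
               z = as.vector(z)) |>
    mutate(group = factor(.data$group, levels = ord))
  tier_of <- setNames(as.character(object$tier), object$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probe_id, y = .data$group, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "panel lncRNA", y = NULL, fill = "mean Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
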