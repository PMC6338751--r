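# Figures for the main result types.

#' @describeIn quantile_stratify Plot mean log-normalized damage/repair per
#'   expression-quantile bin, one panel per assay, colored by strand class,
#'   annotated with gene-wise Spearman correlations.
#' @param object A `quantile_profile`.
#' @param ... Unused.
#' @export
autoplot.quantile_profile <- function(object, ...) {
  labels <- object$correlations |>
    mutate(label = sprintf("%s rho == %.2f", .data$strand_class, .data$rho))
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin, y = .data$mean_log_value,
                               color = .data$strand_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~assay, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = scales_pretty(object$n_bins)) +
    ggplot2::labs(x = "gene expression quantile bin",
                  y = "mean log2(normalized + 1)",
                  color = "strand",
                  caption = paste(labels$assay, labels$label,
                                  collapse = "; ")) +
    ggplot2::theme_minimal()
}

scales_pretty <- function(n) unique(round(seq(1, n, length.out = min(n, 6))))

#' Plot the distribution of TS/(TS+NTS) strand ratios
#'
#' Shows damage and repair strand-share distributions across genes; under
#' active transcription-coupled repair the damage ratio shifts below 0.5 and
#' the repair ratio above.
#'
#' @param estimates A [repair_estimates()] tibble.
#' @return A ggplot object.
#' @export
plot_strand_ratios <- function(estimates) {
  df <- estimates |>
    select("gene_id", damage = "damage_ratio", repair = "xr_ratio") |>
    tidyr::pivot_longer(-"gene_id", names_to = "assay", values_to = "ratio") |>
    filter(!is.na(.data$ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, fill = .data$assay)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "TS / (TS + NTS)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot per-sample relative damage
#'
#' @param reldmg Result of [relative_damage()].
#' @return A ggplot object.
#' @export
plot_relative_damage <- function(reldmg) {
  ggplot2::ggplot(reldmg,
                  ggplot2::aes(x = stats::reorder(.data$sample,
                                                  -.data$relative_damage),
                               y = .data$relative_damage)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative damage (mean 1)") +
    ggplot2::theme_minimal()
}
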