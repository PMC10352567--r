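# ggplot2 figure helpers for pipeline results.

#' Heatmap of log10 glycan ratios
#'
#' Tile heatmap of the [heatmap_matrix()] result with samples ordered by
#' group, sex, week, mouse and glycans in panel order.
#'
#' @param object A `glyco_heatmap` (from [heatmap_matrix()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glyco_heatmap
#' @export
autoplot.glyco_heatmap <- function(object, ...) {
  m <- object$matrix
  df <- tibble::as_tibble(m) |>
    dplyr::mutate(sample_id = factor(rownames(m), levels = rev(rownames(m))),
                  group = object$annotations$group) |>
    tidyr::pivot_longer(-c("sample_id", "group"), names_to = "glycan",
                        values_to = "log10_ratio") |>
    dplyr::mutate(glycan = factor(.data$glycan, levels = colnames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$glycan, y = .data$sample_id,
                                   fill = .data$log10_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey85") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 ratio") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' Group comparison plot for derived traits
#'
#' Boxplots of trait values by diet group, faceted by trait, annotated with
#' the pooled-stratum significance stars.
#'
#' @param traits A [compute_traits()] table.
#' @param stats Optional matching [compare_groups()] result for star
#'   annotations.
#' @param which Traits to show (default all registry traits present).
#' @return A ggplot object.
#' @export
plot_trait_groups <- function(traits, stats = NULL, which = NULL) {
  keys <- intersect(c("sample_id", "mouse_id", "group", "sex", "week"),
                    names(traits))
  long <- tibble::as_tibble(traits) |>
    tidyr::pivot_longer(-dplyr::all_of(keys), names_to = "trait",
                        values_to = "value")
  if (!is.null(which)) long <- dplyr::filter(long, .data$trait %in% which)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                          fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "derived trait value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(stats)) {
    ann <- stats |>
      dplyr::filter(.data$week == "pooled", .data$sex == "pooled") |>
      dplyr::transmute(trait = .data$unit, label = .data$stars)
    if (!is.null(which)) ann <- dplyr::filter(ann, .data$trait %in% which)
    p <- p + ggplot2::geom_text(
      data = dplyr::semi_join(
        dplyr::summarise(dplyr::group_by(long, .data$trait),
                         y = max(.data$value, na.rm = TRUE),
                         .groups = "drop") |>
          dplyr::left_join(ann, by = "trait"),
        long, by = "trait"),
      ggplot2::aes(x = 1.5, y = .data$y, label = .data$label),
      inherit.aes = FALSE)
  }
  p
}

#' Calibration residual plot
#'
#' Pre- and post-fit calibrant mass errors against m/z for one recalibration.
#'
#' @param recal A [recalibrate()] result.
#' @return A ggplot object.
#' @export
plot_calibration <- function(recal) {
  res <- tidy(recal) |>
    tidyr::pivot_longer(c("error_pre", "error_post"), names_to = "stage",
                        values_to = "error_da") |>
    dplyr::mutate(stage = factor(.data$stage, c("error_pre", "error_post"),
                                 c("before", "after")))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$theoretical,
                                    y = .data$error_da,
                                    colour = .data$stage)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "calibrant m/z", y = "mass error (Da)",
                  colour = "fit") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
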