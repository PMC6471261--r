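#' Bar chart of up/down DEM counts per comparison
#'
#' @param dems A `mejamir_dem` tibble.
#' @returns A ggplot.
#' @export
plot_dem_counts <- function(dems) {
  glance(dems) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(direction = sub("^n_", "", .data$direction)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$comparison, y = .data$n,
                                 fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "differentially expressed miRNAs") +
    ggplot2::theme_minimal()
}

#' Temporal profile plot of clustered miRNAs
#'
#' One facet per model profile (significant profiles first), grey member
#' trajectories with the profile shape overlaid.
#'
#' @param x A `mejamir_stem` result.
#' @param max_profiles Facets shown.
#' @returns A ggplot.
#' @export
plot_stem_profiles <- function(x, max_profiles = 8) {
  prof <- head(x$profiles, max_profiles)
  shapes <- prof |>
    tidyr::pivot_longer(dplyr::all_of(c("v1", "v2", "v3", "v4")),
                        names_to = "tp", values_to = "value") |>
    dplyr::mutate(timepoint = factor(TIMEPOINTS[as.integer(substr(.data$tp, 2, 2))],
                                     TIMEPOINTS))
  members <- x$assignments |>
    dplyr::filter(.data$profile_id %in% prof$profile_id) |>
    tidyr::pivot_longer(dplyr::all_of(c("v1", "v2", "v3", "v4")),
                        names_to = "tp", values_to = "value") |>
    dplyr::mutate(timepoint = factor(TIMEPOINTS[as.integer(substr(.data$tp, 2, 2))],
                                     TIMEPOINTS))
  ggplot2::ggplot(members, ggplot2::aes(.data$timepoint, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$mirna_id),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = shapes, ggplot2::aes(group = 1),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~profile_id) +
    ggplot2::labs(x = NULL, y = "log2 fold change vs CK") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mejamir_stem <- function(object, ...) plot_stem_profiles(object, ...)

#' Enrichment dot plot (top terms by p-value)
#'
#' Rich factor on x, term on y, dot size = m, colour = Q-value.
#'
#' @param x A `mejamir_enrich` tibble.
#' @param top_n Terms shown.
#' @returns A ggplot.
#' @export
plot_enrichment <- function(x, top_n = 20) {
  d <- head(dplyr::arrange(x, .data$p_value), top_n) |>
    dplyr::mutate(label = dplyr::coalesce(.data$name, .data$term_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rich_factor,
                                  y = stats::reorder(.data$label,
                                                     -.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$m,
                                     colour = .data$q_value)) +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "rich factor (m/M)", y = NULL, colour = "Qvalue",
                  size = "genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mejamir_enrich <- function(object, ...) plot_enrichment(object, ...)

#' Side-by-side qPCR vs sequencing fold changes
#'
#' @param folds Tibble from [qpcr_folds()].
#' @param dems A `mejamir_dem` tibble (CK-VS-* comparisons used).
#' @returns A ggplot.
#' @export
plot_qpcr_concordance <- function(folds, dems) {
  conc <- concordance(folds, dems)
  conc$table |>
    dplyr::mutate(qpcr = log2(.data$fold), sequencing = .data$log2fc) |>
    tidyr::pivot_longer(c("qpcr", "sequencing"), names_to = "method",
                        values_to = "log2_fold") |>
    ggplot2::ggplot(ggplot2::aes(.data$timepoint, .data$log2_fold,
                                 fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~assay) +
    ggplot2::labs(x = NULL, y = "log2 fold change vs CK") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
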