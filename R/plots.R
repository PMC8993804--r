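depth_label <- function(top, bottom) {
  factor(paste0(top, "–", bottom, " cm"),
         levels = unique(paste0(top, "–", bottom, " cm")[order(top)]))
}

#' Depth profile of a partition variable
#'
#' Plots per-plot values and the across-plot mean of a tracer-partition
#' output (e.g. `net_rhizo_c_mg_per_kg` or `clvr_percent`) against depth,
#' one panel per treatment, with depth increasing downwards as in a soil
#' profile.
#'
#' @param partition Output of [partition_rhizodeposition()].
#' @param var Column to plot (string).
#' @return A ggplot object.
#' @examples
#' sim <- simulate_tracer_experiment(scenario_config(seed = 1))
#' plot_depth_profile(partition_rhizodeposition(sim$samples),
#'                    "net_rhizo_c_mg_per_kg")
#' @export
plot_depth_profile <- function(partition, var = "net_rhizo_c_mg_per_kg") {
  stopifnot(var %in% names(partition))
  df <- partition |>
    dplyr::mutate(
      depth = depth_label(.data$depth_top_cm, .data$depth_bottom_cm),
      treatment = ifelse(is.na(.data$n_rate), .data$species,
                         paste0(.data$species,
                                ifelse(.data$n_rate > 0,
                                       paste0("-", .data$n_rate, "N"), ""))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[var]],
                                   y = .data$depth)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 3, colour = "firebrick") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = var, y = "depth interval") +
    ggplot2::theme_minimal()
}

#' Plot a relative microbial stabilization profile
#'
#' Bars of the RMS index per depth interval and treatment; positive values
#' (necromass-dominated tracer fate) point right, negative (living-biomass
#' dominated) left. Depths outside the 0-100 cm reported range are drawn
#' hollow.
#'
#' @param object A `rhizo_rms_profile` from [rms_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhizo_rms_profile <- function(object, ...) {
  df <- object |>
    dplyr::filter(.data$defined) |>
    dplyr::mutate(
      depth = depth_label(.data$depth_top_cm, .data$depth_bottom_cm),
      treatment = ifelse(is.na(.data$n_rate), .data$species,
                         paste0(.data$species,
                                ifelse(.data$n_rate > 0,
                                       paste0("-", .data$n_rate, "N"), ""))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rms, y = .data$depth,
                                   alpha = .data$in_reported_range)) +
    ggplot2::stat_summary(fun = mean, geom = "col", orientation = "y") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = sprintf("RMS (log%g APE AS / APE PLFA)",
                              object$log_base[1]),
                  y = "depth interval") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Group means with significance letters
#'
#' @param object A `rhizo_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhizo_comparison <- function(object, ...) {
  df <- object$letters
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$group,
                                                      -.data$mean),
                                   y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -0.4) +
    ggplot2::labs(x = object$tukey_factor,
                  y = paste0(object$response,
                             if (object$transform_applied == "log")
                               " (log scale)" else "")) +
    ggplot2::theme_minimal()
}
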