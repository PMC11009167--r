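#' Plot predicted versus chronological age
#'
#' Dots are per-pseudo-replicate predictions, crosses the per-sample means,
#' and the dashed line the perfect-prediction reference y = x.
#'
#' @param object a `tc_cv`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tc_cv <- function(object, ...) {
  p <- object$predictions
  means <- p |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(age = .data$age[1], predicted = mean(.data$predicted),
                     .groups = "drop")
  ggplot2::ggplot(p, ggplot2::aes(x = .data$age, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_point(alpha = 0.5, size = 1.5) +
    ggplot2::geom_point(data = means, shape = 4, size = 3, stroke = 1.2) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "predicted cell tree age (years)") +
    ggplot2::theme_minimal()
}

#' Plot age difference and age acceleration
#'
#' @param cv a `tc_cv`.
#' @param which `"difference"` (predicted minus chronological, with the
#'   fitted trend of predicted on chronological age) or `"acceleration"`
#'   (residual from that trend).
#' @return A ggplot object.
#' @export
plot_age_acceleration <- function(cv, which = c("acceleration", "difference")) {
  which <- match.arg(which)
  aa <- age_acceleration(cv)
  yvar <- if (which == "acceleration") "age_acceleration" else "age_difference"
  ggplot2::ggplot(aa, ggplot2::aes(x = .data$age, y = .data[[yvar]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "chronological age (years)",
                  y = paste(gsub("_", " ", yvar), "(years)")) +
    ggplot2::theme_minimal()
}

#' Plot a cell lineage tree
#'
#' Thin wrapper over [ape::plot.phylo()] with tip labels suppressed (cell
#' trees have hundreds of tips).
#'
#' @param t a `phylo` tree.
#' @param type passed to [ape::plot.phylo()]; `"fan"` gives the circular
#'   rendering.
#' @param ... further arguments to [ape::plot.phylo()].
#' @return Invisibly, the tree.
#' @export
plot_cell_tree <- function(t, type = "fan", ...) {
  ape::plot.phylo(t, type = type, show.tip.label = FALSE, ...)
  invisible(t)
}
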