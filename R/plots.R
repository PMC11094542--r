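#' Quadrant scatter of enzymatic stoichiometry
#'
#' The classic limitation scatter: x = (LAP+NAG)/AP, y = BG/(LAP+NAG);
#' reference lines at 1 split the plane into C&N / C&P / N / P quadrants.
#'
#' @param limitation output of [enzyme_limitation()].
#' @return a ggplot.
#' @export
plot_enzyme_quadrants <- function(limitation) {
  ggplot2::ggplot(limitation,
                  ggplot2::aes(x = .data$quad_x, y = .data$quad_y,
                               colour = .data$quadrant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "(LAP + NAG) / AP", y = "BG / (LAP + NAG)",
                  colour = "limitation") +
    ggplot2::theme_minimal()
}

#' Enzyme-allocation vectors in the unit square
#'
#' Points (x, y) with the 45-degree reference diagonal separating N- from
#' P-limited samples.
#'
#' @param vectors output of [enzyme_vectors()] or [enzyme_limitation()].
#' @return a ggplot.
#' @export
plot_enzyme_vectors <- function(vectors) {
  ggplot2::ggplot(vectors, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$angle_deg), size = 2) +
    ggplot2::scale_colour_gradient2(midpoint = 45, low = "#2166ac",
                                    mid = "grey60", high = "#b2182b") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "(BG + CB) / (BG + CB + AP)",
                  y = "(BG + CB) / (BG + CB + NAG + LAP)",
                  colour = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' @rdname pcoa_ordination
#' @param object a `crust_pcoa`.
#' @param groups optional per-sample group labels for colouring.
#' @export
autoplot.crust_pcoa <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) df$group <- groups[df$sample_id]
  pe <- object$proportion_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::labs(x = sprintf("PCoA1 (%.1f%%)", 100 * pe[1]),
                  y = sprintf("PCoA2 (%.1f%%)", 100 * pe[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point(size = 2)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
}

#' Stacked bars of assembly-process fractions
#'
#' @param fractions output of [assembly_fractions()].
#' @return a ggplot.
#' @export
plot_assembly_fractions <- function(fractions) {
  df <- dplyr::filter(fractions, .data$process != "undefined")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fraction,
                                   fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of pairs", fill = "process") +
    ggplot2::theme_minimal()
}

#' Pairwise betaNTI distribution with the +/-2 reference band
#'
#' @param pairs output of [assembly_pairs()].
#' @param groups optional named sample -> group vector; within-group pairs
#'   are shown per group.
#' @return a ggplot.
#' @export
plot_bnti <- function(pairs, groups = NULL) {
  df <- tibble::as_tibble(pairs)
  df$group <- if (is.null(groups)) "all" else
    ifelse(groups[df$sample_a] == groups[df$sample_b],
           as.character(groups[df$sample_a]), NA_character_)
  df <- dplyr::filter(df, !is.na(.data$group), is.finite(.data$bnti))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$bnti)) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.3) +
    ggplot2::labs(x = NULL, y = expression(beta * "NTI")) +
    ggplot2::theme_minimal()
}

#' @rdname complexity_ratio_fit
#' @param object a `crust_fit`.
#' @param ... unused.
#' @export
autoplot.crust_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[object$ratio]],
                                   y = .data$complexity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "#2166ac") +
    ggplot2::labs(x = sprintf("enzyme ratio (%s)", object$ratio),
                  y = "network complexity (z-score)") +
    ggplot2::theme_minimal()
}
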