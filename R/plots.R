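# ggplot2 views of the result objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an optimality curve
#'
#' Optimal expression `Z_opt(P)` with the inflection point marked.
#'
#' @param object A `lac_optimality_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lac_optimality_curve <- function(object, ...) {
  infl <- attr(object, "inflection_p")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pgal, y = .data$z_opt)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = infl, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::annotate("text", x = infl, y = 0.05, hjust = -0.1,
                      label = sprintf("inflection %.0f uM", infl),
                      size = 3) +
    ggplot2::labs(x = "Pgal (uM)", y = "optimal expression Z_opt",
                  title = "Optimal lac expression vs carbon source") +
    ggplot2::theme_minimal()
}

#' Plot a tradeoff curve
#'
#' Constant-expression growth pairs for the two environments, the Pareto
#' front chord, and the regulated cross point.
#'
#' @param object A `lac_tradeoff`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lac_tradeoff <- function(object, ...) {
  cross <- tibble(g_low = object$cross[["g_low"]],
                  g_high = object$cross[["g_high"]])
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$g_low, y = .data$g_high)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$iptg), vjust = -0.7,
                       size = 3) +
    ggplot2::geom_point(data = cross, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::labs(
      x = sprintf("growth at %g uM Pgal (dbl/hr)", object$p_low),
      y = sprintf("growth at %g uM Pgal (dbl/hr)", object$p_high),
      title = "Cross-environment tradeoff of constant expression",
      subtitle = "points: constant IPTG (uM); cross: regulated optimum") +
    ggplot2::theme_minimal()
}

#' Plot an expression trajectory
#'
#' Population-average uninduced and induced expression over generations.
#'
#' @param object A `lac_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lac_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("generation", "expr_uninduced", "expr_induced")],
    cols = c("expr_uninduced", "expr_induced"),
    names_to = "assay", values_to = "expression")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation,
                                     y = .data$expression,
                                     colour = .data$assay)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(
      values = c(expr_uninduced = "black", expr_induced = "grey55"),
      labels = c(expr_uninduced = "uninduced (0 uM IPTG)",
                 expr_induced = "induced (220 uM IPTG)")) +
    ggplot2::labs(x = "generations", y = "mean expression (of WT induced)",
                  colour = NULL,
                  title = "Population-average expression during adaptation") +
    ggplot2::theme_minimal()
}

#' Contour view of a growth landscape
#'
#' Evaluates either a fitted model or an interpolated surface on a dense
#' (IPTG, Pgal) grid and draws filled contours on log axes.
#'
#' @param x A [lac_growth_params()] object or a surface function from
#'   [interpolate_landscape()].
#' @param i_range,p_range Concentration ranges (uM).
#' @param n Grid resolution per axis.
#' @return A ggplot.
#' @export
plot_landscape <- function(x, i_range = c(0, 220), p_range = c(0, 500),
                           n = 80) {
  grid <- tidyr::expand_grid(
    iptg = exp(seq(log1p(i_range[1]), log1p(i_range[2]), length.out = n)) - 1,
    pgal = exp(seq(log1p(p_range[1]), log1p(p_range[2]), length.out = n)) - 1)
  grid$growth <- if (is.function(x)) x(grid$iptg, grid$pgal)
  else growth_rate(grid$iptg, grid$pgal, as_growth_params(x))
  ggplot2::ggplot(grid, ggplot2::aes(x = log1p(.data$iptg),
                                     y = log1p(.data$pgal),
                                     z = .data$growth)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::labs(x = "log(1 + IPTG uM)", y = "log(1 + Pgal uM)",
                  fill = "growth (dbl/hr)",
                  title = "Growth landscape g(I, P)") +
    ggplot2::theme_minimal()
}
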