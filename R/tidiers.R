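# broom-style tidiers

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a landscape fit
#'
#' @param x A `lac_landscape_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`, `half_width`
#'   (95%, from the fit curvature).
#' @export
tidy.lac_landscape_fit <- function(x, ...) x$conf

#' @rdname tidy.lac_landscape_fit
#' @return `glance()`: a one-row tibble with `residual_rms`, `converged`,
#'   `n_conditions`, `n_free`.
#' @export
glance.lac_landscape_fit <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, converged = x$converged,
         n_conditions = x$n_conditions, n_free = nrow(x$conf))
}

#' Tidy a selection-coefficient fit
#'
#' @param x A `lac_selection_fit`.
#' @param ... Unused.
#' @return One row per parameter (`s`, `x0`) with estimates; `s` carries its
#'   profile-based 95% half-width.
#' @export
tidy.lac_selection_fit <- function(x, ...) {
  tibble(term = c("s", "x0"), estimate = c(x$s, x$x0),
         half_width = c(x$s_half_width, NA_real_))
}

#' @rdname tidy.lac_selection_fit
#' @export
glance.lac_selection_fit <- function(x, ...) {
  tibble(s = x$s, x0 = x$x0, residual_rms = x$residual_rms,
         s_half_width = x$s_half_width, converged = x$converged,
         n_obs = x$n_obs)
}

#' Tidy a calibrated ground truth
#'
#' @param x A `lac_ground_truth`.
#' @param ... Unused.
#' @return The per-anchor residual table.
#' @export
tidy.lac_ground_truth <- function(x, ...) x$residuals
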