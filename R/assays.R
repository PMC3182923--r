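# Plate-reader assay reductions: growth rate from OD600 curves, LacZ activity
# from FDG fluorescence curves.

validate_plate_series <- function(series, channel) {
  need <- c("time_min", "value")
  if (!all(need %in% names(series)))
    abort("A plate time series needs columns `time_min` and `value`.")
  if ("channel" %in% names(series)) {
    ch <- unique(series$channel)
    if (length(ch) != 1 || ch != channel)
      abort(paste0("Series channel must be \"", channel, "\"."))
  }
  if (nrow(series) < 10) abort("A plate time series needs >= 10 samples.")
  if (any(diff(series$time_min) <= 0))
    abort("`time_min` must be strictly increasing.")
  if (any(series$value < 0)) abort("Series values must be nonnegative.")
  invisible(series)
}

#' Growth rate from an OD600 time series
#'
#' Least-squares slope of `log2(OD)` versus time (hours) over the maximal
#' contiguous run of samples inside the exponential-phase OD window, i.e. the
#' growth rate in doublings/hr. The window excludes the sub-detection start
#' and the stationary plateau.
#'
#' @param series A plate time-series tibble (`time_min`, `value`, optionally
#'   `channel == "od600"`).
#' @param od_window Length-2 OD window `(min_od, max_od)` defining
#'   exponential phase.
#' @return Growth rate, doublings/hr.
#' @examples
#' od <- generate_od_curve(1.0, noise_cv = 0, seed = 1)
#' growth_rate_from_od(od)  # 1.0
#' @export
growth_rate_from_od <- function(series, od_window = c(1e-3, 1e-1)) {
  validate_plate_series(series, "od600")
  stopifnot(length(od_window) == 2, od_window[1] < od_window[2])
  inside <- series$value >= od_window[1] & series$value <= od_window[2]
  runs <- rle(inside)
  if (!any(runs$values & runs$lengths >= 5))
    abort("Fewer than 5 contiguous samples inside the OD window.")
  ends <- cumsum(runs$lengths)
  i <- which.max(ifelse(runs$values, runs$lengths, 0))
  idx <- (ends[i] - runs$lengths[i] + 1):ends[i]
  fit <- lm(log2(value) ~ I(time_min / 60), data = series[idx, ])
  unname(coef(fit)[2])
}

#' LacZ activity from an FDG fluorescence time series
#'
#' The maximum over sliding windows of the least-squares fluorescence slope,
#' normalized by culture density. Proportional to the amount of active LacZ;
#' linear over many orders of magnitude of activity.
#'
#' @param series A plate time-series tibble (`time_min`, `value`, optionally
#'   `channel == "fdg"`).
#' @param window_points Sliding-window length in samples (>= 3).
#' @param density_norm OD600 used to normalize (> 0).
#' @return Activity in (fluorescence units / min) per OD, arbitrary scale.
#' @export
lacz_activity_from_fdg <- function(series, window_points = 5,
                                   density_norm = 1) {
  validate_plate_series(series, "fdg")
  if (window_points < 3) abort("`window_points` must be >= 3.")
  if (!(density_norm > 0)) abort("`density_norm` must be positive.")
  n <- nrow(series)
  if (window_points > n)
    abort("`window_points` exceeds the series length.")
  t <- series$time_min; y <- series$value
  slopes <- vapply(seq_len(n - window_points + 1), function(i) {
    j <- i:(i + window_points - 1)
    tt <- t[j] - mean(t[j])
    sum(tt * (y[j] - mean(y[j]))) / sum(tt^2)
  }, numeric(1))
  max(slopes) / density_norm
}
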