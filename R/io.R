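# Readers and writers for the pipeline's plain-text formats:
#   growth grid CSV     iptg_uM,pgal_uM,replicate,growth_dbl_per_hr
#   trajectory CSV      generation,expr_uninduced,expr_induced
#   plate series CSV    well,channel,time_min,value
#   model params JSON   {g0, induction{...}, cost{...}, benefit{...}}
#   schedule JSON       [{iptg_uM, pgal_uM, cycles}, ...]
# Validation errors name the file and the offending column/field.

.grid_cols <- c(iptg_uM = "iptg", pgal_uM = "pgal", replicate = "replicate",
                growth_dbl_per_hr = "growth")

check_header <- function(found, expected, path) {
  missing <- setdiff(expected, found)
  extra <- setdiff(found, expected)
  if (length(missing) || length(extra))
    abort(paste0("Malformed CSV `", path, "`: ",
                 if (length(missing)) paste0("missing column(s) ",
                                             paste(missing, collapse = ", ")),
                 if (length(missing) && length(extra)) "; ",
                 if (length(extra)) paste0("unexpected column(s) ",
                                           paste(extra, collapse = ", "))))
}

#' Read / write a growth grid CSV
#'
#' Schema: header `iptg_uM,pgal_uM,replicate,growth_dbl_per_hr`, UTF-8,
#' `.` decimal. The writer emits a deterministic row order (pgal, iptg,
#' replicate ascending).
#'
#' @param path File path.
#' @return `read_growth_grid()`: a growth-grid tibble (`iptg`, `pgal`,
#'   `replicate`, `growth`).
#' @export
read_growth_grid <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  check_header(names(df), names(.grid_cols), path)
  names(df) <- .grid_cols[names(df)]
  if (any(is.na(df$growth)))
    abort(paste0("Malformed CSV `", path, "`: non-numeric or missing ",
                 "values in column growth_dbl_per_hr."))
  validate_growth_grid(df, arg = path)
  as_tibble(df)
}

#' @rdname read_growth_grid
#' @param grid A growth-grid tibble.
#' @export
write_growth_grid <- function(grid, path) {
  validate_growth_grid(grid)
  out <- grid |>
    arrange(.data$pgal, .data$iptg, .data$replicate) |>
    dplyr::select(iptg_uM = "iptg", pgal_uM = "pgal",
                  replicate = "replicate", growth_dbl_per_hr = "growth")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write an expression trajectory CSV
#'
#' Schema: header `generation,expr_uninduced,expr_induced`.
#'
#' @param path File path.
#' @return `read_trajectory()`: a `lac_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  check_header(names(df), c("generation", "expr_uninduced", "expr_induced"),
               path)
  if (is.unsorted(df$generation))
    abort(paste0("Malformed CSV `", path, "`: column generation must be ",
                 "nondecreasing."))
  structure(as_tibble(df), class = c("lac_trajectory", class(tibble())))
}

#' @rdname read_trajectory
#' @param traj A trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  need <- c("generation", "expr_uninduced", "expr_induced")
  if (!all(need %in% names(traj)))
    abort("`traj` must have columns generation, expr_uninduced, expr_induced.")
  readr::write_csv(traj[, need], path)
  invisible(path)
}

#' Read / write a plate time-series CSV
#'
#' Long format, one file per plate: header `well,channel,time_min,value`.
#'
#' @param path File path.
#' @return `read_plate_series()`: a tibble; filter on `well`/`channel` before
#'   passing to the assay reductions.
#' @export
read_plate_series <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(), channel = readr::col_character(),
    time_min = readr::col_double(), value = readr::col_double()),
    progress = FALSE)
  check_header(names(df), c("well", "channel", "time_min", "value"), path)
  bad <- setdiff(unique(df$channel), c("od600", "fdg"))
  if (length(bad))
    abort(paste0("Malformed CSV `", path, "`: unknown channel value(s) ",
                 paste(bad, collapse = ", "), "."))
  as_tibble(df)
}

#' @rdname read_plate_series
#' @param series A plate time-series tibble.
#' @export
write_plate_series <- function(series, path) {
  need <- c("well", "channel", "time_min", "value")
  if (!all(need %in% names(series)))
    abort("`series` must have columns well, channel, time_min, value.")
  readr::write_csv(series[, need], path)
  invisible(path)
}

# ---- model parameter JSON ----

.params_schema <- list(
  induction = c("z_basal", "z_max", "k_half", "hill_n", "k_anti"),
  cost = c("eta0", "m_sat", "form"),
  benefit = c("delta", "k_pgal", "hill_p", "z_exponent"))

#' Read / write growth-model parameters as JSON
#'
#' The document mirrors the parameter objects: top-level `g0` plus
#' `induction`, `cost` and `benefit` blocks with exactly the constructor
#' field names. Partial documents are completed from `defaults`; unknown
#' keys are rejected.
#'
#' @param path File path.
#' @param defaults Parameter set supplying unspecified fields.
#' @return `read_params()`: a [lac_growth_params()] object.
#' @export
read_params <- function(path, defaults = lac_default_params()) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  params_from_list(doc, defaults = defaults, where = path)
}

params_from_list <- function(doc, defaults = lac_default_params(),
                             where = "params") {
  known_top <- c("g0", names(.params_schema))
  extra <- setdiff(names(doc), known_top)
  if (length(extra))
    abort(paste0("Unknown key(s) in `", where, "`: ",
                 paste(extra, collapse = ", ")))
  for (blk in names(.params_schema)) {
    extra <- setdiff(names(doc[[blk]]), .params_schema[[blk]])
    if (length(extra))
      abort(paste0("Unknown key(s) in `", where, "` block `", blk, "`: ",
                   paste(extra, collapse = ", ")))
  }
  base <- list(g0 = defaults$g0,
               induction = unclass(defaults$induction),
               cost = unclass(defaults$cost),
               benefit = unclass(defaults$benefit))
  merged <- modifyList(base, doc[!vapply(doc, is.null, logical(1))])
  lac_growth_params(g0 = merged$g0,
                    induction = do.call(lac_induction_params, merged$induction),
                    cost = do.call(lac_cost_params, merged$cost),
                    benefit = do.call(lac_benefit_params, merged$benefit))
}

#' @rdname read_params
#' @param params A [lac_growth_params()] object.
#' @export
write_params <- function(params, path) {
  params <- as_growth_params(params)
  doc <- list(g0 = params$g0,
              induction = unclass(params$induction),
              cost = unclass(params$cost),
              benefit = unclass(params$benefit))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write a calibrated ground truth as JSON
#'
#' The frozen calibration artifact: the model parameters, the noise CV, and
#' the per-anchor calibration residuals.
#'
#' @param path File path.
#' @return `read_ground_truth()`: a `lac_ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("model", "noise_cv", "residuals")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    abort(paste0("Ground-truth JSON `", path, "` lacks field(s): ",
                 paste(missing, collapse = ", ")))
  structure(list(
    model = params_from_list(doc$model,
                             defaults = lac_growth_params(),
                             where = path),
    noise_cv = doc$noise_cv,
    residuals = as_tibble(doc$residuals)), class = "lac_ground_truth")
}

#' @rdname read_ground_truth
#' @param truth A `lac_ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "lac_ground_truth"))
  doc <- list(model = list(g0 = truth$model$g0,
                           induction = unclass(truth$model$induction),
                           cost = unclass(truth$model$cost),
                           benefit = unclass(truth$model$benefit)),
              noise_cv = truth$noise_cv,
              residuals = truth$residuals)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write an environment schedule as JSON
#'
#' An array of `{iptg_uM, pgal_uM, cycles}` entries, applied cyclically.
#'
#' @param path File path.
#' @return `read_schedule()`: a [lac_schedule()] tibble.
#' @export
read_schedule <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc <- as_tibble(doc)
  need <- c("iptg_uM", "pgal_uM", "cycles")
  check_header(names(doc), need, path)
  lac_schedule(iptg = doc$iptg_uM, pgal = doc$pgal_uM, cycles = doc$cycles)
}

#' @rdname read_schedule
#' @param schedule A [lac_schedule()] tibble.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "lac_schedule"))
  out <- tibble(iptg_uM = schedule$iptg, pgal_uM = schedule$pgal,
                cycles = schedule$cycles)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
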