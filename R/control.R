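#' Pipeline control parameters
#'
#' Returns the nested list of tuning parameters driving every stage of the
#' postural-transition pipeline, with the published defaults. Any value
#' can be overridden by name; unknown keys are rejected.
#'
#' Sections and defaults:
#' \describe{
#'   \item{preprocess}{`cutoff_hz = 5` (Hz), `order = 4`, `window = 128`
#'     (samples, 1 s), `bias_var_threshold = 1e-5` (rad^2/s^2).}
#'   \item{posture}{`accel_dev_thresh = 0.05` (m/s^2),
#'     `accel_var_thresh = 0.01` (m^2/s^4), `gyro_var_thresh = 0.01`
#'     (rad^2/s^2), `g0 = 9.81` (m/s^2), `min_sp_s = 0.25` (s),
#'     `wavelet = "coif5"`, `j_lo = 3`, `j_hi = 10`.}
#'   \item{fusion}{`beta_sp = 0.5`, `beta_ap = 0`,
#'     `q0 = c(1, 0, -1, 0)/sqrt(2)`.}
#'   \item{detect}{`height = 0.1`, `prominence = 0.1`,
#'     `merge_window_s = 1` (s), `dz_threshold = 0.1` (m),
#'     `max_search_s = 5` (s), `max_duration_s = 10` (s).}
#'   \item{evaluate}{`tolerance_s = 2` (s).}
#' }
#'
#' @param ... named overrides, e.g. `detect = list(dz_threshold = 0.05)`;
#'   section lists are merged key-wise.
#' @return A nested list of class `pt_control`.
#' @export
pt_control <- function(...) {
  ctrl <- list(
    preprocess = list(cutoff_hz = 5, order = 4, window = 128L,
                      bias_var_threshold = 1e-5),
    posture = list(accel_dev_thresh = 0.05, accel_var_thresh = 0.01,
                   gyro_var_thresh = 0.01, g0 = 9.81, min_sp_s = 0.25,
                   wavelet = "coif5", j_lo = 3L, j_hi = 10L),
    fusion = list(beta_sp = 0.5, beta_ap = 0,
                  q0 = c(1, 0, -1, 0) / sqrt(2)),
    detect = list(height = 0.1, prominence = 0.1, merge_window_s = 1,
                  dz_threshold = 0.1, max_search_s = 5,
                  max_duration_s = 10),
    evaluate = list(tolerance_s = 2)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(ctrl))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown control section(s): ", paste(bad, collapse = ", "))
    for (sec in names(over)) {
      badk <- setdiff(names(over[[sec]]), names(ctrl[[sec]]))
      if (length(badk))
        stop("unknown key(s) in [", sec, "]: ", paste(badk, collapse = ", "))
      ctrl[[sec]][names(over[[sec]])] <- over[[sec]]
    }
  }
  validate_control(ctrl)
  class(ctrl) <- "pt_control"
  ctrl
}

validate_control <- function(ctrl) {
  pos <- c(ctrl$preprocess$cutoff_hz, ctrl$preprocess$order,
           ctrl$preprocess$window, ctrl$preprocess$bias_var_threshold,
           ctrl$posture$accel_dev_thresh, ctrl$posture$accel_var_thresh,
           ctrl$posture$gyro_var_thresh, ctrl$posture$g0,
           ctrl$detect$height, ctrl$detect$prominence,
           ctrl$detect$dz_threshold, ctrl$detect$max_search_s,
           ctrl$evaluate$tolerance_s)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("parameter error: thresholds must be positive and finite")
  if (ctrl$posture$j_lo < 1L || ctrl$posture$j_hi <= ctrl$posture$j_lo)
    stop("parameter error: need 1 <= j_lo < j_hi")
  if (length(ctrl$fusion$q0) != 4L)
    stop("parameter error: q0 must have 4 components")
  invisible(ctrl)
}

#' Read pipeline control parameters from a YAML file
#'
#' The file holds the same nested sections as [pt_control()]; absent keys
#' keep their defaults, unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pt_control` list.
#' @export
read_control_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$fusion$q0)) raw$fusion$q0 <- as.numeric(raw$fusion$q0)
  do.call(pt_control, raw)
}

#' Write pipeline control parameters to a YAML file
#'
#' @param control a `pt_control` list.
#' @param path output path.
#' @export
write_control_yaml <- function(control, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write config files")
  yaml::write_yaml(unclass(control), path, precision = 15)
  invisible(path)
}
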