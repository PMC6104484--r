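#' Construct an IMU recording
#'
#' Bundles time-synchronized tri-axial accelerometer and gyroscope streams
#' from a lower-back-worn inertial measurement unit into a validated object.
#' Canonical units are m/s^2 (accelerometer) and rad/s (gyroscope); the
#' canonical axis convention is x = vertical (cranial when standing),
#' y = medio-lateral, z = anterior-posterior.
#'
#' @param time numeric vector of sample times in seconds; strictly
#'   increasing with constant step `1/sample_rate` (tolerance 1e-6 s).
#' @param accel n x 3 numeric matrix of accelerations, m/s^2.
#' @param gyro n x 3 numeric matrix of angular velocities, rad/s.
#' @param sample_rate sampling frequency in samples/s (nominally 128).
#' @param axis_convention character vector of length 3 describing which
#'   input column maps to each body axis, e.g. `c("x", "y", "z")` or
#'   `c("-z", "y", "x")` (see [axis_map()]). Stored for provenance; the
#'   stored matrices are always in canonical order.
#' @param meta free-form list of provenance information.
#'
#' @return An object of class `imu_recording`: a list with elements
#'   `time`, `accel`, `gyro`, `sample_rate`, `axis_convention`, `meta`.
#' @export
imu_recording <- function(time, accel, gyro, sample_rate = 128,
                          axis_convention = c("x", "y", "z"),
                          meta = list()) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  n <- length(time)
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop("accel and gyro must have exactly 3 columns")
  if (nrow(accel) != n || nrow(gyro) != n)
    stop("time, accel and gyro must have equal length")
  if (n < 2L * sample_rate)
    stop("recording too short: need at least 2 s (", 2L * sample_rate,
         " samples), got ", n)
  dt <- diff(time)
  if (any(dt <= 0))
    stop("integrity error: time stamps not strictly increasing")
  if (any(abs(dt - 1 / sample_rate) > 1e-6))
    stop("integrity error: non-uniform sampling beyond 1e-6 s tolerance")
  if (any(!is.finite(accel)))
    stop("integrity error: non-finite accelerometer values")
  gyro_limit <- 2000 * pi / 180
  if (any(abs(gyro) > gyro_limit, na.rm = TRUE))
    stop("integrity error: gyroscope values exceed the 2000 deg/s range")
  dimnames(accel) <- list(NULL, c("x", "y", "z"))
  dimnames(gyro) <- list(NULL, c("x", "y", "z"))
  structure(
    list(time = as.numeric(time), accel = accel, gyro = gyro,
         sample_rate = sample_rate,
         axis_convention = axis_convention, meta = meta),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat("IMU recording:", nrow(x$accel), "samples at", x$sample_rate,
      "samples/s (", sprintf("%.1f", nrow(x$accel) / x$sample_rate),
      "s )\n")
  cat("  axis convention:", paste(x$axis_convention, collapse = ", "), "\n")
  invisible(x)
}

#' Signed axis permutation matrix
#'
#' Builds the 3 x 3 signed permutation matrix that maps sensor columns to
#' the canonical body axes (x vertical, y medio-lateral, z
#' anterior-posterior). Element i of `convention` names the sensor column
#' (optionally sign-flipped) that supplies canonical axis i.
#'
#' @param convention character vector of length 3 with entries from
#'   `"x","y","z"` optionally prefixed by `-`, e.g. `c("-z","y","x")`
#'   meaning canonical x = -sensor z, canonical y = sensor y, canonical
#'   z = sensor x.
#' @return 3 x 3 numeric matrix `M` such that `v_canonical = M %*% v_sensor`.
#' @export
axis_map <- function(convention) {
  if (length(convention) != 3L)
    stop("axis convention must have 3 entries")
  M <- matrix(0, 3, 3)
  axes <- c(x = 1L, y = 2L, z = 3L)
  for (i in 1:3) {
    s <- convention[i]
    sgn <- 1
    if (startsWith(s, "-")) { sgn <- -1; s <- substring(s, 2) }
    else if (startsWith(s, "+")) s <- substring(s, 2)
    j <- axes[[s]]
    if (is.null(j)) stop("unknown axis label: ", convention[i])
    M[i, j] <- sgn
  }
  if (any(colSums(abs(M)) != 1))
    stop("axis convention is not a permutation of x, y, z")
  M
}

apply_axis_map <- function(mat, M) {
  out <- mat %*% t(M)
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

# interpolate interior NaN runs shorter than max_gap samples; error on longer
fill_short_gaps <- function(x, max_gap, what = "signal") {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (any(r$lengths[runs] > max_gap))
    stop("integrity error: missing-value run longer than ", max_gap,
         " samples in ", what)
  if (bad[1L] || bad[length(x)])
    stop("integrity error: missing values at the ", what, " boundary")
  idx <- seq_along(x)
  x[bad] <- stats::approx(idx[!bad], x[!bad], xout = idx[bad])$y
  warning("interpolated ", sum(bad), " missing samples (", length(runs),
          " short gaps) in ", what)
  x
}

#' Read an IMU session from CSV
#'
#' Reads a comma-separated session file with header columns
#' `t, ax, ay, az, gx, gy, gz` ('.' decimal separator), converts units and
#' axis order to canonical form, and validates stream integrity. Gyroscope
#' values recorded in deg/s are converted to rad/s. Missing-value (NaN)
#' runs shorter than 0.25 s are linearly interpolated with a warning;
#' longer runs are an integrity error.
#'
#' @param path path to the CSV file.
#' @param convention axis convention of the file's columns (see
#'   [axis_map()]); default already canonical.
#' @param gyro_units `"rad/s"` (default) or `"deg/s"`.
#' @param sample_rate expected sampling rate; inferred from the time column
#'   when `NULL`.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, convention = c("x", "y", "z"),
                         gyro_units = c("rad/s", "deg/s"),
                         sample_rate = NULL) {
  gyro_units <- match.arg(gyro_units)
  dat <- utils::read.csv(path, header = TRUE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  tm <- as.numeric(dat$t)
  if (anyDuplicated(tm))
    stop("integrity error: duplicated time stamps")
  if (is.null(sample_rate)) {
    dt <- stats::median(diff(tm))
    sample_rate <- round(1 / dt)
  }
  max_gap <- max(1L, floor(0.25 * sample_rate) - 1L)
  accel <- sapply(c("ax", "ay", "az"),
                  function(k) fill_short_gaps(as.numeric(dat[[k]]), max_gap, k))
  gyro <- sapply(c("gx", "gy", "gz"),
                 function(k) fill_short_gaps(as.numeric(dat[[k]]), max_gap, k))
  if (gyro_units == "deg/s") gyro <- gyro * pi / 180
  M <- axis_map(convention)
  accel <- apply_axis_map(accel, M)
  gyro <- apply_axis_map(gyro, M)
  imu_recording(tm, accel, gyro, sample_rate = sample_rate,
                meta = list(source = path, gyro_units_in = gyro_units))
}

#' Write an IMU session to CSV
#'
#' Inverse of [read_imu_csv()]: writes canonical-unit streams with header
#' `t, ax, ay, az, gx, gy, gz`. Values are written in full double precision
#' so that a read/write round trip is the identity to 1e-9.
#'
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(t = rec$time,
                   ax = rec$accel[, 1], ay = rec$accel[, 2],
                   az = rec$accel[, 3],
                   gx = rec$gyro[, 1], gy = rec$gyro[, 2],
                   gz = rec$gyro[, 3])
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a reference annotation set
#'
#' Reference postural-transition events, typically derived from a video
#' rating timed in full seconds.
#'
#' @param start,end numeric vectors, event start/end times in seconds.
#' @param direction character vector with entries `"SiSt"` (sit-to-stand)
#'   or `"StSi"` (stand-to-sit).
#' @param resolution timing resolution of the reference in seconds
#'   (1.0 for video-derived references).
#' @return An object of class `annotation_set`: a data.frame with columns
#'   `start`, `end`, `direction`, sorted by `start`, with attribute
#'   `resolution`.
#' @export
annotation_set <- function(start, end, direction, resolution = 1.0) {
  direction <- as.character(direction)
  if (length(start) != length(end) || length(start) != length(direction))
    stop("start, end and direction must have equal length")
  if (any(!direction %in% c("SiSt", "StSi")))
    stop("validation error: unknown direction label: ",
         paste(unique(setdiff(direction, c("SiSt", "StSi"))), collapse = ", "))
  if (any(end <= start))
    stop("validation error: event end <= start")
  o <- order(start)
  ann <- data.frame(start = as.numeric(start)[o], end = as.numeric(end)[o],
                    direction = direction[o], stringsAsFactors = FALSE)
  if (nrow(ann) > 1L && any(ann$start[-1L] < ann$end[-nrow(ann)]))
    stop("validation error: overlapping events")
  attr(ann, "resolution") <- resolution
  class(ann) <- c("annotation_set", "data.frame")
  ann
}

#' Read reference annotations from CSV
#'
#' @param path CSV file with columns `start_s`, `end_s`,
#'   `direction` (`SiSt`/`StSi`).
#' @param resolution timing resolution in seconds.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, resolution = 1.0) {
  dat <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "direction")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  annotation_set(dat$start_s, dat$end_s, dat$direction,
                 resolution = resolution)
}

#' Write reference annotations to CSV
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(start_s = ann$start, end_s = ann$end,
                   direction = ann$direction)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected events to CSV
#'
#' One row per event with `start_s, end_s, duration_s, direction, class,
#' delta_dz_m`; times in seconds with 3 decimals (sub-millisecond precision
#' is below the timing resolution of the method). An empty event list
#' yields a header-only file.
#'
#' @param events a `pt_events` data.frame (see [classify_events()]), sorted
#'   by start index.
#' @param path output file path.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(start_s = sprintf("%.3f", events$start_s),
                   end_s = sprintf("%.3f", events$end_s),
                   duration_s = sprintf("%.3f", events$duration),
                   direction = events$direction,
                   class = events$klass,
                   delta_dz_m = sprintf("%.4f", events$delta_dz))
  if (nrow(events) == 0L)
    df <- df[0L, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detected events from CSV
#'
#' @param path file written by [write_events_csv()].
#' @return data.frame with numeric `start_s`, `end_s`, `duration`,
#'   `delta_dz` and character `direction`, `klass`.
#' @export
read_events_csv <- function(path) {
  dat <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "duration_s", "direction", "class",
            "delta_dz_m")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  data.frame(start_s = as.numeric(dat$start_s),
             end_s = as.numeric(dat$end_s),
             duration = as.numeric(dat$duration_s),
             direction = dat$direction, klass = dat$class,
             delta_dz = as.numeric(dat$delta_dz_m),
             stringsAsFactors = FALSE)
}
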