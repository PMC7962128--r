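#' Read a shank gyroscope trace from the package's IMU CSV dialect
#'
#' The dialect is one header row `time_s,gyro_x,gyro_y,gyro_z` followed by
#' one row per sample, time in seconds and angular velocities in deg/s.
#' Only the sagittal (y-axis) gyro channel is consumed downstream; the x and
#' z columns are carried for completeness and may be absent.
#'
#' Timestamps must be strictly increasing and uniformly spaced: sample
#' intervals deviating from the median interval by more than `jitter_tol`
#' (relative) are rejected, because downstream event detection assumes a
#' constant sampling rate.
#'
#' @param path CSV file path.
#' @param leg which leg the sensor was worn on.
#' @param subject_id subject identifier.
#' @param jitter_tol maximum relative deviation of any sampling interval
#'   from the median interval (default 1%).
#' @return an [angvel_signal] holding the `gyro_y` channel, with
#'   `sample_rate` inferred from the timestamps.
#' @seealso [write_imu_csv()]
#' @export
read_imu_csv <- function(path, leg = c("left", "right"), subject_id = "S1",
                         jitter_tol = 0.01) {
  leg <- match.arg(leg)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("time_s", "gyro_y")) {
    if (!col %in% names(df)) {
      stop_format("IMU CSV %s is missing required column '%s'", path, col)
    }
  }
  tm <- as.numeric(df$time_s)
  if (anyNA(tm) || any(diff(tm) <= 0)) {
    stop_format("IMU CSV %s: time_s must be strictly increasing", path)
  }
  dt <- diff(tm)
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) / dt0 > jitter_tol)) {
    stop_format(
      "IMU CSV %s: non-uniform sampling (interval jitter exceeds %.1f%%)",
      path, 100 * jitter_tol)
  }
  angvel_signal(as.numeric(df$gyro_y), sample_rate = 1 / dt0,
                leg = leg, subject_id = subject_id)
}

#' Write an angular-velocity signal in the IMU CSV dialect
#'
#' Timestamps are reconstructed from the sampling rate starting at zero.
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces samples bit-exactly.
#'
#' @param signal an [angvel_signal].
#' @param path output file path.
#' @param gyro_x,gyro_z optional companion channels (recycled scalar 0 by
#'   default).
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(signal, path, gyro_x = 0, gyro_z = 0) {
  assert_signal(signal)
  n <- length(signal$samples)
  tm <- (seq_len(n) - 1) / signal$sample_rate
  gx <- rep_len(as.numeric(gyro_x), n)
  gz <- rep_len(as.numeric(gyro_z), n)
  lines <- c(
    "time_s,gyro_x,gyro_y,gyro_z",
    sprintf("%.17g,%.17g,%.17g,%.17g", tm, gx, signal$samples, gz)
  )
  writeLines(lines, path)
  invisible(path)
}

# PAMAP2 column layout: 54 space-separated columns per row; col 1 timestamp
# (s), col 2 activityID, col 3 heart rate, then three 17-column IMU blocks.
# Within a block: temperature, 3x accel (16g), 3x accel (6g), 3x gyro
# (rad/s), 3x magnetometer, 4x orientation.
.pamap2_block_start <- c(hand = 4L, chest = 21L, ankle = 38L)
.pamap2_walking_id <- 4L

#' Parse walking segments from a PAMAP2 activity file
#'
#' Reads a PAMAP2 `.dat` protocol file (space-separated, 54 columns), keeps
#' rows whose activity is walking (activity ID 4), extracts the requested
#' IMU site's sagittal gyroscope channel, converts rad/s to deg/s (the
#' package-internal unit), and splits the retained rows into continuous
#' segments wherever consecutive timestamps are more than `gap` seconds
#' apart. Rows with a missing timestamp or gyro value are dropped before
#' segmentation; segments shorter than two samples are discarded.
#'
#' @param path `.dat` file path.
#' @param imu_site which IMU block to read: `"ankle"` (default; the shank
#'   sensor used for gait), `"hand"`, or `"chest"`.
#' @param axis gyro axis within the block, `"x"`, `"y"` (default,
#'   mediolateral/sagittal-plane rotation) or `"z"`.
#' @param leg,subject_id metadata attached to the returned signals (PAMAP2
#'   does not record the instrumented side).
#' @param gap timestamp gap (s) that starts a new segment.
#' @return a list of [angvel_signal] objects, one per continuous walking
#'   segment (possibly empty).
#' @export
read_pamap2 <- function(path, imu_site = c("ankle", "hand", "chest"),
                        axis = c("y", "x", "z"), leg = "left",
                        subject_id = "pamap2", gap = 1) {
  imu_site <- match.arg(imu_site)
  axis <- match.arg(axis)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.table(path, header = FALSE, na.strings = c("NaN", "NA"))
  if (ncol(df) != 54L) {
    stop_format("PAMAP2 file %s has %d columns per line, expected 54",
                path, ncol(df))
  }
  gyro_col <- .pamap2_block_start[[imu_site]] + 7L +
    match(axis, c("x", "y", "z")) - 1L
  keep <- !is.na(df[[2L]]) & df[[2L]] == .pamap2_walking_id &
    !is.na(df[[1L]]) & !is.na(df[[gyro_col]])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(list())
  tm <- df[[1L]]
  omega <- df[[gyro_col]] * 180 / pi
  seg_id <- cumsum(c(1, as.integer(diff(tm) > gap)))
  out <- list()
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 2L) next
    rate <- 1 / stats::median(diff(tm[idx]))
    out[[length(out) + 1L]] <- angvel_signal(
      omega[idx], sample_rate = rate, leg = leg, subject_id = subject_id)
  }
  out
}

#' Load the packaged confusion-matrix fixtures
#'
#' Returns the per-model, per-output confusion counts transcribed from the
#' published clinical validation of the two-part gait network: for each of
#' the four cross-validation models, two detection blocks (normal gait and
#' stroke gait treated in turn as the positive class) and five
#' classification blocks (stroke gait plus the four abnormality labels).
#'
#' One printed cell is inconsistent as published: model 4's circumduction
#' true-negative count reads 489, which makes that block sum to 600 while
#' every other block of the model sums to the fold size 500, and which is
#' irreconcilable with the model's published summary accuracy. The
#' documented correction (489 -> 389) restores both. `corrected = TRUE`
#' (the default) applies it; `corrected = FALSE` returns the verbatim
#' transcription.
#'
#' @param corrected apply the documented single-cell correction.
#' @return a data.frame with columns `model` (1-4), `task`
#'   (`"detection"`/`"classification"`), `label`, `tp`, `fp`, `fn`, `tn`.
#' @examples
#' fx <- load_confusion_fixtures()
#' subset(fx, model == 1 & task == "detection")
#' @export
load_confusion_fixtures <- function(corrected = TRUE) {
  path <- system.file("extdata", "confusion_tables.json",
                      package = "strokegait", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fx <- rbind(
    data.frame(task = "detection", raw$detection,
               stringsAsFactors = FALSE),
    data.frame(task = "classification", raw$classification,
               stringsAsFactors = FALSE)
  )
  fx <- fx[, c("model", "task", "label", "tp", "fp", "fn", "tn")]
  if (corrected && NROW(raw$corrections)) {
    for (i in seq_len(NROW(raw$corrections))) {
      cr <- raw$corrections[i, ]
      row <- fx$model == cr$model & fx$task == cr$task & fx$label == cr$label
      stopifnot(sum(row) == 1L, fx[row, cr$field] == cr$printed)
      fx[row, cr$field] <- cr$corrected
    }
  }
  fx
}

#' Extract one confusion block from the fixture table
#'
#' @param fixtures result of [load_confusion_fixtures()].
#' @param model model number 1-4.
#' @param label block label, e.g. `"normal"`, `"stroke"`, `"drop_foot"`.
#' @return a [confusion_counts] object.
#' @export
fixture_block <- function(fixtures, model, label) {
  row <- fixtures[fixtures$model == model & fixtures$label == label, ]
  if (nrow(row) != 1L) {
    stop_format("no unique fixture block for model %s, label '%s'",
                model, label)
  }
  confusion_counts(row$tp, row$fp, row$fn, row$tn)
}
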