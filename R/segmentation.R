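#' Detect mid-swing events in a shank angular-velocity signal
#'
#' Mid-swing is the instant the shank's sagittal angular velocity reaches
#' its in-cycle maximum, which appears as a tall positive peak once per
#' stride. Peaks are local maxima at or above `min_peak`; when two
#' qualifying peaks are closer than `min_separation`, the taller one is
#' kept (the earlier one if equally tall). Within a flat-topped maximum the
#' earliest sample is reported.
#'
#' An optional zero-phase low-pass Butterworth filter can be applied before
#' peak picking via `lowpass_hz` (requires the `signal` package); the
#' default applies no filtering.
#'
#' @param signal an [angvel_signal].
#' @param min_peak minimum peak height in deg/s (default 50, well below the
#'   mid-swing peak of comfortable-pace walking yet above stance-phase
#'   activity).
#' @param min_separation minimum time between reported peaks in seconds
#'   (default 0.4, roughly half of the shortest plausible stride period).
#' @param lowpass_hz optional low-pass cutoff in Hz applied before
#'   detection; `NULL` (default) disables filtering.
#' @return integer vector of mid-swing sample indices (possibly empty),
#'   strictly increasing.
#' @export
detect_midswing <- function(signal, min_peak = 50, min_separation = 0.4,
                            lowpass_hz = NULL) {
  assert_signal(signal)
  x <- signal$samples
  min_len <- 2 * min_separation * signal$sample_rate
  if (length(x) < min_len) {
    stop_format(
      "signal too short for peak detection: %d samples, need >= %.0f",
      length(x), min_len)
  }
  if (!is.null(lowpass_hz)) {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop_format("the 'signal' package is required for lowpass_hz")
    }
    bf <- signal::butter(2, 2 * lowpass_hz / signal$sample_rate, "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  n <- length(x)
  # local maximum: strictly above predecessor, not below successor; the
  # strict/weak asymmetry reports the first sample of a flat crest
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_peak]
  if (length(cand) == 0L) return(integer(0))
  min_gap <- min_separation * signal$sample_rate
  # keep taller peaks first; stable order makes equal heights favour the
  # earlier sample
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect heel-strike events following mid-swings
#'
#' Heel strike is located at the first negative trough after mid-swing:
#' for each mid-swing index, the first local minimum whose value is below
#' zero, searched up to (not including) the next mid-swing. A mid-swing
#' with no qualifying trough yields `NA` at its position.
#'
#' @param signal an [angvel_signal].
#' @param midswing_indices strictly increasing mid-swing sample indices.
#' @return integer vector aligned with `midswing_indices`; `NA` where no
#'   heel strike was found.
#' @export
detect_heelstrike <- function(signal, midswing_indices) {
  assert_signal(signal)
  x <- signal$samples
  n <- length(x)
  ms <- as.integer(midswing_indices)
  if (length(ms) && (any(ms < 1L | ms > n) || any(diff(ms) <= 0))) {
    stop_format("midswing_indices must be strictly increasing and in range")
  }
  out <- rep(NA_integer_, length(ms))
  for (k in seq_along(ms)) {
    hi <- if (k < length(ms)) ms[k + 1L] - 1L else n
    lo <- ms[k] + 1L
    if (hi - lo < 1L) next
    seg <- lo:hi
    inner <- seg[-c(1L, length(seg))]
    if (length(inner) == 0L) next
    is_min <- x[inner] < x[inner - 1L] & x[inner] <= x[inner + 1L] &
      x[inner] < 0
    if (any(is_min)) out[k] <- inner[which(is_min)[1L]]
  }
  out
}

#' Detect toe-off events (convention)
#'
#' Toe off ends the stance phase, but unlike mid-swing and heel strike it
#' has no sharp signature in the shank angular velocity alone. The
#' convention implemented here places toe off at the most negative local
#' minimum in the window between a cycle's heel strike and the next
#' mid-swing (the pre-swing trough). It is provided for completeness and is
#' not used by the recognition pipeline.
#'
#' @param signal an [angvel_signal].
#' @param midswing_indices mid-swing indices.
#' @param heelstrike_indices aligned heel-strike indices (from
#'   [detect_heelstrike()]).
#' @return integer vector of length `length(midswing_indices) - 1`, the
#'   toe-off preceding each mid-swing after the first; `NA` where
#'   undetermined.
#' @export
detect_toeoff <- function(signal, midswing_indices, heelstrike_indices) {
  assert_signal(signal)
  x <- signal$samples
  ms <- as.integer(midswing_indices)
  hs <- as.integer(heelstrike_indices)
  stopifnot(length(hs) == length(ms))
  if (length(ms) < 2L) return(integer(0))
  out <- rep(NA_integer_, length(ms) - 1L)
  for (k in seq_len(length(ms) - 1L)) {
    if (is.na(hs[k])) next
    lo <- hs[k] + 1L
    hi <- ms[k + 1L] - 1L
    if (hi - lo < 2L) next
    inner <- (lo + 1L):(hi - 1L)
    is_min <- x[inner] < x[inner - 1L] & x[inner] <= x[inner + 1L]
    if (any(is_min)) {
      mins <- inner[is_min]
      out[k] <- mins[which.min(x[mins])]
    }
  }
  out
}

#' Split a signal into raw gait cycles at mid-swing events
#'
#' Cycle `k` spans the half-open sample interval
#' `[midswing(k), midswing(k+1))`, so `n` mid-swing events produce `n - 1`
#' cycles and the cycles concatenate back to the spanned samples exactly.
#' Samples before the first and after the last mid-swing (partial cycles)
#' are discarded.
#'
#' @param signal an [angvel_signal].
#' @param midswing_indices strictly increasing mid-swing indices.
#' @return list of numeric vectors, each with a `span` attribute
#'   `c(start, end)` giving the half-open source interval in sample
#'   indices; empty list when fewer than two indices are supplied.
#' @export
split_cycles <- function(signal, midswing_indices) {
  assert_signal(signal)
  ms <- as.integer(midswing_indices)
  if (length(ms) < 2L) return(list())
  if (any(diff(ms) <= 0) || ms[1L] < 1L || ms[length(ms)] > length(signal$samples)) {
    stop_format("midswing_indices must be strictly increasing and in range")
  }
  lapply(seq_len(length(ms) - 1L), function(k) {
    v <- signal$samples[ms[k]:(ms[k + 1L] - 1L)]
    attr(v, "span") <- c(start = ms[k], end = ms[k + 1L])
    v
  })
}

#' Time-normalize a raw gait cycle to a fixed number of points
#'
#' Subjects walk at different speeds, so raw cycles differ in length; the
#' network input is a cycle resampled to `n_points` (default 100) values by
#' linear interpolation. The interpolation grid covers the cycle's
#' half-open span: point `j` sits at `(j-1) * L / n_points` in sample units
#' for a cycle of `L` samples, so the first output point equals the
#' cycle's first sample and the grid never reaches the following cycle's
#' mid-swing. For cycles shorter than `n_points` the last grid points can
#' pass the final sample; they clamp to it. Only time is normalized —
#' amplitudes are left untouched, since peak magnitude carries diagnostic
#' information.
#'
#' @param raw_cycle numeric vector of at least 2 samples (as produced by
#'   [split_cycles()]).
#' @param n_points output length (default 100).
#' @return numeric vector of length `n_points`, carrying through any
#'   `span` attribute of the input.
#' @export
normalize_cycle <- function(raw_cycle, n_points = 100) {
  x <- as.numeric(raw_cycle)
  L <- length(x)
  if (L < 2L) {
    stop_format("cannot normalize a degenerate cycle of %d sample(s)", L)
  }
  grid <- (seq_len(n_points) - 1) * L / n_points
  out <- stats::approx(x = seq_len(L) - 1, y = x, xout = pmin(grid, L - 1),
                       method = "linear", rule = 2)$y
  if (!is.null(attr(raw_cycle, "span"))) {
    attr(out, "span") <- attr(raw_cycle, "span")
  }
  out
}

#' Segment a continuous signal into normalized gait cycles
#'
#' Convenience wrapper: [detect_midswing()] then [split_cycles()] then
#' [normalize_cycle()] on every cycle.
#'
#' @inheritParams detect_midswing
#' @param n_points points per normalized cycle.
#' @return list with `cycles` (matrix, one 100-point row per gait cycle),
#'   `spans` (two-column matrix of half-open source intervals),
#'   `midswing_indices`, and the signal's `subject_id` and `leg`.
#' @export
segment_signal <- function(signal, min_peak = 50, min_separation = 0.4,
                           lowpass_hz = NULL, n_points = 100) {
  ms <- detect_midswing(signal, min_peak = min_peak,
                        min_separation = min_separation,
                        lowpass_hz = lowpass_hz)
  raw <- split_cycles(signal, ms)
  cycles <- do.call(rbind, lapply(raw, normalize_cycle, n_points = n_points))
  if (is.null(cycles)) cycles <- matrix(numeric(0), 0, n_points)
  spans <- do.call(rbind, lapply(raw, attr, "span"))
  if (is.null(spans)) spans <- matrix(integer(0), 0, 2,
                                      dimnames = list(NULL, c("start", "end")))
  list(cycles = cycles, spans = spans, midswing_indices = ms,
       subject_id = signal$subject_id, leg = signal$leg)
}
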