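#' Angular-velocity signal for one leg
#'
#' Container for a uniformly sampled sagittal-plane (mediolateral-axis)
#' shank angular-velocity trace, the only channel the recognition pipeline
#' consumes. Values are in degrees per second; the default sampling rate of
#' 128 Hz matches research-grade wearable IMUs.
#'
#' @param samples numeric vector of angular velocities (deg/s), length >= 2,
#'   all finite.
#' @param sample_rate sampling rate in Hz, > 0.
#' @param leg `"left"` or `"right"`.
#' @param subject_id subject identifier string.
#' @return an object of class `angvel_signal`: a list with fields
#'   `samples`, `sample_rate`, `leg`, `subject_id`.
#' @examples
#' sig <- angvel_signal(sin(seq(0, 10, by = 1 / 128)) * 100)
#' print(sig)
#' @export
angvel_signal <- function(samples, sample_rate = 128,
                          leg = c("left", "right"), subject_id = "S1") {
  leg <- match.arg(leg)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop_format("an angular-velocity signal needs at least 2 samples, got %d",
                length(samples))
  }
  if (!all(is.finite(samples))) {
    stop_format("angular-velocity samples must all be finite")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop_format("sample_rate must be a single positive number")
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         leg = leg, subject_id = as.character(subject_id)),
    class = "angvel_signal"
  )
}

#' @export
print.angvel_signal <- function(x, ...) {
  cat(sprintf(
    "<angvel_signal> subject %s, %s leg: %d samples @ %g Hz (%.2f s)\n",
    x$subject_id, x$leg, length(x$samples), x$sample_rate,
    length(x$samples) / x$sample_rate))
  cat(sprintf("  range [%.1f, %.1f] deg/s\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.angvel_signal <- function(x) length(x$samples)

is_angvel_signal <- function(x) inherits(x, "angvel_signal")

assert_signal <- function(x) {
  if (!is_angvel_signal(x)) {
    stop_format("expected an `angvel_signal` object; see angvel_signal()")
  }
  invisible(x)
}
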