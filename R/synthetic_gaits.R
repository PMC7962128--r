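#' Template for one gait cycle of shank angular velocity
#'
#' Piecewise-smooth waveform realizing the three canonical gait events of
#' the shank's sagittal angular velocity: a tall positive mid-swing peak,
#' a negative heel-strike trough immediately after it, a slightly negative
#' stance plateau, and a negative pre-swing trough before the next peak.
#' The waveform is a baseline plateau plus three Gaussian bumps placed at
#' phase fractions of the cycle; amplitudes are parameterized by the target
#' extreme values so `midswing_peak` and the troughs are (approximately)
#' the realized extremes.
#'
#' @param cycle_duration nominal stride period in seconds.
#' @param midswing_peak mid-swing peak angular velocity, deg/s, > 0.
#' @param heelstrike_trough heel-strike trough value, deg/s, < 0.
#' @param stance_plateau stance-phase baseline, deg/s (typically slightly
#'   negative).
#' @param preswing_trough pre-swing trough value, deg/s.
#' @param peak_phase,peak_width phase location and Gaussian width (cycle
#'   fractions) of the mid-swing peak.
#' @param heelstrike_phase,heelstrike_width location/width of the
#'   heel-strike trough.
#' @param preswing_phase,preswing_width location/width of the pre-swing
#'   trough.
#' @return an object of class `gait_template`.
#' @export
gait_template <- function(cycle_duration = 1.0, midswing_peak = 250,
                          heelstrike_trough = -100, stance_plateau = -20,
                          preswing_trough = -80,
                          peak_phase = 0.15, peak_width = 0.05,
                          heelstrike_phase = 0.30, heelstrike_width = 0.04,
                          preswing_phase = 0.88, preswing_width = 0.05) {
  if (!is.finite(midswing_peak) || midswing_peak <= 0) {
    stop_format("midswing_peak must be positive, got %g", midswing_peak)
  }
  if (!is.finite(heelstrike_trough) || heelstrike_trough >= 0) {
    stop_format("heelstrike_trough must be negative, got %g",
                heelstrike_trough)
  }
  if (!is.finite(cycle_duration) || cycle_duration <= 0) {
    stop_format("cycle_duration must be positive, got %g", cycle_duration)
  }
  structure(as.list(environment()), class = "gait_template")
}

#' Abnormality profile for a synthetic leg
#'
#' Encodes which gait abnormalities a leg expresses and how strongly. Each
#' flag applies a deterministic, independently learnable perturbation to
#' the cycle template:
#' \describe{
#'   \item{drop foot}{mid-swing peak attenuated by `df_attenuation`
#'     (weakened dorsiflexion lowers swing velocity).}
#'   \item{circumduction}{swing peak broadened by `c_broadening`
#'     (the semicircular swing prolongs the high-velocity phase).}
#'   \item{hip hiking}{secondary mid-stance bump of `hh_bump` deg/s
#'     (pelvic elevation perturbs the stance trace).}
#'   \item{back knee}{late-stance reversal bump of `bk_reversal` deg/s
#'     (knee hyperextension reverses shank rotation before pre-swing).}
#' }
#' These encodings are engineered fixtures with plausible signs and
#' magnitudes, not claims about stroke physiology. Stroke gait in general
#' (with or without any abnormality flag) additionally carries tremor —
#' band-limited (roughly sub-15 Hz) oscillation of standard deviation
#' `tremor_sd` emulating the trembling and vibration seen on paretic-side
#' angular-velocity traces; a profile with all flags off and
#' `tremor_sd = 0` is a healthy gait.
#'
#' @param drop_foot,circumduction,hip_hiking,back_knee logical flags.
#' @param tremor_sd standard deviation (deg/s) of the band-limited tremor
#'   added sample-wise; 0 for healthy legs.
#' @param stroke whether the leg is a stroke (paretic or non-paretic) leg;
#'   defaults to `TRUE` whenever any flag is set or `tremor_sd > 0`.
#' @param df_attenuation fractional mid-swing peak attenuation under drop
#'   foot (default 0.5, a severe drop foot).
#' @param c_broadening fractional swing-peak broadening under
#'   circumduction (default 0.6).
#' @param hh_bump mid-stance bump amplitude in deg/s (default 45).
#' @param bk_reversal late-stance reversal amplitude in deg/s (default 40).
#' @return an object of class `abnormality_profile`.
#' @export
abnormality_profile <- function(drop_foot = FALSE, circumduction = FALSE,
                                hip_hiking = FALSE, back_knee = FALSE,
                                tremor_sd = 0,
                                stroke = NULL,
                                df_attenuation = 0.5, c_broadening = 0.6,
                                hh_bump = 45, bk_reversal = 40) {
  flags <- c(drop_foot, circumduction, hip_hiking, back_knee)
  stopifnot(is.logical(flags), length(flags) == 4L, !anyNA(flags))
  if (tremor_sd < 0 || df_attenuation < 0 || c_broadening < 0 ||
      hh_bump < 0 || bk_reversal < 0) {
    stop_format("effect sizes and tremor_sd must be non-negative")
  }
  stroke <- stroke %||% (any(flags) || tremor_sd > 0)
  if (any(flags) && !stroke) {
    stop_format("a leg with abnormality flags must be a stroke leg")
  }
  structure(
    list(drop_foot = drop_foot, circumduction = circumduction,
         hip_hiking = hip_hiking, back_knee = back_knee,
         tremor_sd = tremor_sd, stroke = stroke,
         df_attenuation = df_attenuation, c_broadening = c_broadening,
         hh_bump = hh_bump, bk_reversal = bk_reversal),
    class = "abnormality_profile"
  )
}

# Uniformly rescale a template's amplitudes (between-subject vigor).
.scale_template <- function(template, s) {
  for (f in c("midswing_peak", "heelstrike_trough", "stance_plateau",
              "preswing_trough")) {
    template[[f]] <- template[[f]] * s
  }
  template
}

# Band-limited tremor noise: white Gaussian noise convolved with a
# Gaussian kernel (s.d. `bandwidth_samples`), normalized so the output
# standard deviation equals `sd`. At 128 Hz the default 2-sample kernel
# concentrates energy below ~10-15 Hz, the band of pathological shank
# oscillation, rather than spreading it to the Nyquist frequency as white
# noise would.
.tremor_noise <- function(n, sd, bandwidth_samples = 2) {
  half <- 3L * ceiling(bandwidth_samples)
  k <- stats::dnorm(seq(-half, half), sd = bandwidth_samples)
  k <- k / sqrt(sum(k^2))
  w <- stats::rnorm(n + 2L * half)
  as.numeric(stats::filter(w, k, sides = 2))[(half + 1L):(half + n)] * sd
}

# Evaluate one noiseless cycle of the (possibly perturbed) template on a
# phase grid u in [0, 1). `amp_scale` models walking vigor and scales the
# whole waveform uniformly, so flag perturbations that reshape the cycle
# (e.g. the drop-foot peak attenuation, which lowers the peak-to-trough
# ratio) stay distinguishable from ordinary amplitude variation.
.template_cycle <- function(template, profile, n_samples, amp_scale = 1) {
  u <- (seq_len(n_samples) - 1) / n_samples
  g <- function(mu, s) exp(-(u - mu)^2 / (2 * s^2))
  peak_amp <- template$midswing_peak - template$stance_plateau
  peak_width <- template$peak_width
  if (profile$drop_foot) peak_amp <- peak_amp * (1 - profile$df_attenuation)
  if (profile$circumduction) peak_width <- peak_width * (1 + profile$c_broadening)
  w <- template$stance_plateau +
    peak_amp * g(template$peak_phase, peak_width) +
    (template$heelstrike_trough - template$stance_plateau) *
      g(template$heelstrike_phase, template$heelstrike_width) +
    (template$preswing_trough - template$stance_plateau) *
      g(template$preswing_phase, template$preswing_width)
  if (profile$hip_hiking) w <- w + profile$hh_bump * g(0.45, 0.06)
  if (profile$back_knee) w <- w + profile$bk_reversal * g(0.80, 0.05)
  w * amp_scale
}

#' Synthesize one leg's angular-velocity stream with known ground truth
#'
#' Concatenates `n_gaits` template cycles with per-cycle duration jitter
#' and amplitude jitter, applies the profile's deterministic abnormality
#' perturbations, records the exact mid-swing sample of every cycle on the
#' noiseless waveform, and finally adds seeded tremor noise
#' (`profile$tremor_sd`). With `tremor_sd = 0` the recorded indices are the
#' exact per-cycle argmax samples of the emitted stream.
#'
#' @param template a [gait_template()].
#' @param profile an [abnormality_profile()].
#' @param n_gaits number of cycles, >= 1.
#' @param seed RNG seed; identical inputs give a bit-identical stream.
#' @param sample_rate Hz.
#' @param duration_jitter_sd relative s.d. of per-cycle duration (default
#'   5%).
#' @param amp_jitter_sd relative s.d. of per-cycle peak amplitude.
#' @param leg,subject_id metadata for the emitted signal.
#' @return list with `signal` ([angvel_signal]), `midswing_indices`
#'   (planted ground-truth event samples, one per cycle), and `label`
#'   (a [gait_label()] implied by the profile).
#' @export
synthesize_leg <- function(template, profile, n_gaits, seed = 1,
                           sample_rate = 128, duration_jitter_sd = 0.05,
                           amp_jitter_sd = 0.05,
                           leg = "left", subject_id = "SYN") {
  stopifnot(inherits(template, "gait_template"),
            inherits(profile, "abnormality_profile"))
  if (n_gaits < 1L) stop_format("n_gaits must be >= 1, got %g", n_gaits)
  local_seed(seed, {
    durations <- template$cycle_duration *
      pmax(0.5, 1 + stats::rnorm(n_gaits, 0, duration_jitter_sd))
    amps <- pmax(0.2, 1 + stats::rnorm(n_gaits, 0, amp_jitter_sd))
    lengths <- pmax(16L, as.integer(round(durations * sample_rate)))
    pieces <- vector("list", n_gaits)
    midswing <- integer(n_gaits)
    offset <- 0L
    for (k in seq_len(n_gaits)) {
      w <- .template_cycle(template, profile, lengths[k], amps[k])
      midswing[k] <- offset + which.max(w)
      pieces[[k]] <- w
      offset <- offset + lengths[k]
    }
    x <- unlist(pieces, use.names = FALSE)
    if (profile$tremor_sd > 0) {
      x <- x + .tremor_noise(length(x), profile$tremor_sd)
    }
    list(
      signal = angvel_signal(x, sample_rate = sample_rate, leg = leg,
                             subject_id = subject_id),
      midswing_indices = midswing,
      label = gait_label(ng = !profile$stroke, sg = profile$stroke,
                         sgw_df = profile$drop_foot,
                         sgw_c = profile$circumduction,
                         sgw_hh = profile$hip_hiking,
                         sgw_bk = profile$back_knee)
    )
  })
}

#' Configuration for a synthetic labelled gait cohort
#'
#' `legs` is a data.frame with one row per instrumented leg: columns
#' `subject`, `leg` (`"left"`/`"right"`), `n_gaits`, `stroke`, and the four
#' abnormality flags `sgw_df`, `sgw_c`, `sgw_hh`, `sgw_bk` (logical or
#' 0/1). The default layout mirrors the published clinical cohort: eight
#' stroke subjects with per-leg abnormality combinations (including one leg
#' carrying all four abnormalities and legs carrying a single one,
#' totalling 2037 stroke gaits) and seven healthy subjects contributing
#' 1000 normal gaits per side (2000 total).
#'
#' @param legs per-leg layout data.frame (default: the clinical-shaped
#'   cohort described above).
#' @param seed master seed; fixes every downstream draw.
#' @param sample_rate Hz.
#' @param tremor_sd tremor noise s.d. applied to stroke legs (deg/s).
#' @param duration_jitter_sd relative per-cycle duration jitter s.d.
#' @param subject_scale_sd relative s.d. of a per-leg overall amplitude
#'   scale emulating between-subject variation.
#' @param template base [gait_template()] shared by all legs.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(legs = default_cohort_legs(), seed = 0,
                          sample_rate = 128, tremor_sd = 15,
                          duration_jitter_sd = 0.05,
                          subject_scale_sd = 0.08,
                          template = gait_template()) {
  need <- c("subject", "leg", "n_gaits", "stroke",
            "sgw_df", "sgw_c", "sgw_hh", "sgw_bk")
  missing_cols <- setdiff(need, names(legs))
  if (length(missing_cols)) {
    stop_format("legs is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (any(legs$n_gaits <= 0)) stop_format("all n_gaits must be positive")
  structure(
    list(legs = legs, seed = seed, sample_rate = sample_rate,
         tremor_sd = tremor_sd, duration_jitter_sd = duration_jitter_sd,
         subject_scale_sd = subject_scale_sd, template = template),
    class = "cohort_config"
  )
}

#' Default per-leg layout mirroring the clinical cohort
#'
#' @return data.frame accepted by [cohort_config()]; stroke gaits total
#'   2037 and normal gaits 2000.
#' @export
default_cohort_legs <- function() {
  s <- function(subject, leg, n, df = 0, c = 0, hh = 0, bk = 0) {
    data.frame(subject = subject, leg = leg, n_gaits = n, stroke = TRUE,
               sgw_df = df == 1, sgw_c = c == 1, sgw_hh = hh == 1,
               sgw_bk = bk == 1)
  }
  stroke <- rbind(
    s("P1", "left", 50),
    s("P1", "right", 39, hh = 1, bk = 1),
    s("P2", "left", 68),
    s("P2", "right", 52, df = 1, hh = 1),
    s("P3", "left", 92),
    s("P3", "right", 76, c = 1),
    s("P4", "left", 187, c = 1, hh = 1, bk = 1),
    s("P4", "right", 190),
    s("P5", "left", 169),
    s("P5", "right", 158, df = 1, c = 1, hh = 1, bk = 1),
    s("P6", "left", 158, df = 1, bk = 1),
    s("P6", "right", 171),
    s("P7", "left", 139, hh = 1),
    s("P7", "right", 158),
    s("P8", "left", 155),
    s("P8", "right", 175, df = 1, hh = 1)
  )
  # 1000 healthy gaits per side, split across the seven healthy subjects
  per_subject <- c(143, 143, 143, 143, 143, 143, 142)
  healthy <- do.call(rbind, lapply(seq_len(7), function(i) {
    data.frame(subject = sprintf("H%d", i), leg = c("left", "right"),
               n_gaits = per_subject[i], stroke = FALSE,
               sgw_df = FALSE, sgw_c = FALSE, sgw_hh = FALSE,
               sgw_bk = FALSE)
  }))
  rbind(stroke, healthy)
}

#' Synthesize a labelled cohort of normalized gait cycles
#'
#' For every leg in the configuration, generates a continuous
#' angular-velocity stream with `n_gaits + 1` planted mid-swing events,
#' splits it mid-swing to mid-swing with the segmentation module (using the
#' planted ground-truth events, so each leg yields exactly `n_gaits`
#' cycles), and time-normalizes each cycle to 100 points. Per-leg seeds are
#' derived from the master seed, so the whole cohort is bit-reproducible.
#'
#' @param config a [cohort_config()].
#' @param n_points points per normalized cycle.
#' @return a [gait_dataset]: normalized cycles plus per-cycle multi-label
#'   ground truth.
#' @export
synthesize_cohort <- function(config, n_points = 100) {
  stopifnot(inherits(config, "cohort_config"))
  legs <- config$legs
  n_legs <- nrow(legs)
  derived <- local_seed(config$seed, {
    list(sub_seeds = sample.int(.Machine$integer.max - 1L, n_legs),
         scales = pmax(0.5, 1 + stats::rnorm(n_legs, 0,
                                             config$subject_scale_sd)))
  })
  cycle_rows <- vector("list", n_legs)
  label_rows <- vector("list", n_legs)
  for (i in seq_len(n_legs)) {
    row <- legs[i, ]
    tpl <- config$template
    tpl <- .scale_template(tpl, derived$scales[i])
    profile <- abnormality_profile(
      drop_foot = as.logical(row$sgw_df),
      circumduction = as.logical(row$sgw_c),
      hip_hiking = as.logical(row$sgw_hh),
      back_knee = as.logical(row$sgw_bk),
      tremor_sd = if (row$stroke) config$tremor_sd else 0,
      stroke = as.logical(row$stroke)
    )
    syn <- synthesize_leg(
      tpl, profile, n_gaits = row$n_gaits + 1L, seed = derived$sub_seeds[i],
      sample_rate = config$sample_rate,
      duration_jitter_sd = config$duration_jitter_sd,
      leg = row$leg, subject_id = row$subject
    )
    raw <- split_cycles(syn$signal, syn$midswing_indices)
    stopifnot(length(raw) == row$n_gaits)
    cycle_rows[[i]] <- do.call(
      rbind, lapply(raw, normalize_cycle, n_points = n_points))
    lab <- syn$label
    label_rows[[i]] <- data.frame(
      subject = row$subject, leg = row$leg,
      cycle_index = seq_len(row$n_gaits),
      ng = as.integer(lab$ng), sg = as.integer(lab$sg),
      sgw_df = as.integer(lab$sgw_df), sgw_c = as.integer(lab$sgw_c),
      sgw_hh = as.integer(lab$sgw_hh), sgw_bk = as.integer(lab$sgw_bk)
    )
  }
  gait_dataset(do.call(rbind, cycle_rows), do.call(rbind, label_rows))
}
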