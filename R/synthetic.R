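# Synthetic ambulatory ECG generator.  Waveform anatomy (P wave, QRS, T
# wave) is schematic; what matters to the pipeline is that (a) the PQ
# interval is an exactly flat true isoelectric segment, (b) the ST window
# [F+40, F+160] ms carries an analytically exact parametric shape
# (level + slope + quadratic scoop), and (c) T-wave encroachment can push
# the T upstroke into the ST window without any true ST deviation.

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Beat template parameters
#'
#' ST morphology of a single synthetic beat.  Over the ST window the shape
#' is, with tau ms after F and x = (tau - 100) / 60 in \[-1, 1\]:
#' `st_level + st_slope * (tau - 100) / 100 + st_scoop * q(x)`, where q is
#' the discrete-orthogonal quadratic (the shape LPT coefficient 3 measures,
#' scaled to peak deflection 1 at the window edges) — the three leading
#' discrete Legendre shapes, so level, slope and scoop map one-to-one onto
#' LPT coefficients 1-3.
#'
#' @param st_level ST level in uV (|value| <= 500).
#' @param st_slope ST slope in uV per 100 ms.
#' @param st_scoop peak quadratic (scooping) deflection in uV.
#' @param t_onset_shift shift of the T wave in ms; negative values move the
#'   T wave toward the QRS (heart-rate-related encroachment).
#' @param qrs_amplitude R-wave amplitude in uV.
#' @return object of class `beat_params`.
#' @export
beat_params <- function(st_level = 0, st_slope = 0, st_scoop = 0,
                        t_onset_shift = 0, qrs_amplitude = 1000) {
  if (abs(st_level) > 500 || abs(st_slope) > 500 || abs(st_scoop) > 500)
    stop("ST parameters out of physiological range (|x| <= 500 uV)")
  if (t_onset_shift < -120 || t_onset_shift > 60)
    stop("t_onset_shift out of range [-120, 60] ms")
  structure(list(st_level = st_level, st_slope = st_slope,
                 st_scoop = st_scoop, t_onset_shift = t_onset_shift,
                 qrs_amplitude = qrs_amplitude),
            class = "beat_params")
}

# piecewise-linear QRS: Q dip, R spike at F, S dip, J point at F + 30 ms
qrs_shape <- function(tau, amp, abnormal = FALSE) {
  pts_t <- c(-20, -15, 0, 12, 30)
  pts_v <- c(0, -0.08, 1, -0.15, 0) * amp
  if (abnormal) {                      # wide, tall ectopic-like complex
    pts_t <- c(-30, -20, 0, 18, 44)
    pts_v <- c(0, -0.05, 1.6, -0.4, 0) * amp
  }
  out <- numeric(length(tau))
  inside <- tau >= pts_t[1] & tau <= pts_t[length(pts_t)]
  if (any(inside))
    out[inside] <- stats::approx(pts_t, pts_v, xout = tau[inside])$y
  out
}

# Discrete-orthogonal quadratic scoop shape: on the M-point window grid it
# is exactly orthogonal to the constant and linear basis functions
# (c_M = 2/(M-1) corrects the quadrature of the continuous P2), and it is
# scaled to reach the peak deflection 1 at the window edges x = +-1.  This
# is precisely the shape that LPT coefficient 3 measures.
scoop_shape <- function(x, M = 32L) {
  c_m <- 2 / (M - 1)
  (3 * x^2 - 1 - c_m) / (2 - c_m)
}

# Parametric ST shape: exact over the analysis window [40, 160] ms after F,
# held at its F+160 value out to 230 ms (ischaemic deviation persists into
# the ST-T region; a hard return to baseline just past the measurement
# point would be unphysiological and lets the low-pass filter bleed the
# post-ST baseline into the measurement), then tapered to zero by the
# T-wave peak.
st_component <- function(tau, p) {
  tc <- pmin(tau, 160)
  x <- (tc - 100) / 60
  val <- p$st_level + p$st_slope * (tc - 100) / 100 +
    p$st_scoop * scoop_shape(x)
  w <- rep(0, length(tau))
  w[tau >= 40 & tau <= 230] <- 1
  ramp_in <- tau >= 30 & tau < 40
  w[ramp_in] <- (tau[ramp_in] - 30) / 10
  ramp_out <- tau > 230 & tau <= 260
  w[ramp_out] <- (260 - tau[ramp_out]) / 30
  val * w
}

# full beat waveform at offsets tau (ms relative to F)
beat_waveform <- function(tau, p, abnormal = FALSE) {
  v <- qrs_shape(tau, p$qrs_amplitude, abnormal)
  if (!abnormal)
    v <- v + 100 * exp(-((tau + 200) / 15)^2 / 2)            # P wave
  t_center <- 260 + p$t_onset_shift
  t_amp <- if (abnormal) -250 else 300
  v + t_amp * exp(-((tau - t_center) / 30)^2 / 2) +          # T wave
    st_component(tau, p)
}

#' Generate a single synthetic beat
#'
#' @param params a [beat_params()].
#' @param fs sampling frequency in Hz.
#' @param pre_ms,post_ms waveform support before/after the fiducial point.
#' @return list with `samples` (uV), `fiducial` (sample index of F) and
#'   `fs`.
#' @export
make_beat <- function(params, fs = 250, pre_ms = 300, post_ms = 360) {
  n_pre <- round(pre_ms * fs / 1000)
  n_post <- round(post_ms * fs / 1000)
  tau <- (seq(-n_pre, n_post)) * 1000 / fs
  list(samples = beat_waveform(tau, params), fiducial = n_pre + 1L, fs = fs)
}

#' Transient ST episode specification
#'
#' An episode imposes a triangular temporal profile (0 at onset, 1 at the
#' extremum, back to 0 at offset) on its ST parameters.  Ischaemic episodes
#' carry true ST deviation (level beyond +-50 uV, optionally slope and
#' scooping) and may or may not modulate heart rate; heart-rate-related
#' episodes carry no true ST deviation — their apparent ST change comes
#' from rate-driven T-wave encroachment into the ST window.
#'
#' @param class `"ischaemic"` or `"heart_rate_related"`.
#' @param onset_s,extremum_s,offset_s episode timing in seconds
#'   (onset < extremum < offset).
#' @param magnitude_uv ST level at the extremum (uV); ischaemic episodes
#'   must exceed 50 uV in magnitude, heart-rate-related must be 0.
#' @param slope_uv,scoop_uv slope / scoop at the extremum (uV), ischaemic
#'   only.
#' @param hr_delta_bpm heart-rate increase at the extremum; must be > 0 for
#'   heart-rate-related episodes.
#' @param t_shift_ms T-wave shift at the extremum (ms, negative =
#'   encroachment); defaults to `-min(70, 1.8 * hr_delta_bpm)` for
#'   heart-rate-related episodes and 0 otherwise.
#' @param leads affected lead indices.
#' @return object of class `episode_spec`.
#' @export
episode_spec <- function(class = c("ischaemic", "heart_rate_related"),
                         onset_s, extremum_s, offset_s, magnitude_uv = 0,
                         slope_uv = 0, scoop_uv = 0, hr_delta_bpm = 0,
                         t_shift_ms = NULL, leads = 1L) {
  class <- match.arg(class)
  if (!(onset_s < extremum_s && extremum_s < offset_s))
    stop("episode requires onset < extremum < offset")
  if (class == "ischaemic" && abs(magnitude_uv) <= 50)
    stop("ischaemic episodes must deviate by more than 50 uV")
  if (class == "heart_rate_related") {
    if (hr_delta_bpm <= 0)
      stop("heart-rate-related episodes need hr_delta_bpm > 0")
    if (magnitude_uv != 0 || slope_uv != 0 || scoop_uv != 0)
      stop("heart-rate-related episodes carry no true ST deviation")
  }
  if (is.null(t_shift_ms))
    t_shift_ms <- if (class == "heart_rate_related")
      -min(70, 1.8 * hr_delta_bpm) else 0
  structure(list(class = class, onset_s = onset_s, extremum_s = extremum_s,
                 offset_s = offset_s, magnitude_uv = magnitude_uv,
                 slope_uv = slope_uv, scoop_uv = scoop_uv,
                 hr_delta_bpm = hr_delta_bpm, t_shift_ms = t_shift_ms,
                 leads = as.integer(leads)),
            class = "episode_spec")
}

# triangular episode weight at time t (s)
episode_weight <- function(ep, t) {
  ifelse(t <= ep$onset_s | t >= ep$offset_s, 0,
         ifelse(t <= ep$extremum_s,
                (t - ep$onset_s) / (ep$extremum_s - ep$onset_s),
                (ep$offset_s - t) / (ep$offset_s - ep$extremum_s)))
}

#' Synthetic record configuration
#'
#' @param duration_s record length in seconds.
#' @param fs sampling frequency (Hz).
#' @param leads number of leads.
#' @param base_hr resting heart rate (bpm).
#' @param episodes list of [episode_spec()] objects.
#' @param axis_shifts list of `list(time_s =, offsets_uv =)` step changes of
#'   the per-lead ST offset (postural axis shifts).
#' @param noise_rms high-frequency Gaussian noise RMS (uV).
#' @param baseline_wander `c(amplitude_uv, frequency_hz)` sinusoidal wander.
#' @param abnormal_beat_rate probability that a beat is ectopic.
#' @param seed integer; fully determines the generated record.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 60, fs = 250, leads = 2L,
                         base_hr = 70, episodes = list(),
                         axis_shifts = list(), noise_rms = 0,
                         baseline_wander = c(0, 0.3),
                         abnormal_beat_rate = 0, seed = 1L) {
  for (ep in episodes) for (ep2 in episodes) {
    if (!identical(ep, ep2) && length(intersect(ep$leads, ep2$leads)) &&
        ep$onset_s < ep2$offset_s && ep2$onset_s < ep$offset_s)
      stop("overlapping episodes on the same lead")
  }
  structure(list(duration_s = duration_s, fs = fs, leads = as.integer(leads),
                 base_hr = base_hr, episodes = episodes,
                 axis_shifts = axis_shifts, noise_rms = noise_rms,
                 baseline_wander = baseline_wander,
                 abnormal_beat_rate = abnormal_beat_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic annotated ambulatory ECG record
#'
#' Builds a beat train whose rate follows the configured base rate plus the
#' episodes' triangular heart-rate trajectories; each beat's ST parameters
#' follow the episodes' triangular ST trajectories and step axis shifts;
#' sinusoidal baseline wander, white measurement noise and labeled ectopic
#' beats are superimposed.  The same seed reproduces the record exactly.
#'
#' @param config a [synth_config()].
#' @return list with `record` (an [ecg_record()]), `truth` (per-beat
#'   injected ground-truth parameters) and `episodes` (the configured
#'   episode list).
#' @export
make_record <- function(config) {
  with_seed(config$seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    hr_at <- function(t) {
      h <- config$base_hr
      for (ep in config$episodes)
        h <- h + ep$hr_delta_bpm * episode_weight(ep, t)
      h
    }
    # beat train: next fiducial from the instantaneous rate at current time
    fidu_ms <- c()
    t <- 500
    while (t < config$duration_s * 1000 - 400) {
      fidu_ms <- c(fidu_ms, t)
      t <- t + 60000 / hr_at(t / 1000)
    }
    nb <- length(fidu_ms)
    abnormal <- stats::runif(nb) < config$abnormal_beat_rate
    sig <- matrix(0, n, config$leads)
    truth <- data.frame(beat = seq_len(nb), time_s = fidu_ms / 1000,
                        hr = hr_at(fidu_ms / 1000),
                        label = ifelse(abnormal, "abnormal", "normal"))
    st_truth <- array(0, c(nb, config$leads, 4),
                      dimnames = list(NULL, NULL,
                                      c("level", "slope", "scoop", "tshift")))
    for (j in seq_len(nb)) {
      tj <- fidu_ms[j] / 1000
      for (l in seq_len(config$leads)) {
        p <- c(level = 0, slope = 0, scoop = 0, tshift = 0)
        for (ep in config$episodes) {
          if (!(l %in% ep$leads)) next
          w <- episode_weight(ep, tj)
          p["level"] <- p["level"] + w * ep$magnitude_uv
          p["slope"] <- p["slope"] + w * ep$slope_uv
          p["scoop"] <- p["scoop"] + w * ep$scoop_uv
          p["tshift"] <- p["tshift"] + w * ep$t_shift_ms
        }
        for (ax in config$axis_shifts)
          if (tj >= ax$time_s) p["level"] <- p["level"] + ax$offsets_uv[l]
        st_truth[j, l, ] <- p
        bp <- beat_params(st_level = p["level"], st_slope = p["slope"],
                          st_scoop = p["scoop"], t_onset_shift = p["tshift"])
        fidu_idx <- round(fidu_ms[j] * fs / 1000)
        n_pre <- round(300 * fs / 1000)
        n_post <- round(360 * fs / 1000)
        lo <- max(1L, fidu_idx - n_pre)
        hi <- min(n, fidu_idx + n_post)
        tau <- (seq(lo, hi) - fidu_idx) * 1000 / fs
        sig[lo:hi, l] <- sig[lo:hi, l] +
          beat_waveform(tau, bp, abnormal = abnormal[j])
      }
    }
    tt <- seq_len(n) / fs
    for (l in seq_len(config$leads)) {
      if (config$baseline_wander[1] > 0)
        sig[, l] <- sig[, l] + config$baseline_wander[1] *
          sin(2 * pi * config$baseline_wander[2] * tt + (l - 1) * pi / 3)
      if (config$noise_rms > 0)
        sig[, l] <- sig[, l] + stats::rnorm(n, 0, config$noise_rms)
    }
    beats <- data.frame(fiducial = round(fidu_ms * fs / 1000),
                        label = truth$label)
    truth$st_level <- st_truth[, 1, "level"]
    truth$st_slope <- st_truth[, 1, "slope"]
    truth$st_scoop <- st_truth[, 1, "scoop"]
    truth$t_shift <- st_truth[, 1, "tshift"]
    list(record = ecg_record(sig, fs, beats), truth = truth,
         st_truth = st_truth, episodes = config$episodes)
  })
}

# T-wave encroachment contribution inside the ST window, used when corpus
# patterns are drawn directly (without synthesizing whole records)
encroachment_pattern <- function(t_shift_ms, window = st_window_spec()) {
  tau <- seq(window$start_offset_ms, window$end_offset_ms,
             length.out = window$n_samples)
  300 * exp(-((tau - (260 + t_shift_ms)) / 30)^2 / 2)
}

#' Generate a labeled training corpus of ST pattern-vector intervals
#'
#' Draws annotated intervals with class-conditional ST morphology, sampling
#' pattern vectors directly on the ST window grid (the analytic shape the
#' record generator injects), plus per-beat parameter jitter and white
#' measurement noise.  Defaults: no-deviation intervals have level/slope/
#' scoop ~ N(0, 15/15/6 uV); ischaemic intervals draw a level of 60-250 uV
#' magnitude (negative with probability 0.75), slope ~ N(0, 60), scoop up to
#' 50 uV; heart-rate-related intervals have no true deviation but a T-wave
#' encroachment of 30-70 ms.  These defaults yield descending
#' per-coefficient standard deviations, matching the ordering observed on
#' real ambulatory corpora.
#'
#' @param n_ischaemic,n_non_ischaemic,n_no_deviation interval counts.
#' @param beats_per_interval pattern vectors per interval.
#' @param noise_rms per-sample measurement noise (uV).
#' @param effect_scale multiplies every drawn interval-level ST parameter
#'   (0 gives a zero-variance corpus of all-zero patterns when noise and
#'   jitter are also 0).
#' @param jitter_scale multiplies the per-beat parameter jitter.
#' @param seed RNG seed.
#' @param window ST window specification.
#' @return list of intervals, each `list(patterns, label)`, suitable for
#'   [build_classes()] / [train_klt()].
#' @export
make_training_corpus <- function(n_ischaemic = 40, n_non_ischaemic = 20,
                                 n_no_deviation = 60,
                                 beats_per_interval = 30, noise_rms = 10,
                                 effect_scale = 1, jitter_scale = 1,
                                 seed = 1L, window = st_window_spec()) {
  with_seed(seed, {
    tau <- seq(window$start_offset_ms, window$end_offset_ms,
               length.out = window$n_samples)
    x <- (tau - 100) / 60
    shape <- function(level, slope, scoop, tshift = NULL) {
      v <- level + slope * (tau - 100) / 100 + scoop * scoop_shape(x)
      if (!is.null(tshift)) v <- v + encroachment_pattern(tshift, window)
      v
    }
    draw_interval <- function(label) {
      if (label == "ischaemic_deviation") {
        lev <- sample(c(-1, 1), 1, prob = c(0.75, 0.25)) *
          stats::runif(1, 60, 250)
        slo <- stats::rnorm(1, 0, 60)
        sco <- sample(c(-1, 1), 1) * stats::runif(1, 0, 50)
        tsh <- NULL
      } else if (label == "non_ischaemic_deviation") {
        lev <- stats::rnorm(1, 0, 15); slo <- stats::rnorm(1, 0, 15)
        sco <- stats::rnorm(1, 0, 6)
        tsh <- -stats::runif(1, 30, 70)
      } else {
        lev <- stats::rnorm(1, 0, 15); slo <- stats::rnorm(1, 0, 15)
        sco <- stats::rnorm(1, 0, 6)
        tsh <- NULL
      }
      lev <- lev * effect_scale; slo <- slo * effect_scale
      sco <- sco * effect_scale
      if (effect_scale == 0) tsh <- NULL   # no residual T-wave tail either
      else if (!is.null(tsh)) tsh <- tsh * effect_scale
      js <- jitter_scale
      pats <- t(vapply(seq_len(beats_per_interval), function(i) {
        shape(lev + stats::rnorm(1, 0, 5 * js),
              slo + stats::rnorm(1, 0, 3 * js),
              sco + stats::rnorm(1, 0, 2 * js),
              if (is.null(tsh)) NULL else tsh + stats::rnorm(1, 0, 3 * js)) +
          stats::rnorm(window$n_samples, 0, noise_rms)
      }, numeric(window$n_samples)))
      list(patterns = pats, label = label)
    }
    c(lapply(seq_len(n_ischaemic),
             function(i) draw_interval("ischaemic_deviation")),
      lapply(seq_len(n_non_ischaemic),
             function(i) draw_interval("non_ischaemic_deviation")),
      lapply(seq_len(n_no_deviation),
             function(i) draw_interval("no_deviation")))
  })
}
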