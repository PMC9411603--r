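# Synthetic 12-lead ECG generator: Gaussian-bump P-QRS-T morphology with
# class-conditioned abnormalities, plus the simple waveform measurements
# (R-peak detection, RR statistics, QRS width, ST offset, P amplitude)
# used to validate it.

# Fixed per-lead projection of the base beat, loosely following standard
# lead geometry (aVR and the right precordials inverted/attenuated).
# Arbitrary but versioned: changing these silently would change every
# downstream fixture.
LEAD_SCALE <- c(I = 0.7, II = 1.0, III = 0.4, aVR = -0.9, aVL = 0.25,
                aVF = 0.65, V1 = -0.6, V2 = -0.3, V3 = 0.3, V4 = 0.9,
                V5 = 1.1, V6 = 0.9)

#' Morphology parameters for one cardiac cycle
#'
#' The beat is a sum of five Gaussian bumps (P, Q, R, S, T).  Centers are
#' seconds relative to the R peak; widths are Gaussian sigmas in seconds;
#' amplitudes are mV in lead II before per-lead scaling.  `pr` is the
#' P-to-R interval (s); `qrs_scale` multiplies the Q/R/S widths (bundle
#' branch block morphology); `st_offset` shifts the ST segment (mV).
#'
#' @param pr P-to-R interval in seconds (default 0.16).
#' @param p_amp P-wave amplitude in mV (default 0.15).
#' @param qrs_scale width multiplier for the QRS bumps (default 1).
#' @param qrs_amp_scale amplitude multiplier for the QRS bumps.
#' @param st_offset ST-segment offset in mV (default 0).
#' @param t_amp T-wave amplitude in mV.
#' @return a `morphology_params` list.
#' @export
morphology_params <- function(pr = 0.16, p_amp = 0.15, qrs_scale = 1,
                              qrs_amp_scale = 1, st_offset = 0,
                              t_amp = 0.35) {
  structure(list(pr = pr, p_amp = p_amp, qrs_scale = qrs_scale,
                 qrs_amp_scale = qrs_amp_scale, st_offset = st_offset,
                 t_amp = t_amp),
            class = "morphology_params")
}

#' Evaluate one cardiac cycle on a time grid
#'
#' Returns the waveform of a single beat for one lead, sampled at `fs` over
#' `[-0.35, 0.55]` s around the R peak.  Used directly by tests and as the
#' kernel of [synth_record()].
#'
#' @param lead_index 1-12, ordering as [ecg_leads()].
#' @param params a [morphology_params()].
#' @param fs sampling rate, Hz.
#' @return list with `t` (seconds relative to R) and `x` (mV).
#' @export
synth_beat_template <- function(lead_index, params = morphology_params(),
                                fs = 500) {
  t <- seq(-0.35, 0.55, by = 1 / fs)
  list(t = t, x = beat_on_grid(t, lead_index, params))
}

# Beat waveform at times `t` (seconds relative to the R peak).
beat_on_grid <- function(t, lead_index, p) {
  g <- function(center, sigma, amp) amp * exp(-((t - center)^2) / (2 * sigma^2))
  s <- LEAD_SCALE[[lead_index]]
  qs <- p$qrs_scale; qa <- p$qrs_amp_scale
  x <- g(-p$pr, 0.025, p$p_amp * 0.9 * s) +
    g(-0.025 * qs, 0.007 * qs, -0.12 * qa * s) +
    g(0, 0.010 * qs, 1.2 * qa * s) +
    g(0.025 * qs, 0.007 * qs, -0.25 * qa * s) +
    g(0.30, 0.060, p$t_amp * s)
  if (p$st_offset != 0) {
    # smooth plateau over the ST segment (~60-240 ms after R)
    ramp <- function(u) 1 / (1 + exp(-u / 0.012))
    x <- x + p$st_offset * s * (ramp(t - 0.06 * qs) * ramp(0.26 - t))
  }
  x
}

#' Synthetic dataset configuration
#'
#' Defaults emulate the CPSC2018 profile the pipeline was designed around:
#' 500 Hz, record durations 6-60 s with mean about 16 s and roughly 13%
#' of records longer than 1.5x the 16.384 s window (drawn from a truncated
#' log-normal), heart rate 50-100 bpm, 50 Hz power-line noise, baseline
#' wander and broadband muscle noise at modest amplitudes.
#'
#' @param n_records number of records.
#' @param class_mix named proportions over [ecg_classes()] (normalized to
#'   sum to 1); default uniform.
#' @param duration_range allowed duration interval in seconds.
#' @param duration_meanlog,duration_sdlog log-normal duration parameters.
#' @param fs sampling rate, Hz.
#' @param heart_rate_range beats per minute.
#' @param baseline_amp,baseline_freq baseline wander amplitude (mV) and
#'   frequency (Hz).
#' @param line_amp 50 Hz power-line noise amplitude (mV).
#' @param line_freq power-line frequency (Hz).
#' @param white_sd broadband (muscle) noise standard deviation (mV).
#' @param seed integer RNG seed; the same config always yields the same
#'   dataset.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_records = 100,
                         class_mix = NULL,
                         duration_range = c(6, 60),
                         duration_meanlog = 2.657,
                         duration_sdlog = 0.48,
                         fs = 500,
                         heart_rate_range = c(50, 100),
                         baseline_amp = 0.1, baseline_freq = 0.25,
                         line_amp = 0.05, line_freq = 50,
                         white_sd = 0.03,
                         seed = 1L) {
  classes <- ecg_classes()
  if (is.null(class_mix)) {
    class_mix <- stats::setNames(rep(1 / 9, 9L), classes)
  }
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% classes)) {
    stop("`class_mix` must be named with classes from ecg_classes()")
  }
  mix <- stats::setNames(numeric(9L), classes)
  mix[names(class_mix)] <- class_mix
  if (any(mix < 0) || sum(mix) <= 0) stop("invalid class mix")
  mix <- mix / sum(mix)
  stopifnot(duration_range[1L] > 0, duration_range[2L] > duration_range[1L])
  structure(list(n_records = as.integer(n_records), class_mix = mix,
                 duration_range = duration_range,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog, fs = fs,
                 heart_rate_range = heart_rate_range,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 line_amp = line_amp, line_freq = line_freq,
                 white_sd = white_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @param ... overrides passed to [synth_config()].
#' @export
noise_free_config <- function(...) {
  synth_config(baseline_amp = 0, line_amp = 0, white_sd = 0, ...)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate one labeled synthetic record
#'
#' Class-conditioned generative rules: `Normal` has regular RR and standard
#' morphology; `AF` has i.i.d.-jittered RR intervals (cv about 0.2) and no
#' P wave; `I-AVB` has PR 240 ms; `LBBB`/`RBBB` widen the QRS beyond
#' 120 ms (LBBB accentuated in leads I, V1, V2, V5, V6, aVR; RBBB adds a
#' delayed R' in V1-V3); `PAC`/`PVC` insert premature beats (the PVC beat
#' widened and high-amplitude, without a P wave); `STD`/`STE` shift the ST
#' segment by -/+ 0.1-0.3 mV.  Noise per the config; age and sex are drawn
#' from fixed demographic distributions.
#'
#' @param class_label one of [ecg_classes()].
#' @param config a [synth_config()].
#' @param seed integer seed for this record.
#' @param record_id identifier for the generated record.
#' @return an [ecg_record].
#' @export
synth_record <- function(class_label, config = synth_config(), seed = 1L,
                         record_id = "S0001") {
  if (!class_label %in% ecg_classes()) {
    stop(sprintf("unknown class %s; permitted: %s", dQuote(class_label),
                 paste(ecg_classes(), collapse = ", ")))
  }
  with_seed(seed, synth_record_impl(class_label, config, record_id))
}

synth_record_impl <- function(class_label, config, record_id) {
  fs <- config$fs
  dur <- draw_duration(config)
  L <- as.integer(round(dur * fs))
  hr <- stats::runif(1, config$heart_rate_range[1L],
                     config$heart_rate_range[2L])
  rr0 <- 60 / hr

  params <- morphology_params()
  lead_gain <- rep(1, 12L)
  rprime <- FALSE
  switch(class_label,
    "Normal" = NULL,
    "AF" = { params$p_amp <- 0 },
    "I-AVB" = { params$pr <- 0.24 },
    "LBBB" = {
      params$qrs_scale <- 2.5
      idx <- match(c("I", "V1", "V2", "V5", "V6", "aVR"), ecg_leads())
      lead_gain[idx] <- 1.35
    },
    "RBBB" = { params$qrs_scale <- 2.5; rprime <- TRUE },
    "PAC" = NULL,
    "PVC" = NULL,
    "STD" = { params$st_offset <- -stats::runif(1, 0.1, 0.3) },
    "STE" = { params$st_offset <- stats::runif(1, 0.1, 0.3) })

  # beat schedule
  rr <- if (class_label == "AF") {
    n_max <- ceiling(dur / (rr0 * 0.5)) + 2L
    rr0 * pmax(0.5, 1 + stats::rnorm(n_max, 0, 0.2))
  } else {
    rep(rr0, ceiling(dur / rr0) + 2L)
  }
  if (class_label %in% c("PAC", "PVC")) {
    # one premature beat per ~5 s, compensatory pause after
    n_ect <- max(1L, floor(dur / 5))
    pos <- unique(pmin(length(rr) - 1L, 3L + (seq_len(n_ect) - 1L) *
                         max(3L, floor(5 / rr0))))
    rr[pos] <- rr0 * 0.6
    rr[pos + 1L] <- rr0 * 1.35
    ect_pos <- pos + 1L   # index of the premature beat itself
  } else {
    ect_pos <- integer(0)
  }
  beat_t <- cumsum(rr)
  beat_t <- beat_t[beat_t < dur + 0.5]

  sig <- matrix(0, 12L, L)
  tgrid <- (seq_len(L) - 1L) / fs
  for (b in seq_along(beat_t)) {
    tb <- beat_t[b]
    p <- params
    gain <- lead_gain
    if (b %in% ect_pos) {
      if (class_label == "PVC") {
        p$qrs_scale <- 2.5; p$qrs_amp_scale <- 1.5; p$p_amp <- 0
      } else {              # PAC: ectopic P vector, accentuated V1/II/aVF
        p$p_amp <- 0.22
        idx <- match(c("V1", "II", "aVF"), ecg_leads())
        gain[idx] <- gain[idx] * 1.2
      }
    }
    i0 <- max(1L, as.integer(floor((tb - 0.45) * fs)))
    i1 <- min(L, as.integer(ceiling((tb + 0.65) * fs)))
    if (i0 > i1) next
    tt <- tgrid[i0:i1] - tb
    for (ld in 1:12) {
      w <- beat_on_grid(tt, ld, p) * gain[ld]
      if (rprime && ld %in% 7:9) {  # V1-V3 delayed R'
        w <- w + 0.8 * abs(LEAD_SCALE[[ld]]) *
          exp(-((tt - 0.055 * p$qrs_scale)^2) / (2 * (0.012 * p$qrs_scale)^2))
      }
      sig[ld, i0:i1] <- sig[ld, i0:i1] + w
    }
  }

  if (config$baseline_amp > 0) {
    phase <- stats::runif(12L, 0, 2 * pi)
    for (ld in 1:12) {
      sig[ld, ] <- sig[ld, ] + config$baseline_amp *
        sin(2 * pi * config$baseline_freq * tgrid + phase[ld])
    }
  }
  if (config$line_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    line <- config$line_amp * sin(2 * pi * config$line_freq * tgrid + phase)
    sig <- sweep(sig, 2L, line, `+`)
  }
  if (config$white_sd > 0) {
    sig <- sig + matrix(stats::rnorm(length(sig), 0, config$white_sd),
                        nrow(sig))
  }

  age <- max(18, min(95, round(stats::rnorm(1, 60, 15))))
  sex <- if (stats::runif(1) < 0.5) "female" else "male"
  rec <- ecg_record(sig, fs = fs, age = age, sex = sex, label = class_label,
                    record_id = record_id)
  # ground-truth generation parameters, for validation
  attr(rec, "synth_meta") <- list(heart_rate = hr, duration = dur,
                                  morphology = params)
  rec
}

draw_duration <- function(config) {
  repeat {
    d <- stats::rlnorm(1, config$duration_meanlog, config$duration_sdlog)
    if (d >= config$duration_range[1L] && d <= config$duration_range[2L]) {
      return(d)
    }
  }
}

#' Generate a labeled synthetic dataset
#'
#' Class counts follow the configured mix via largest-remainder rounding
#' (each class within one record of its exact share).  Per-record seeds are
#' derived from the config seed, so the same config always reproduces the
#' same dataset bit for bit.
#'
#' @param config a [synth_config()].
#' @param id_prefix prefix for generated record ids.
#' @return list with `records` (list of [ecg_record]) and `manifest`
#'   (a `label_manifest`).
#' @export
synth_dataset <- function(config = synth_config(), id_prefix = "S") {
  n <- config$n_records
  counts <- largest_remainder(config$class_mix * n)
  labels <- rep(names(counts), counts)
  labels <- with_seed(config$seed, sample(labels))
  records <- lapply(seq_len(n), function(i) {
    synth_record(labels[i], config,
                 seed = (config$seed * 1000003L + i) %% .Machine$integer.max,
                 record_id = sprintf("%s%04d", id_prefix, i))
  })
  manifest <- stats::setNames(as.list(labels),
                              vapply(records, `[[`, "", "record_id"))
  class(manifest) <- "label_manifest"
  list(records = records, manifest = manifest)
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x))) - sum(fl)
  if (rem > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  stats::setNames(as.integer(fl), names(x))
}

# --- waveform measurements -------------------------------------------------

#' Simple waveform measurements on a 12-lead record
#'
#' `detect_r_peaks()` finds R peaks in one lead by thresholded local maxima
#' with a 250 ms refractory period.  `ecg_features()` summarizes the
#' rhythm- and morphology-level quantities the synthetic classes
#' manipulate: mean RR and RR coefficient of variation, QRS width (ms),
#' ST-segment offset (mV) and P-wave amplitude (mV).  Intended for
#' validating generated data, not for clinical use.
#'
#' @param record an [ecg_record].
#' @param lead lead name (default `"II"`).
#' @param threshold_frac peak threshold as a fraction of the lead maximum.
#' @return `detect_r_peaks()`: integer sample indices of R peaks.
#' @export
detect_r_peaks <- function(record, lead = "II", threshold_frac = 0.5) {
  x <- record$signal[match(lead, ecg_leads()), ]
  thr <- threshold_frac * max(x)
  refractory <- as.integer(0.25 * record$fs)
  n <- length(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] >= x[cand - 1L] & x[cand] >= x[cand + 1L]]
  peaks <- integer(0)
  for (i in cand) {
    if (!length(peaks) || i - peaks[length(peaks)] > refractory) {
      peaks <- c(peaks, i)
    } else if (x[i] > x[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  peaks
}

#' @rdname detect_r_peaks
#' @return `ecg_features()`: named numeric vector with `n_beats`,
#'   `mean_rr` (s), `rr_cv`, `heart_rate` (bpm), `qrs_width_ms`,
#'   `st_offset` (mV), `p_amp` (mV).
#' @export
ecg_features <- function(record, lead = "II") {
  fs <- record$fs
  x <- record$signal[match(lead, ecg_leads()), ]
  peaks <- detect_r_peaks(record, lead)
  rr <- diff(peaks) / fs
  mean_rr <- if (length(rr)) mean(rr) else NA_real_
  rr_cv <- if (length(rr) > 1L) stats::sd(rr) / mean_rr else NA_real_

  widths <- st <- pamp <- numeric(0)
  for (pk in peaks) {
    lo <- pk - as.integer(0.12 * fs); hi <- pk + as.integer(0.15 * fs)
    if (lo < 1L || hi > length(x)) next
    seg <- x[lo:hi]
    above <- which(abs(seg) > 0.1)
    if (length(above)) {
      widths <- c(widths, (max(above) - min(above) + 1L) / fs * 1000)
    }
    # PR-segment baseline vs mid-ST amplitude
    pr_lo <- pk - as.integer(0.09 * fs); pr_hi <- pk - as.integer(0.05 * fs)
    st_lo <- pk + as.integer(0.10 * fs); st_hi <- pk + as.integer(0.16 * fs)
    p_lo <- pk - as.integer(0.21 * fs); p_hi <- pk - as.integer(0.11 * fs)
    if (pr_lo >= 1L && st_hi <= length(x) && p_lo >= 1L) {
      base <- mean(x[pr_lo:pr_hi])
      st <- c(st, mean(x[st_lo:st_hi]) - base)
      pamp <- c(pamp, max(abs(x[p_lo:p_hi] - base)))
    }
  }
  c(n_beats = length(peaks), mean_rr = mean_rr, rr_cv = rr_cv,
    heart_rate = if (is.na(mean_rr)) NA_real_ else 60 / mean_rr,
    qrs_width_ms = if (length(widths)) stats::median(widths) else NA_real_,
    st_offset = if (length(st)) stats::median(st) else NA_real_,
    p_amp = if (length(pamp)) stats::median(pamp) else NA_real_)
}
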