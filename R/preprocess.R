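# Signal conditioning and 2D construction: band-pass denoising, Welch PSD
# diagnostics, symmetric min-max normalization, lead splicing into an L x 12
# plane, slicing into 8192-sample windows, and channel-axis expansion.

#' Band-pass filter specification
#'
#' Defaults follow the pipeline's denoising stage: a Butterworth band-pass
#' with cutoffs 0.5-49 Hz (removing baseline wander below and power-line /
#' muscle noise above), order 3, applied forward-backward so the ECG
#' waveform is not phase-distorted.
#'
#' @param low_cut,high_cut cutoff frequencies in Hz.
#' @param order filter order (per pass).
#' @param zero_phase apply forward-backward (`filtfilt`)? Default `TRUE`.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 49, order = 3,
                        zero_phase = TRUE) {
  if (!(low_cut > 0 && high_cut > low_cut)) {
    stop("need 0 < low_cut < high_cut")
  }
  if (order < 1) stop("`order` must be a positive integer")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

butter_for <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$high_cut >= nyq) {
    stop(sprintf("high_cut %g Hz must be below the Nyquist frequency %g Hz",
                 spec$high_cut, nyq))
  }
  signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq,
                 type = "pass")
}

#' Band-pass filter a 12-lead record
#'
#' Each lead is filtered independently; the output has the same length as
#' the input.  With `zero_phase = TRUE` the filter runs forward and
#' backward (`signal::filtfilt`), doubling the effective order and giving
#' zero phase shift.
#'
#' @param record an [ecg_record].
#' @param spec a [filter_spec()].
#' @return the filtered [ecg_record].
#' @export
bandpass <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "ecg_record"))
  bf <- butter_for(spec, record$fs)
  out <- record$signal
  for (i in seq_len(nrow(out))) {
    out[i, ] <- if (spec$zero_phase) {
      signal::filtfilt(bf, record$signal[i, ])
    } else {
      as.numeric(signal::filter(bf, record$signal[i, ]))
    }
  }
  record$signal <- out
  record
}

#' Magnitude response of the configured band-pass filter
#'
#' Utility for verifying attenuation at specific frequencies (e.g. 50 Hz
#' power-line noise).  For a zero-phase specification the squared response
#' of the single pass is returned, which is what two passes apply.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @param freq frequencies (Hz) at which to evaluate.
#' @return numeric vector of linear gains in (0, 1].
#' @export
filter_gain <- function(spec, fs, freq) {
  bf <- butter_for(spec, fs)
  w <- 2 * pi * freq / fs
  z <- exp(1i * w)
  h <- vapply(z, function(zz) {
    num <- sum(bf$b * zz^-(seq_along(bf$b) - 1))
    den <- sum(bf$a * zz^-(seq_along(bf$a) - 1))
    Mod(num / den)
  }, numeric(1))
  if (spec$zero_phase) h^2 else h
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over 50%-overlapping segments, one-sided,
#' density-scaled so that the integral over frequency approximates the
#' signal variance.  Supported tapers: `blackman`, `hanning`, `triangular`.
#'
#' @param x numeric vector (one lead's time series).
#' @param fs sampling rate in Hz.
#' @param window one of `"blackman"`, `"hanning"`, `"triangular"`.
#' @param nperseg segment length in samples (256, 512 or 1024 in the
#'   diagnostic grid; any value >= 8 is accepted).
#' @param detrend subtract the mean of each segment? Default `TRUE`.
#' @return list with `freq` (Hz, 0 to fs/2) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = 500, window = c("hanning", "blackman",
                                              "triangular"),
                      nperseg = 256, detrend = TRUE) {
  window <- match.arg(window)
  nperseg <- as.integer(nperseg)
  if (length(x) < nperseg) {
    stop(sprintf("series length %d is shorter than nperseg %d",
                 length(x), nperseg))
  }
  w <- switch(window,
              hanning = signal::hanning(nperseg),
              blackman = signal::blackman(nperseg),
              triangular = signal::triang(nperseg))
  step <- nperseg %/% 2L
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  scale <- fs * sum(w^2)
  acc <- numeric(nperseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    spec <- Mod(stats::fft(seg * w))^2 / scale
    half <- spec[seq_len(nperseg %/% 2L + 1L)]
    # one-sided: double everything except DC and (for even n) Nyquist
    half[-1L] <- 2 * half[-1L]
    if (nperseg %% 2L == 0L) half[length(half)] <- half[length(half)] / 2
    acc <- acc + half
  }
  list(freq = seq(0L, nperseg %/% 2L) * fs / nperseg,
       psd = acc / length(starts))
}

#' Symmetric min-max normalization of a 2D ECG
#'
#' Affinely rescales the whole voltage matrix so its observed minimum and
#' maximum map exactly onto a symmetric target interval, by default
#' \[-3 mV, 3 mV\]:
#' \deqn{A'_{ij} = R_{min} + \frac{(R_{max}-R_{min})(A_{ij}-A_{min})}
#'                               {A_{max}-A_{min}}.}
#' The observed extrema are taken over the entire matrix, all leads
#' jointly, so every slice of a record shares one normalization map.
#'
#' @param A numeric matrix (L samples x 12 leads), mV.
#' @param r_min,r_max target interval bounds, mV.
#' @return list with `values` (normalized matrix) and `params` (a
#'   `normalization_params` list with `r_min`, `r_max`, `a_min`, `a_max`).
#' @export
minmax_normalize <- function(A, r_min = -3, r_max = 3) {
  if (!all(is.finite(A))) stop("input matrix contains non-finite values")
  if (!(r_min < r_max)) stop("need r_min < r_max")
  a_min <- min(A); a_max <- max(A)
  if (a_max == a_min) {
    stop("zero amplitude range: constant record cannot be normalized")
  }
  out <- r_min + (r_max - r_min) * (A - a_min) / (a_max - a_min)
  # guard against floating-point overshoot: the map is onto [r_min, r_max]
  out[out < r_min] <- r_min
  out[out > r_max] <- r_max
  params <- structure(list(r_min = r_min, r_max = r_max,
                           a_min = a_min, a_max = a_max),
                      class = "normalization_params")
  list(values = out, params = params)
}

#' Splice the 12 leads into a two-dimensional plane
#'
#' Stacks the lead time series as columns of an L x 12 matrix (the
#' transpose of the record's lead x sample storage), treating the 12-lead
#' ECG like a tall grayscale image whose pixels are voltages.
#'
#' @param record an [ecg_record].
#' @return numeric L x 12 matrix with lead names as column names.
#' @export
to_two_dimensional <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  t(record$signal)
}

#' Slicing policy
#'
#' @param slice_len window length in samples (default 8192, i.e. 16.384 s
#'   at 500 Hz).
#' @param overlap overlap between consecutive windows (default 4096).
#' @param long_threshold_factor records longer than this multiple of
#'   `slice_len` are cut into overlapping windows (default 1.5).
#' @return a `slicing_policy` list.
#' @export
slicing_policy <- function(slice_len = 8192, overlap = 4096,
                           long_threshold_factor = 1.5) {
  slice_len <- as.integer(slice_len); overlap <- as.integer(overlap)
  if (!(overlap > 0L && overlap < slice_len)) {
    stop("need 0 < overlap < slice_len")
  }
  structure(list(slice_len = slice_len, overlap = overlap,
                 long_threshold_factor = long_threshold_factor),
            class = "slicing_policy")
}

#' Cut a 2D ECG into fixed-length windows
#'
#' Three cases, for window length `S` (= 8192 by default):
#' short records (`L < S`) give one window zero-padded at the tail;
#' records with `S <= L < 1.5 S` give one window with the tail truncated;
#' records with `L >= 1.5 S` give `n = floor(2 L / S) - 1` windows of
#' length `S` whose starts are `S - overlap` (= 4096) samples apart.
#'
#' @param A numeric L x 12 matrix.
#' @param policy a [slicing_policy()].
#' @return list of slices; each has `values` (S x 12 matrix),
#'   `origin_offset` (0-based sample offset into the record) and
#'   `n_padded` (zero-padded tail samples, short records only).
#' @export
slice_ecg <- function(A, policy = slicing_policy()) {
  L <- nrow(A); S <- policy$slice_len
  if (is.null(L) || L == 0L) stop("empty 2D ECG (L = 0)")
  step <- S - policy$overlap
  if (L < S) {
    padded <- rbind(A, matrix(0, S - L, ncol(A)))
    return(list(list(values = padded, origin_offset = 0L,
                     n_padded = S - L)))
  }
  if (L < policy$long_threshold_factor * S) {
    return(list(list(values = A[seq_len(S), , drop = FALSE],
                     origin_offset = 0L, n_padded = 0L)))
  }
  n <- (2L * L) %/% S - 1L
  lapply(seq_len(n) - 1L, function(i) {
    list(values = A[(i * step + 1L):(i * step + S), , drop = FALSE],
         origin_offset = i * step, n_padded = 0L)
  })
}

#' Add the trailing channel axis
#'
#' Turns an S x 12 window into the S x 12 x 1 array shape the 2D
#' convolutional network expects; values are unchanged.
#'
#' @param values an S x 12 matrix (already 3-dimensional input is an
#'   error: the channel axis must be added exactly once).
#' @return S x 12 x 1 array.
#' @export
expand_dims <- function(values) {
  if (length(dim(values)) == 3L) {
    stop("input already has a channel axis (3 dimensions)")
  }
  if (!is.matrix(values)) stop("input must be a matrix")
  array(values, dim = c(dim(values), 1L))
}

#' Full preprocessing pipeline for one record
#'
#' Runs filter -> 2D splice -> min-max normalize (whole record) -> slice ->
#' expand dims.  Padded tail samples of short records are forced to exactly
#' zero after normalization, so a padded window reads as silence rather
#' than the normalized image of 0 mV.
#'
#' @param record an [ecg_record].
#' @param fspec a [filter_spec()], or `NULL` to skip filtering.
#' @param policy a [slicing_policy()].
#' @param r_min,r_max normalization target interval, mV.
#' @return list of `two_dim_slice` objects, each with `values`
#'   (S x 12 x 1 array), `record_id`, `slice_index`, `origin_offset`,
#'   `label`, `age`, `sex`, and the shared `norm_params`.
#' @export
preprocess_record <- function(record, fspec = filter_spec(),
                              policy = slicing_policy(),
                              r_min = -3, r_max = 3) {
  stopifnot(inherits(record, "ecg_record"))
  filtered <- if (is.null(fspec)) record else bandpass(record, fspec)
  A <- to_two_dimensional(filtered)
  norm <- minmax_normalize(A, r_min = r_min, r_max = r_max)
  pieces <- slice_ecg(norm$values, policy)
  lapply(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    v <- p$values
    if (p$n_padded > 0L) {
      v[(nrow(v) - p$n_padded + 1L):nrow(v), ] <- 0
    }
    structure(list(values = expand_dims(v), record_id = record$record_id,
                   slice_index = i, origin_offset = p$origin_offset,
                   label = record$label, age = record$age, sex = record$sex,
                   norm_params = norm$params),
              class = "two_dim_slice")
  })
}
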