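make_tone_record <- function(freq, amp = 1, L = 5000, fs = 500) {
  t <- (seq_len(L) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  ecg_record(matrix(rep(x, each = 12), 12, L), fs = fs,
             record_id = sprintf("tone%g", freq))
}

rms <- function(x) sqrt(mean(x^2))

test_that("band-pass removes DC and matches its own magnitude response", {
  fs <- 500
  spec <- filter_spec()  # 0.5-49 Hz, order 3, zero-phase

  dc <- ecg_record(matrix(1, 12, 20000), fs = fs, record_id = "dc")
  out <- bandpass(dc, spec)
  expect_identical(dim(out$signal), dim(dc$signal))
  expect_lt(mean(abs(out$signal)), 0.01)

  # oracle: the designed filter's magnitude response at the tone frequency
  core <- 1001:4000  # avoid filtfilt edge transients
  for (freq in c(10, 50)) {
    tone <- make_tone_record(freq, L = 5000, fs = fs)
    filt <- bandpass(tone, spec)
    measured <- rms(filt$signal[2, core]) / rms(tone$signal[2, core])
    expect_equal(measured, filter_gain(spec, fs, freq), tolerance = 0.02)
  }
  expect_equal(filter_gain(spec, fs, 10), 1, tolerance = 0.1)   # passband
  expect_lt(filter_gain(spec, fs, 50), filter_gain(spec, fs, 10))
  expect_lt(filter_gain(spec, fs, 100), 0.01)  # deep stopband
})

test_that("band-pass rejects cutoffs at or above Nyquist", {
  rec <- fixture_record(L = 100)
  expect_error(bandpass(rec, filter_spec(high_cut = 250)), "Nyquist")
  expect_error(filter_spec(low_cut = 0), "low_cut")
})

test_that("welch psd satisfies Parseval and locates tones", {
  fs <- 500
  x <- with_fixed_seed(21, stats::rnorm(65536))
  for (win in c("hanning", "blackman", "triangular")) {
    w <- welch_psd(x, fs = fs, window = win, nperseg = 1024)
    integral <- sum(w$psd) * (w$freq[2] - w$freq[1])
    expect_equal(integral, stats::var(x), tolerance = 0.2)
    expect_equal(range(w$freq), c(0, fs / 2))
  }
  t <- (seq_len(8192) - 1) / fs
  tone <- sin(2 * pi * 10 * t)
  w <- welch_psd(tone, fs = fs, window = "hanning", nperseg = 512)
  expect_lt(abs(w$freq[which.max(w$psd)] - 10), fs / 512 + 1e-9)
  expect_error(welch_psd(tone, window = "kaiser"), "hanning")
  expect_error(welch_psd(tone[1:100], nperseg = 256), "shorter")
})

test_that("filtering attenuates the psd at every bin above 60 Hz", {
  cfg <- synth_config(seed = 9, white_sd = 0.08, line_amp = 0.1)
  rec <- synth_record("Normal", cfg, seed = 2, record_id = "noisy")
  filt <- bandpass(rec, filter_spec())
  raw_psd <- welch_psd(rec$signal[1, ], fs = rec$fs, nperseg = 256)
  flt_psd <- welch_psd(filt$signal[1, ], fs = rec$fs, nperseg = 256)
  hi <- raw_psd$freq >= 60
  expect_true(all(flt_psd$psd[hi] < raw_psd$psd[hi]))
})

test_that("min-max normalization reproduces the worked example exactly", {
  A <- matrix(c(-20.9, 0, 20.7, 0), 2, 2)
  res <- minmax_normalize(A)
  expect_equal(min(res$values), -3)
  expect_equal(max(res$values), 3)
  f0 <- -3 + 6 * 20.9 / 41.6                # f(0) = 0.014423...
  expect_equal(res$values[2, 1], f0)
  expect_equal(res$values[2, 2], f0)
  expect_equal(res$values[1, 1], -3)
  expect_equal(res$values[1, 2], 3)
  expect_equal(res$params$a_min, -20.9)
  expect_equal(res$params$a_max, 20.7)

  # symmetric input maps midpoint to midpoint
  B <- matrix(c(-1, 0, 1), 3, 1)
  expect_equal(minmax_normalize(B)$values[2, 1], 0)

  expect_error(minmax_normalize(matrix(2, 3, 3)), "zero amplitude range")
})

test_that("normalization is monotone and hits both endpoints", {
  A <- with_fixed_seed(4, matrix(stats::rcauchy(8192 * 12), 8192, 12))
  res <- minmax_normalize(A)
  expect_equal(min(res$values), -3)
  expect_equal(max(res$values), 3)
  o <- order(A)
  expect_true(!is.unsorted(res$values[o]))
})

test_that("the 2D ECG is the transpose of the stored signal", {
  rec <- fixture_record(L = 17)
  A <- to_two_dimensional(rec)
  expect_identical(unname(A), unname(t(rec$signal)))
  leads <- ecg_record(matrix(rep(1:12, 30), 12, 30), record_id = "const")
  A2 <- to_two_dimensional(leads)
  for (j in 1:12) expect_true(all(A2[, j] == j))
  one <- ecg_record(matrix(2, 12, 1), record_id = "L1")
  expect_identical(dim(to_two_dimensional(one)), c(1L, 12L))
})

test_that("slicing follows the three length rules", {
  pol <- slicing_policy()
  mk <- function(L) matrix(as.numeric(seq_len(L)), L, 12)

  s1 <- slice_ecg(mk(5000), pol)            # L < 8192: zero-pad
  expect_length(s1, 1)
  expect_identical(dim(s1[[1]]$values), c(8192L, 12L))
  expect_true(all(s1[[1]]$values[5001:8192, ] == 0))
  expect_identical(s1[[1]]$values[1:5000, 1], as.numeric(1:5000))

  s2 <- slice_ecg(mk(10000), pol)           # 8192 <= L < 12288: truncate tail
  expect_length(s2, 1)
  expect_identical(s2[[1]]$values[, 2], as.numeric(1:8192))

  s3 <- slice_ecg(mk(20480), pol)           # floor(2L/8192) - 1 = 4
  expect_length(s3, 4)
  expect_equal(vapply(s3, `[[`, 0L, "origin_offset"),
               c(0L, 4096L, 8192L, 12288L))
  for (sl in s3) {
    expect_identical(sl$values[, 1],
                     as.numeric(sl$origin_offset + 1:8192))
  }

  s4 <- slice_ecg(mk(12288), pol)           # boundary: exactly 1.5 x 8192
  expect_length(s4, 2)

  expect_error(slice_ecg(mk(0), pol), "L = 0")
})

test_that("slice count matches floor(2L/S) - 1 with full coverage", {
  pol <- slicing_policy()
  Ls <- with_fixed_seed(6, sample(12288:80000, 25))
  for (L in Ls) {
    slices <- slice_ecg(matrix(0, L, 12), pol)
    n <- length(slices)
    expect_identical(n, (2L * L) %/% 8192L - 1L)
    offs <- vapply(slices, `[[`, 0L, "origin_offset")
    expect_equal(offs, (seq_len(n) - 1L) * 4096L)
    # joint coverage of [0, 4096 (n-1) + 8192); adjacent overlap = 4096
    expect_equal(offs[n] + 8192L, 4096L * (n - 1L) + 8192L)
    if (n > 1) expect_equal(offs[2] - offs[1], 4096L)
  }
})

test_that("expand_dims adds exactly one channel axis", {
  m <- matrix(1:24, 12, 2)
  a <- expand_dims(m)
  expect_identical(dim(a), c(12L, 2L, 1L))
  expect_identical(as.vector(a), as.vector(m))
  expect_error(expand_dims(a), "already")
})

test_that("preprocess_record composes the stages in order", {
  cfg <- synth_config(seed = 14)
  long <- synth_record("AF", synth_config(seed = 14,
                                          duration_range = c(40.9, 41),
                                          duration_meanlog = log(40.96),
                                          duration_sdlog = 0.001),
                       seed = 3, record_id = "long")
  slices <- preprocess_record(long)
  expect_length(slices, (2L * ncol(long$signal)) %/% 8192L - 1L)
  for (sl in slices) {
    expect_identical(dim(sl$values), c(8192L, 12L, 1L))
    expect_true(all(sl$values >= -3 & sl$values <= 3))
    expect_equal(sl$record_id, "long")
    expect_equal(sl$label, "AF")
  }
  # the record-level normalization attains both endpoints exactly
  norm <- minmax_normalize(to_two_dimensional(bandpass(long)))
  expect_equal(min(norm$values), -3)
  expect_equal(max(norm$values), 3)

  short <- synth_record("Normal", synth_config(seed = 15,
                                               duration_range = c(10, 10.1)),
                        seed = 4, record_id = "short")
  ss <- preprocess_record(short)
  expect_length(ss, 1)
  L <- ncol(short$signal)
  expect_true(all(ss[[1]]$values[(L + 1):8192, , 1] == 0))

  const <- ecg_record(matrix(1, 12, 1000), record_id = "flat")
  expect_error(preprocess_record(const, fspec = NULL),
               "zero amplitude range")
})
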