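# Minimal WFDB support: header (.hea) + 16-bit little-endian signal (.dat),
# format 16, one .dat shared by all 12 leads, interleaved by sample.
# Output is rescaled to mV using each signal's gain and baseline.

#' Read or write a 12-lead WFDB record pair
#'
#' Supports the common single-segment dialect: a `.hea` header naming one
#' interleaved format-16 `.dat` file, 12 signals, gain in ADC units per mV
#' and an integer baseline.  `read_wfdb()` returns voltages in mV.
#'
#' @param path path to the `.hea` file (or the record name without
#'   extension).
#' @return `read_wfdb()`: an [ecg_record].
#' @export
read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rec_name <- top[1L]
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(top[3L]) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (nsig != 12L) stop(sprintf("expected 12 signals in %s, got %d", hea, nsig))
  specs <- lapply(lines[2L:(1L + nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- f[2L]
    if (fmt != "16") stop("only WFDB format 16 is supported, got ", fmt)
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gb <- strsplit(gain_field, "[(/]")[[1L]]
    gain <- as.numeric(gb[1L])
    baseline <- if (length(gb) >= 2L) as.numeric(sub("\\)$", "", gb[2L])) else 0
    if (!is.finite(gain) || gain == 0) gain <- 200
    list(file = f[1L], gain = gain, baseline = baseline)
  })
  datafiles <- unique(vapply(specs, `[[`, "", "file"))
  if (length(datafiles) != 1L) {
    stop("multi-file WFDB records are not supported")
  }
  dat <- file.path(dirname(hea), datafiles)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  n_int <- file.size(dat) %/% 2L
  adc <- readBin(dat, "integer", n = n_int, size = 2L, signed = TRUE,
                 endian = "little")
  L <- length(adc) %/% nsig
  if (!is.na(nsamp) && nsamp != L) {
    stop(sprintf("header declares %d samples but %s holds %d", nsamp, dat, L))
  }
  m <- matrix(adc[seq_len(L * nsig)], nrow = nsig)  # interleaved by sample
  sig <- m
  for (i in seq_len(nsig)) {
    sig[i, ] <- (m[i, ] - specs[[i]]$baseline) / specs[[i]]$gain
  }
  ecg_record(sig, fs = fs, record_id = rec_name)
}

#' @rdname read_wfdb
#' @param record an [ecg_record].
#' @param dir output directory; files are named after `record$record_id`.
#' @param gain ADC units per mV (default 1000).
#' @export
write_wfdb <- function(record, dir, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  id <- record$record_id
  L <- ncol(record$signal)
  adc <- round(record$signal * gain)
  if (any(abs(adc) > 32767)) {
    stop("signal exceeds the 16-bit ADC range at gain ", gain)
  }
  hea <- file.path(dir, paste0(id, ".hea"))
  dat_name <- paste0(id, ".dat")
  lines <- c(sprintf("%s 12 %g %d", id, record$fs, L),
             sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s",
                     dat_name, gain, ecg_leads()))
  writeLines(lines, hea)
  writeBin(as.integer(adc), file.path(dir, dat_name), size = 2L,
           endian = "little")
  invisible(hea)
}
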