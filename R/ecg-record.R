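#' @keywords internal
"_PACKAGE"

#' Rhythm classes and lead names
#'
#' The nine rhythm classes handled by the pipeline, in the fixed order used
#' by every confusion matrix and probability vector in the package: normal
#' sinus rhythm, atrial fibrillation (AF), first-degree atrioventricular
#' block (I-AVB), left and right bundle branch block (LBBB, RBBB), premature
#' atrial and ventricular contractions (PAC, PVC), and ST-segment depression
#' and elevation (STD, STE).
#'
#' @return `ecg_classes()`: character vector of the 9 class names.
#'   `ecg_leads()`: the 12 standard lead names in storage order.
#' @export
ecg_classes <- function() {
  c("Normal", "AF", "I-AVB", "LBBB", "RBBB", "PAC", "PVC", "STD", "STE")
}

#' @rdname ecg_classes
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Construct a 12-lead ECG record
#'
#' An `ecg_record` bundles one patient's 12-lead voltage matrix with its
#' sampling rate, demographics and rhythm label.  Voltages are in mV with
#' leads as rows, in the standard order I, II, III, aVR, aVL, aVF, V1-V6.
#'
#' @param signal numeric matrix, 12 rows (leads) by L >= 1 columns
#'   (samples), all values finite, units mV.
#' @param fs sampling rate in Hz (default 500).
#' @param age age in years, or `NA` when unknown.
#' @param sex `"female"`, `"male"`, or `NA` when unknown.
#' @param label one of [ecg_classes()], or `NA` for unlabeled input.
#' @param record_id character identifier.
#' @param extra_labels optional character vector of secondary labels
#'   (kept for provenance; the classifier uses `label` only).
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs = 500, age = NA_real_, sex = NA_character_,
                       label = NA_character_, record_id = "record",
                       extra_labels = character()) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix (12 leads x L samples)")
  }
  if (nrow(signal) != 12L) {
    stop(sprintf("expected 12 leads, got %d rows in `signal`", nrow(signal)))
  }
  if (ncol(signal) < 1L) stop("`signal` must have at least one sample")
  if (!all(is.finite(signal))) stop("`signal` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive number (Hz)")
  }
  age <- as.numeric(age)[1L]
  sex <- as.character(sex)[1L]
  if (!is.na(sex) && !sex %in% c("female", "male")) {
    stop("`sex` must be \"female\", \"male\" or NA")
  }
  label <- as.character(label)[1L]
  if (!is.na(label) && !label %in% ecg_classes()) {
    stop(sprintf("unknown label %s; permitted classes: %s",
                 dQuote(label), paste(ecg_classes(), collapse = ", ")))
  }
  extra_labels <- as.character(extra_labels)
  bad <- setdiff(extra_labels, ecg_classes())
  if (length(bad)) {
    stop(sprintf("unknown secondary label(s) %s; permitted classes: %s",
                 paste(dQuote(bad), collapse = ", "),
                 paste(ecg_classes(), collapse = ", ")))
  }
  storage.mode(signal) <- "double"
  dimnames(signal) <- list(ecg_leads(), NULL)
  structure(
    list(record_id = as.character(record_id)[1L], signal = signal,
         fs = as.numeric(fs), age = age, sex = sex, label = label,
         extra_labels = extra_labels),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s>  12 x %d samples @ %g Hz (%.2f s)\n",
              x$record_id, ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat(sprintf("  age: %s  sex: %s  label: %s%s\n",
              ifelse(is.na(x$age), "?", format(x$age)),
              ifelse(is.na(x$sex), "?", x$sex),
              ifelse(is.na(x$label), "?", x$label),
              if (length(x$extra_labels))
                paste0(" (+", paste(x$extra_labels, collapse = ","), ")")
              else ""))
  invisible(x)
}

#' @export
format.ecg_record <- function(x, ...) {
  sprintf("<ecg_record %s: 12x%d @ %gHz, %s>", x$record_id,
          ncol(x$signal), x$fs, ifelse(is.na(x$label), "?", x$label))
}

record_duration <- function(record) ncol(record$signal) / record$fs

#' Read or write a CPSC2018-style label manifest
#'
#' The manifest is a CSV with a header row, one row per record: the record
#' id in the first column and one to three rhythm labels in the remaining
#' columns (`Recording,First_label,Second_label,Third_label`).  The first
#' label is the ground truth used for training; secondary labels are
#' retained but unused.
#'
#' @param path CSV file path.
#' @return `read_manifest()`: a `label_manifest`, i.e. a named list mapping
#'   record id to a character vector of labels (first = ground truth).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("manifest needs an id column and >= 1 label column")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  entries <- lapply(seq_len(nrow(df)), function(i) {
    labs <- as.character(df[i, -1L])
    labs <- labs[!is.na(labs) & nzchar(labs)]
    bad <- setdiff(labs, ecg_classes())
    if (length(bad)) {
      stop(sprintf("unknown label token %s for record %s; permitted: %s",
                   paste(dQuote(bad), collapse = ", "), ids[i],
                   paste(ecg_classes(), collapse = ", ")))
    }
    labs
  })
  names(entries) <- ids
  structure(entries, class = "label_manifest")
}

#' @rdname read_manifest
#' @param manifest a `label_manifest` or a named list of label vectors.
#' @export
write_manifest <- function(manifest, path) {
  ids <- names(manifest)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("manifest must be a named list with unique record ids")
  }
  pad <- function(labs) c(labs, rep("", 3L - length(labs)))[1:3]
  m <- t(vapply(manifest, pad, character(3)))
  df <- data.frame(Recording = ids, First_label = m[, 1L],
                   Second_label = m[, 2L], Third_label = m[, 3L],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Lossless archive format for ECG records
#'
#' `write_record()` and `read_record()` round-trip an [ecg_record]
#' (including metadata and a bit-exact voltage matrix) through a versioned
#' single-file archive, used for intermediate artifacts between pipeline
#' stages.
#'
#' @param record an [ecg_record].
#' @param path file path (conventionally `.ecgr`).
#' @return `read_record()` returns the stored [ecg_record].
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  obj <- list(format = "dseresnet-record", version = 1L,
              record = unclass(record))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "dseresnet-record")) {
    stop("not a dseresnet record archive: ", path)
  }
  if (!identical(obj$version, 1L)) {
    stop(sprintf("record archive version %s not supported (expected 1)",
                 format(obj$version)))
  }
  r <- obj$record
  ecg_record(r$signal, fs = r$fs, age = r$age, sex = r$sex, label = r$label,
             record_id = r$record_id, extra_labels = r$extra_labels)
}
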