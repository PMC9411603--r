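# Minimal MATLAB Level-5 (.mat) codec covering the CPSC2018 dialect:
# double / char / 1x1 struct arrays, little-endian, optionally
# zlib-compressed elements on read.  Data type and array class codes follow
# the published MAT-file format tables.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L
MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_STRUCT <- 2L

pad8 <- function(n) (8L - n %% 8L) %% 8L

mat5_tag <- function(type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), raw(), size = 4L,
           endian = "little")
}

mat5_element <- function(type, data_raw) {
  c(mat5_tag(type, length(data_raw)), data_raw,
    raw(pad8(length(data_raw))))
}

mat5_numeric_raw <- function(x) {
  writeBin(as.double(x), raw(), size = 8L, endian = "little")
}

mat5_int32_raw <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

# Build one miMATRIX element (as raw) for a double matrix, a character
# scalar, or a named list (1x1 struct).  `name` is empty for struct fields.
mat5_matrix <- function(value, name) {
  name_raw <- if (nzchar(name)) charToRaw(name) else raw(0)
  header <- function(class_code, dims) {
    c(mat5_element(MI_UINT32,
                   writeBin(as.integer(c(class_code, 0L)), raw(),
                            size = 4L, endian = "little")),
      mat5_element(MI_INT32, mat5_int32_raw(dims)),
      mat5_element(MI_INT8, name_raw))
  }
  body <-
    if (is.character(value)) {
      s <- if (length(value) && !is.na(value)) value[1L] else ""
      codes <- utf8ToInt(s)
      dims <- if (nchar(s)) c(1L, length(codes)) else c(0L, 0L)
      c(header(MX_CHAR, dims),
        mat5_element(MI_UINT16,
                     writeBin(as.integer(codes), raw(), size = 2L,
                              endian = "little")))
    } else if (is.list(value)) {
      fields <- names(value)
      stopifnot(!is.null(fields), all(nzchar(fields)))
      fn_raw <- unlist(lapply(fields, function(f) {
        b <- charToRaw(f)
        if (length(b) > 31L) stop("struct field name too long: ", f)
        c(b, raw(32L - length(b)))
      }))
      c(header(MX_STRUCT, c(1L, 1L)),
        mat5_element(MI_INT32, mat5_int32_raw(32L)),
        mat5_element(MI_INT8, fn_raw),
        unlist(lapply(value, mat5_matrix, name = "")))
    } else {
      x <- value
      if (is.null(x) || (length(x) == 1L && is.na(x))) x <- numeric(0)
      dims <- if (is.matrix(x)) dim(x) else c(length(x) > 0L, length(x))
      if (!is.matrix(x)) dims <- if (length(x)) c(1L, length(x)) else c(0L, 0L)
      c(header(MX_DOUBLE, dims),
        mat5_element(MI_DOUBLE, mat5_numeric_raw(x)))
    }
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

#' Low-level MATLAB v5 file writer
#'
#' Writes named variables (double matrices, character scalars, or named
#' lists encoded as 1x1 structs) to an uncompressed little-endian MAT
#' Level-5 file.  This is the subset of the format the CPSC2018 archive
#' uses; it is not a general MAT writer.
#'
#' @param vars named list of variables.
#' @param path output file.
#' @export
#' @keywords internal
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by dseresnet on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  desc_raw <- charToRaw(desc)
  header <- c(desc_raw, rep(charToRaw(" "), 116L - length(desc_raw)),
              raw(8L),
              writeBin(c(256L), raw(), size = 2L, endian = "little"),
              charToRaw("IM"))
  body <- unlist(lapply(names(vars), function(nm) {
    mat5_matrix(vars[[nm]], nm)
  }))
  writeBin(c(header, body), path)
  invisible(path)
}

# --- reader ----------------------------------------------------------------

mat5_read_int <- function(raw, off, size, signed = TRUE) {
  readBin(raw[(off + 1L):(off + size)], "integer", n = 1L, size = size,
          signed = signed, endian = "little")
}

# Returns list(type, nbytes, data_off, next_off) for the element at `off`.
mat5_read_tag <- function(raw, off) {
  word <- mat5_read_int(raw, off, 4L)
  small_size <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
  if (small_size != 0L) {                       # small data element format
    list(type = bitwAnd(word, 0xFFFFL), nbytes = small_size,
         data_off = off + 4L, next_off = off + 8L)
  } else {
    nbytes <- mat5_read_int(raw, off + 4L, 4L)
    list(type = word, nbytes = nbytes, data_off = off + 8L,
         next_off = off + 8L + nbytes + pad8(nbytes))
  }
}

mat5_decode_numeric <- function(raw, off, nbytes, type) {
  sub <- raw[seq_len(nbytes) + off]
  switch(as.character(type),
         "1" = as.double(readBin(sub, "integer", nbytes, 1L, TRUE, endian = "little")),
         "2" = as.double(readBin(sub, "integer", nbytes, 1L, FALSE, endian = "little")),
         "3" = as.double(readBin(sub, "integer", nbytes %/% 2L, 2L, TRUE, endian = "little")),
         "4" = as.double(readBin(sub, "integer", nbytes %/% 2L, 2L, FALSE, endian = "little")),
         "5" = as.double(readBin(sub, "integer", nbytes %/% 4L, 4L, TRUE, endian = "little")),
         "6" = as.double(readBin(sub, "integer", nbytes %/% 4L, 4L, TRUE, endian = "little")),
         "7" = as.double(readBin(sub, "double", nbytes %/% 4L, 4L, endian = "little")),
         "9" = readBin(sub, "double", nbytes %/% 8L, 8L, endian = "little"),
         "16" = utf8ToInt(rawToChar(sub)),
         stop("unsupported MAT data type code ", type))
}

# Parse one miMATRIX payload (raw slice without the outer tag).
mat5_parse_matrix <- function(raw) {
  off <- 0L
  flags <- mat5_read_tag(raw, off)
  class_code <- bitwAnd(mat5_read_int(raw, flags$data_off, 4L), 0xFFL)
  off <- flags$next_off
  dims_el <- mat5_read_tag(raw, off)
  ndim <- dims_el$nbytes %/% 4L
  dims <- vapply(seq_len(ndim) - 1L, function(i)
    mat5_read_int(raw, dims_el$data_off + 4L * i, 4L), integer(1))
  off <- dims_el$next_off
  name_el <- mat5_read_tag(raw, off)
  name <- if (name_el$nbytes > 0L)
    rawToChar(raw[seq_len(name_el$nbytes) + name_el$data_off]) else ""
  off <- name_el$next_off

  value <-
    if (class_code == MX_STRUCT) {
      fl <- mat5_read_tag(raw, off)
      flen <- mat5_read_int(raw, fl$data_off, 4L)
      off <- fl$next_off
      fn <- mat5_read_tag(raw, off)
      nfields <- fn$nbytes %/% flen
      fields <- vapply(seq_len(nfields), function(i) {
        b <- raw[seq_len(flen) + fn$data_off + (i - 1L) * flen]
        rawToChar(b[b != as.raw(0)])
      }, character(1))
      off <- fn$next_off
      out <- vector("list", nfields)
      names(out) <- fields
      for (i in seq_len(nfields)) {
        el <- mat5_read_tag(raw, off)
        if (el$type != MI_MATRIX) stop("malformed struct field element")
        sub <- raw[seq_len(el$nbytes) + el$data_off]
        out[[i]] <- mat5_parse_matrix(sub)$value
        off <- el$next_off
      }
      out
    } else if (class_code == MX_CHAR) {
      el <- mat5_read_tag(raw, off)
      codes <- mat5_decode_numeric(raw, el$data_off, el$nbytes, el$type)
      intToUtf8(codes)
    } else {
      el <- mat5_read_tag(raw, off)
      x <- mat5_decode_numeric(raw, el$data_off, el$nbytes, el$type)
      if (length(dims) == 2L && all(dims > 0L)) {
        matrix(x, nrow = dims[1L], ncol = dims[2L])
      } else if (prod(dims) == 0L) numeric(0) else array(x, dim = dims)
    }
  list(name = name, value = value)
}

#' Low-level MATLAB v5 file reader
#'
#' Reads the subset of MAT Level-5 files written by [write_mat5()] or by
#' common scientific tools for the CPSC2018 archive: little-endian files
#' holding double, char and 1x1 struct arrays, with or without per-element
#' zlib compression.
#'
#' @param path file path.
#' @return named list of variables.
#' @export
#' @keywords internal
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128L) stop("not a MAT v5 file (too short): ", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") stop("unsupported MAT file byte order marker: ", endian)
  off <- 128L
  out <- list()
  while (off < length(raw)) {
    el <- mat5_read_tag(raw, off)
    payload <- if (el$nbytes > 0L) raw[seq_len(el$nbytes) + el$data_off] else raw(0)
    if (el$type == MI_COMPRESSED) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- mat5_read_tag(payload, 0L)
      if (inner$type != MI_MATRIX) stop("unexpected compressed element type")
      payload <- payload[seq_len(inner$nbytes) + inner$data_off]
      parsed <- mat5_parse_matrix(payload)
      out[[parsed$name]] <- parsed$value
    } else if (el$type == MI_MATRIX) {
      parsed <- mat5_parse_matrix(payload)
      out[[parsed$name]] <- parsed$value
    }  # other top-level element types are skipped
    off <- el$next_off
  }
  out
}

# --- CPSC2018 dialect ------------------------------------------------------

#' Read or write a CPSC2018-style .mat ECG record
#'
#' CPSC2018 stores each record as a MATLAB struct `ECG` with fields `sex`
#' (char, `'Male'`/`'Female'`), `age` (double, possibly empty) and `data`
#' (12 x L double, mV).  Missing age or sex map to `NA`.  Lead rows are in
#' the standard order I, II, III, aVR, aVL, aVF, V1-V6.
#'
#' @param path `.mat` file path.
#' @param fs sampling rate to stamp on the record (the file itself carries
#'   none; CPSC2018 is 500 Hz).
#' @param label optional rhythm label to attach (from the manifest).
#' @return `read_cpsc_mat()`: an [ecg_record].
#' @export
read_cpsc_mat <- function(path, fs = 500, label = NA_character_) {
  vars <- read_mat5(path)
  st <- vars[["ECG"]]
  if (is.null(st)) {
    structs <- Filter(is.list, vars)
    if (length(structs) != 1L) {
      stop("no `ECG` struct found in ", path)
    }
    st <- structs[[1L]]
  }
  if (!is.list(st) || is.null(st[["data"]])) {
    stop("malformed ECG struct in ", path, ": missing field `data`")
  }
  sig <- st[["data"]]
  if (!is.matrix(sig) || !is.numeric(sig)) {
    stop("field `data` in ", path, " is not a numeric matrix")
  }
  if (nrow(sig) != 12L) {
    stop(sprintf("expected 12 leads in field `data` of %s, got %d",
                 path, nrow(sig)))
  }
  age <- st[["age"]]
  age <- if (is.null(age) || length(age) == 0L || !is.finite(age[1L]))
    NA_real_ else as.numeric(age[1L])
  sex_raw <- st[["sex"]]
  sex <- if (is.null(sex_raw) || !is.character(sex_raw) || !nzchar(sex_raw))
    NA_character_
  else switch(tolower(substr(sex_raw, 1L, 1L)),
              f = "female", m = "male", NA_character_)
  id <- sub("\\.mat$", "", basename(path))
  ecg_record(sig, fs = fs, age = age, sex = sex, label = label,
             record_id = id)
}

#' @rdname read_cpsc_mat
#' @param record an [ecg_record].
#' @export
write_cpsc_mat <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  sex <- if (is.na(record$sex)) "" else
    c(female = "Female", male = "Male")[[record$sex]]
  age <- if (is.na(record$age)) numeric(0) else record$age
  write_mat5(list(ECG = list(sex = sex, age = age, data = record$signal)),
             path)
}
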