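# Minimal reader for MATLAB level-5 MAT-files: real 2-D numeric arrays,
# plain or zlib-compressed elements, both byte orders. This covers the
# layout of the public basic-hand-movement repository (per-class
# trials x samples matrices). The HDF5-based v7.3 dialect is detected and
# rejected with a pointer to re-saving as level 5.

mi_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
                  `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

read_mi_numeric <- function(raw, type, endian) {
  n <- length(raw)
  switch(as.character(type),
    `1` = readBin(raw, "integer", n, size = 1L, signed = TRUE, endian = endian),
    `2` = readBin(raw, "integer", n, size = 1L, signed = FALSE, endian = endian),
    `3` = readBin(raw, "integer", n / 2L, size = 2L, signed = TRUE, endian = endian),
    `4` = readBin(raw, "integer", n / 2L, size = 2L, signed = FALSE, endian = endian),
    `5` = readBin(raw, "integer", n / 4L, size = 4L, endian = endian),
    `6` = readBin(raw, "integer", n / 4L, size = 4L, endian = endian),
    `7` = readBin(raw, "numeric", n / 4L, size = 4L, endian = endian),
    `9` = readBin(raw, "double", n / 8L, size = 8L, endian = endian),
    stop(sprintf("unsupported MAT data type %d", type)))
}

read_uint32 <- function(raw, off, endian) {
  b <- as.integer(raw[off + 1:4])
  if (endian == "little")
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  else
    b[4] + b[3] * 256 + b[2] * 65536 + b[1] * 16777216
}

# parse one data element starting at offset `off` (0-based) in `raw`;
# returns list(type, data = raw payload, next_off)
mat_element <- function(raw, off, endian) {
  t32 <- read_uint32(raw, off, endian)
  small_n <- t32 %/% 65536
  if (small_n > 0) {
    type <- t32 %% 65536
    data <- raw[off + 4 + seq_len(small_n)]
    list(type = type, data = data, next_off = off + 8L)
  } else {
    nb <- read_uint32(raw, off + 4L, endian)
    if (off + 8 + nb > length(raw))
      stop("corrupt MAT-file: element extends past end of file")
    data <- if (nb > 0) raw[off + 8 + seq_len(nb)] else raw(0)
    # compressed elements (type 15) are stored without tail padding
    pad <- if (t32 == 15) 0L else (8L - nb %% 8L) %% 8L
    list(type = t32, data = data, next_off = off + 8L + nb + pad)
  }
}

# decode a miMATRIX payload into a named numeric matrix (or NULL if the
# array class is not a real numeric 2-D array)
mat_matrix <- function(payload, endian) {
  off <- 0L
  flags <- mat_element(payload, off, endian); off <- flags$next_off
  fw <- read_uint32(flags$data, 0L, endian)
  cls <- fw %% 256
  complex_flag <- (fw %/% 2048) %% 2 == 1
  dims_el <- mat_element(payload, off, endian); off <- dims_el$next_off
  dims <- read_mi_numeric(dims_el$data, 5L, endian)
  name_el <- mat_element(payload, off, endian); off <- name_el$next_off
  nm <- rawToChar(name_el$data[name_el$data != as.raw(0)])
  if (!(cls %in% c(6, 7, 8, 9, 10, 11, 12, 13)) || complex_flag ||
      length(dims) != 2L)
    return(list(name = nm, value = NULL))
  real_el <- mat_element(payload, off, endian)
  vals <- read_mi_numeric(real_el$data, real_el$type, endian)
  if (length(vals) != prod(dims))
    stop(sprintf("corrupt MAT array '%s': %d values for dims %s",
                 nm, length(vals), paste(dims, collapse = "x")))
  list(name = nm, value = matrix(as.numeric(vals), nrow = dims[1]))
}

#' Read numeric arrays from a MATLAB level-5 MAT-file
#'
#' Supports real 2-D numeric arrays (double, single, integer classes) in
#' plain or zlib-compressed data elements. Other array classes are skipped
#' with a warning. v7.3 (HDF5) files are rejected with a descriptive error.
#'
#' @param path path to the `.mat` file.
#' @return Named list of numeric matrices.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop(sprintf("MAT-file not found: %s", path))
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) >= 8 && identical(raw[2:4], charToRaw("HDF")))
    stop(sprintf(paste0("'%s' is a v7.3 (HDF5) MAT-file; re-save it with ",
                        "MATLAB's '-v7' flag or scipy.io.savemat"), path))
  if (length(raw) < 136)
    stop(sprintf("'%s' is too short to be a level-5 MAT-file", path))
  magic <- rawToChar(raw[127:128])
  endian <- if (magic == "IM") "little" else if (magic == "MI") "big" else
    stop(sprintf("'%s' has no level-5 MAT-file endian marker", path))
  out <- list()
  off <- 128L
  while (off + 8 <= length(raw)) {
    el <- mat_element(raw, off, endian)
    off <- el$next_off
    if (el$type == 15) {  # zlib-compressed element
      inner <- memDecompress(el$data, type = "gzip")
      el <- mat_element(inner, 0L, endian)
    }
    if (el$type == 14) {
      m <- mat_matrix(el$data, endian)
      if (is.null(m$value))
        warning(sprintf("skipping non-numeric MAT variable '%s'", m$name))
      else out[[m$name]] <- m$value
    }
  }
  out
}

#' Default variable-name table of the basic-hand-movement repository
#'
#' Maps each grasp class code to the variable prefix used in the public
#' MAT-files; channels are stored as `<prefix>_ch1` / `<prefix>_ch2`
#' matrices with one trial per row.
#'
#' @return Named character vector (names = class codes C,H,L,P,S,T).
#' @export
default_mat_names <- function() {
  c(C = "cyl", H = "hook", L = "lat", P = "palm", S = "spher", T = "tip")
}

#' Load the public basic-hand-movement sEMG dataset
#'
#' Reads every `.mat` file in `path` (sorted by name) and builds one
#' [signal_record()] per trial row. Record order is deterministic: class
#' order C, H, L, P, S, T, then file, then trial row. DB1 holds 900 trials
#' of 5 subjects (30 per class per subject, 3000 samples per channel at
#' 500 Hz); DB2 holds 1800 trials of one subject over three days.
#'
#' @param path directory containing the MAT-files.
#' @param dataset_id "DB1" or "DB2" (stored as the dataset name).
#' @param fs sampling rate in Hz (500 for the public data).
#' @param name_table class-code to variable-prefix map
#'   (default [default_mat_names()]).
#' @return A [grasp_dataset()].
#' @export
load_basic_hand_movements <- function(path, dataset_id = c("DB1", "DB2"),
                                      fs = 500,
                                      name_table = default_mat_names()) {
  dataset_id <- match.arg(dataset_id)
  if (!dir.exists(path)) stop(sprintf("directory not found: %s", path))
  files <- sort(list.files(path, pattern = "\\.mat$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no .mat files in %s", path))
  mats <- lapply(files, read_mat)
  classes <- unname(grasp_classes())
  if (!all(classes %in% names(name_table)))
    stop("name_table must map every class code C,H,L,P,S,T")
  records <- list()
  for (cls in classes) {
    prefix <- name_table[[cls]]
    v1 <- paste0(prefix, "_ch1")
    v2 <- paste0(prefix, "_ch2")
    for (fi in seq_along(mats)) {
      m <- mats[[fi]]
      if (is.null(m[[v1]]) || is.null(m[[v2]]))
        stop(sprintf("file '%s' lacks variables '%s'/'%s'; pass a name_table matching this dialect",
                     basename(files[fi]), v1, v2))
      if (!identical(dim(m[[v1]]), dim(m[[v2]])))
        stop(sprintf("channel matrices '%s' and '%s' in '%s' differ in shape",
                     v1, v2, basename(files[fi])))
      for (tr in seq_len(nrow(m[[v1]]))) {
        records[[length(records) + 1L]] <-
          signal_record(m[[v1]][tr, ], m[[v2]][tr, ], fs = fs, label = cls,
                        meta = list(file = basename(files[fi]), trial = tr))
      }
    }
  }
  grasp_dataset(records, name = dataset_id)
}
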