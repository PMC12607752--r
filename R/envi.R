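#' Write a hyperspectral cube as an ENVI .hdr/.dat pair
#'
#' The ENVI format stores the cube as flat binary (`.dat`) described by a
#' plain-text header (`.hdr`). Supported interleaves: `bil` (band
#' interleaved by line, the default), `bip` and `bsq`; supported data types
#' are ENVI code 4 (32-bit float, the camera's native precision) and 5
#' (64-bit float, lossless for R doubles). Byte order is little-endian.
#'
#' @param cube numeric h x w x bands array.
#' @param wavelengths band-centre wavelengths in nm, length = bands.
#' @param path base path; `.hdr` and `.dat` extensions are appended.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data type code, 4 (float32) or 5 (float64).
#' @return invisibly, the paths written (named `hdr`, `dat`).
#' @export
write_envi <- function(cube, wavelengths, path,
                       interleave = c("bil", "bip", "bsq"),
                       data_type = 4L) {
  interleave <- match.arg(interleave)
  if (length(dim(cube)) != 3L) stop("cube must be a 3-dimensional array")
  d <- dim(cube)
  if (length(wavelengths) != d[3])
    stop("wavelengths length (", length(wavelengths),
         ") must equal band count (", d[3], ")")
  if (!data_type %in% c(4L, 5L)) stop("data_type must be 4 (float32) or 5 (float64)")

  # ENVI axis order: lines = rows, samples = columns.
  # BSQ: band-major [sample, line, band]; BIL: [sample, band, line];
  # BIP: [band, sample, line]. Fastest-varying axis first.
  x <- switch(interleave,
    bsq = aperm(cube, c(2, 1, 3)),
    bil = aperm(cube, c(2, 3, 1)),
    bip = aperm(cube, c(3, 2, 1)))

  hdr_path <- paste0(path, ".hdr")
  dat_path <- paste0(path, ".dat")
  hdr <- c(
    "ENVI",
    "description = { synthetic hyperspectral cube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength units = nm"),
    paste0("wavelength = {\n ",
           paste(format(wavelengths, digits = 12, trim = TRUE), collapse = ", "),
           " }")
  )
  writeLines(hdr, hdr_path)
  con <- file(dat_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  invisible(c(hdr = hdr_path, dat = dat_path))
}

# Parse an ENVI header into a named list; values spanning {...} blocks are
# collapsed first.
parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ENVI")
    stop("parse error in field 'magic': header does not start with 'ENVI'")
  fields <- list()
  # Stateful scan: accumulate lines until braces balance, then split on '='.
  raw_lines <- lines[-1]
  buf <- character(0)
  open <- 0L
  for (ln in raw_lines) {
    buf <- c(buf, ln)
    open <- open + lengths(regmatches(ln, gregexpr("{", ln, fixed = TRUE))) -
      lengths(regmatches(ln, gregexpr("}", ln, fixed = TRUE)))
    if (open > 0L) next
    entry <- paste(buf, collapse = " ")
    buf <- character(0)
    if (!nzchar(trimws(entry))) next
    m <- regexpr("=", entry, fixed = TRUE)
    if (m == -1L) stop("parse error in field '", trimws(entry),
                       "': expected 'key = value'")
    key <- tolower(trimws(substr(entry, 1L, m - 1L)))
    val <- trimws(substr(entry, m + 1L, nchar(entry)))
    fields[[key]] <- val
  }
  if (open != 0L) stop("parse error in field 'wavelength': unbalanced braces")
  fields
}

envi_int_field <- function(fields, key) {
  if (is.null(fields[[key]])) stop("parse error in field '", key, "': missing")
  v <- suppressWarnings(as.integer(fields[[key]]))
  if (is.na(v)) stop("parse error in field '", key, "': not an integer")
  v
}

#' Read an ENVI .hdr/.dat pair
#'
#' Inverse of [write_envi()]: accepts `bil`, `bip` and `bsq` interleaves and
#' data types 4/5. The header's `bands` entry must agree with the length of
#' its wavelength list; a mismatch raises a parse error naming the field.
#'
#' @param path base path (without extension) or the `.hdr` path itself.
#' @return list with `cube` (h x w x bands array) and `wavelengths`.
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  dat_path <- sub("\\.hdr$", ".dat", hdr_path)
  if (!file.exists(hdr_path)) stop("header not found: ", hdr_path)
  if (!file.exists(dat_path)) stop("data file not found: ", dat_path)
  f <- parse_envi_header(hdr_path)

  samples <- envi_int_field(f, "samples")
  lines_n <- envi_int_field(f, "lines")
  bands <- envi_int_field(f, "bands")
  data_type <- envi_int_field(f, "data type")
  if (!data_type %in% c(4L, 5L))
    stop("parse error in field 'data type': unsupported code ", data_type)
  interleave <- tolower(f[["interleave"]])
  if (is.null(interleave) || !interleave %in% c("bil", "bip", "bsq"))
    stop("parse error in field 'interleave': must be bil, bip or bsq")
  byte_order <- envi_int_field(f, "byte order")

  wavelengths <- NULL
  if (!is.null(f[["wavelength"]])) {
    wl_txt <- gsub("[{}]", "", f[["wavelength"]])
    wavelengths <- as.numeric(strsplit(wl_txt, ",")[[1]])
    if (anyNA(wavelengths))
      stop("parse error in field 'wavelength': non-numeric entry")
    if (length(wavelengths) != bands)
      stop("parse error in field 'wavelength': ", length(wavelengths),
           " wavelengths but bands = ", bands)
  }

  n <- samples * lines_n * bands
  con <- file(dat_path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n,
               size = if (data_type == 4L) 4L else 8L,
               endian = if (byte_order == 0L) "little" else "big")
  if (length(x) != n)
    stop("parse error in field 'samples/lines/bands': data file holds ",
         length(x), " values, header promises ", n)

  cube <- switch(interleave,
    bsq = aperm(array(x, c(samples, lines_n, bands)), c(2, 1, 3)),
    bil = aperm(array(x, c(samples, bands, lines_n)), c(3, 1, 2)),
    bip = aperm(array(x, c(bands, samples, lines_n)), c(3, 2, 1)))
  list(cube = cube, wavelengths = wavelengths)
}
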