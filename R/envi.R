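# Minimal ENVI raster I/O: enough of the format (BSQ/BIL/BIP interleaves,
# wavelength list in the header) to round-trip the cubes this pipeline
# produces and consumes. Data type 4 (32-bit float) or 5 (64-bit float),
# little endian.

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<path>` (binary, band-sequential by default) and `<path>.hdr`
#' with the wavelength list, so the cube can be read back with
#' [read_envi()] or by standard ENVI-aware software.
#'
#' @param values rows x cols x bands numeric array.
#' @param wavelengths numeric vector of band centers in nm.
#' @param path output path for the binary file (header gets `.hdr` appended).
#' @param interleave one of "bsq", "bil", "bip".
#' @return `path`, invisibly.
#' @export
write_envi <- function(values, wavelengths, path, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  stopifnot(is.array(values), length(dim(values)) == 3L,
            dim(values)[3] == length(wavelengths))
  d <- dim(values) # rows (lines), cols (samples), bands
  hdr <- c(
    "ENVI",
    "description = {grainspec hyperspectral cube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    paste0("interleave = ", interleave),
    "byte order = 0",
    "wavelength units = nm",
    paste0("wavelength = {", paste(format(wavelengths, trim = TRUE), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # array is stored [row, col, band]; ENVI expects pixel-major per interleave
  x <- switch(interleave,
    bsq = aperm(values, c(2L, 1L, 3L)),          # sample, line, band
    bil = aperm(values, c(2L, 3L, 1L)),          # sample, band, line
    bip = aperm(values, c(3L, 2L, 1L))           # band, sample, line
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get1 <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^", key, "\\s*=\\s*[^\\n{]+"), txt, perl = TRUE))
    if (!length(m)) return(NULL)
    trimws(sub(paste0("(?i)^", key, "\\s*="), "", m, perl = TRUE))
  }
  getblock <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?si)", key, "\\s*=\\s*\\{[^}]*\\}"), txt, perl = TRUE))
    if (!length(m)) return(NULL)
    inner <- sub("^[^{]*\\{", "", m)
    inner <- sub("\\}\\s*$", "", inner)
    trimws(strsplit(inner, ",")[[1]])
  }
  list(
    samples = as.integer(get1("samples")),
    lines = as.integer(get1("lines")),
    bands = as.integer(get1("bands")),
    data_type = as.integer(get1("data type")),
    interleave = tolower(get1("interleave")),
    byte_order = as.integer(get1("byte order") %||% "0"),
    offset = as.integer(get1("header offset") %||% "0"),
    wavelength = suppressWarnings(as.numeric(getblock("wavelength")))
  )
}

#' Read an ENVI-format hyperspectral cube
#'
#' @param path path to the binary file; the header is looked up at
#'   `<path>.hdr` or, failing that, by swapping the extension.
#' @return list with `values` (rows x cols x bands array) and `wavelengths`.
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) hdr_path <- sub("\\.[^.]*$", ".hdr", path)
  if (!file.exists(hdr_path)) gs_stop("no ENVI header found for ", path, class = "io_error")
  h <- parse_envi_header(hdr_path)
  if (any(vapply(h[c("samples", "lines", "bands", "data_type")],
                 function(x) length(x) != 1L || is.na(x), logical(1))))
    gs_stop("malformed ENVI header at ", hdr_path, class = "io_error")
  if (!h$data_type %in% c(4L, 5L))
    gs_stop("unsupported ENVI data type ", h$data_type, class = "io_error")
  size <- if (h$data_type == 4L) 4L else 8L
  endian <- if (h$byte_order == 1L) "big" else "little"
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb")
  on.exit(close(con))
  if (h$offset > 0) readBin(con, "raw", n = h$offset)
  x <- readBin(con, "double", n = n, size = size, endian = endian)
  dims <- switch(h$interleave,
    bsq = c(h$samples, h$lines, h$bands),
    bil = c(h$samples, h$bands, h$lines),
    bip = c(h$bands, h$samples, h$lines),
    gs_stop("unknown interleave ", h$interleave, class = "io_error")
  )
  dim(x) <- dims
  values <- switch(h$interleave,
    bsq = aperm(x, c(2L, 1L, 3L)),
    bil = aperm(x, c(3L, 1L, 2L)),
    bip = aperm(x, c(3L, 2L, 1L))
  )
  list(values = values, wavelengths = h$wavelength)
}
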