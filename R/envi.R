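#' Hyperspectral intensity cube
#'
#' Container for a hyperspectral image: a numeric array `[rows, cols, bands]`
#' of recorded intensity (or reflectance) with its wavelength grid. `rows`
#' index the scan direction (y), `cols` the cross-track slit position (x).
#'
#' @param data numeric array `[rows, cols, bands]`
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, `length(wavelengths) == dim(data)[3]`
#' @param saturated optional logical matrix `[rows, cols]` flagging
#'   saturated/invalid pixels; defaults to all-`FALSE`
#' @param meta named list of provenance fields (free-form)
#' @return an object of class `spectral_cube`
#' @export
spectral_cube <- function(data, wavelengths, saturated = NULL, meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3])
    stop("wavelength grid length does not match band count")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (is.null(saturated)) {
    saturated <- matrix(FALSE, dim(data)[1], dim(data)[2])
  }
  stopifnot(identical(dim(saturated), dim(data)[1:2]))
  structure(list(data = data, wavelengths = wavelengths,
                 saturated = saturated, meta = meta),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  if (any(x$saturated)) cat(sprintf("  %d saturated pixels\n", sum(x$saturated)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

# Map ENVI data type codes to R read/write parameters.
.envi_types <- list(
  `4` = list(what = "numeric", size = 4L),
  `5` = list(what = "numeric", size = 8L)
)

#' Write a cube as an ENVI header + band-sequential binary
#'
#' Produces `<path>.hdr` (ASCII, with the `wavelength` block populated) and
#' `<path>.bsq` (raw little-endian floats, band-sequential interleave).
#'
#' @param cube a [spectral_cube]
#' @param path output path without extension
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64, default;
#'   preserves bit-exact reruns)
#' @return `path`, invisibly
#' @export
write_envi <- function(cube, path, data_type = 5) {
  stopifnot(inherits(cube, "spectral_cube"))
  dt <- .envi_types[[as.character(data_type)]]
  if (is.null(dt)) stop("unsupported ENVI data type: ", data_type)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {uhicoral spectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = nm",
    paste0("wavelength = {", paste(format(cube$wavelengths, digits = 10),
                                   collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".bsq"), "wb")
  on.exit(close(con))
  # BSQ: full spatial plane per band; R arrays are column-major so aperm
  # puts cols (samples) fastest, then rows (lines), then bands.
  writeBin(as.numeric(aperm(cube$data, c(2, 1, 3))), con,
           size = dt$size, endian = "little")
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key, "\\s*=\\s*(\\S+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) stop("ENVI header missing field: ", key)
    m[2]
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], "[,\n]")[[1]])
  }
  list(samples = as.integer(get_scalar("samples")),
       lines = as.integer(get_scalar("lines")),
       bands = as.integer(get_scalar("bands")),
       data_type = as.integer(get_scalar("data type")),
       interleave = tolower(get_scalar("interleave")),
       wavelength = get_block("wavelength"))
}

#' Read an ENVI header + binary cube
#'
#' Supports band-sequential (bsq) interleave with float32/float64 samples,
#' the format written by [write_envi()].
#'
#' @param path path without extension, or to the `.hdr` file
#' @return a [spectral_cube]
#' @export
read_envi <- function(path) {
  path <- sub("\\.(hdr|bsq)$", "", path)
  h <- .parse_envi_header(paste0(path, ".hdr"))
  if (h$interleave != "bsq") stop("only bsq interleave is supported")
  dt <- .envi_types[[as.character(h$data_type)]]
  if (is.null(dt)) stop("unsupported ENVI data type: ", h$data_type)
  n <- h$samples * h$lines * h$bands
  con <- file(paste0(path, ".bsq"), "rb")
  on.exit(close(con))
  raw <- readBin(con, dt$what, n = n, size = dt$size, endian = "little")
  if (length(raw) != n) stop("binary file shorter than header promises")
  arr <- aperm(array(raw, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3))
  wl <- if (is.null(h$wavelength)) seq_len(h$bands) else h$wavelength
  spectral_cube(arr, wl, meta = list(source = paste0(path, ".bsq")))
}
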