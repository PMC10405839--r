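# Signal container ----------------------------------------------------------
#
# Single-file binary container: an 8-byte magic, a 4-byte little-endian
# header length, a JSON header describing geometry/config/array layout, then
# the raw little-endian float64 payload.  Doubles round-trip bit-exactly.

.sig_magic <- "RINGSIG1"

#' Write a signal set to disk
#'
#' Stores a [signal_set()] losslessly in the package's self-describing binary
#' container (JSON header + IEEE-754 float64 payload).  `read_signals()`
#' reproduces the array bit-exactly along with all configuration and
#' geometry fields.
#'
#' @param signals a [signal_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  stopifnot(inherits(signals, "signal_set"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  header <- list(
    mode = signals$mode,
    dim = dim(signals$data),
    wavelength = signals$wavelength,
    tx_indices = signals$tx_indices,
    config = unclass(signals$config),
    geometry = list(n_elements = signals$geometry$n_elements,
                    radius = signals$geometry$radius)
  )
  hj <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                                   null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.sig_magic), con)
  writeBin(length(hj), con, size = 4L, endian = "little")
  writeBin(hj, con)
  writeBin(as.vector(signals$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a signal set written by [write_signals()]
#'
#' @param path file path.
#' @return a [signal_set()].
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, .sig_magic))
    stop("not a ringtomo signal container: ", path, call. = FALSE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  for (f in c("mode", "dim", "config", "geometry"))
    if (is.null(header[[f]]))
      stop("corrupt signal container: missing '", f, "'", call. = FALSE)
  cf <- header$config
  for (f in c("sampling_rate", "n_samples", "center_frequency",
              "fractional_bandwidth", "wavelengths", "water_sos",
              "acquisition_delay"))
    if (is.null(cf[[f]]))
      stop("corrupt signal container: missing '", f, "'", call. = FALSE)
  n <- prod(header$dim)
  x <- readBin(con, "numeric", n, size = 8L, endian = "little")
  if (length(x) != n)
    stop("corrupt signal container: truncated payload", call. = FALSE)
  config <- acquisition_config(cf$sampling_rate, cf$n_samples,
                               cf$center_frequency, cf$fractional_bandwidth,
                               cf$wavelengths, cf$water_sos,
                               cf$acquisition_delay)
  geom <- make_ring_geometry(header$geometry$n_elements,
                             header$geometry$radius)
  signal_set(header$mode, array(x, dim = header$dim), config, geom,
             tx_indices = header$tx_indices,
             wavelength = if (is.null(header$wavelength)) NA_real_
                          else header$wavelength)
}

# Image export ---------------------------------------------------------------

# Minimal single-strip uncompressed 32-bit IEEE-float TIFF writer (the
# installed TIFF bindings clamp float writes to [0, 1]; reading arbitrary
# float TIFFs works fine, so only the writer is in-house).
write_float_tiff <- function(pixels, path) {
  h <- nrow(pixels); w <- ncol(pixels)
  data <- as.vector(t(pixels)) # row-major
  n_tags <- 9L
  # layout: 8-byte header | IFD | payload
  ifd_offset <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  data_offset <- ifd_offset + ifd_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                       # little-endian
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_offset, con, size = 4L, endian = "little")
  writeBin(n_tags, con, size = 2L, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
  tag(256, 4, 1, w)                 # ImageWidth
  tag(257, 4, 1, h)                 # ImageLength
  tag(258, 3, 1, 32)                # BitsPerSample
  tag(259, 3, 1, 1)                 # Compression: none
  tag(262, 3, 1, 1)                 # Photometric: BlackIsZero
  tag(273, 4, 1, data_offset)       # StripOffsets
  tag(278, 4, 1, h)                 # RowsPerStrip
  tag(279, 4, 1, 4 * w * h)         # StripByteCounts
  tag(339, 3, 1, 3)                 # SampleFormat: IEEE float
  writeBin(0L, con, size = 4L, endian = "little")  # next IFD: none
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Export a reconstructed image to TIFF + CSV sidecar
#'
#' Writes a 32-bit float TIFF (NaN background preserved) and a CSV sidecar
#' `<path>.meta.csv` recording mode, units, pixel size and origin.
#'
#' @param image a [recon_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
export_image <- function(image, path) {
  stopifnot(inherits(image, "recon_image"))
  if (!is.matrix(image$pixels))
    stop("image pixels must be a 2D matrix", call. = FALSE)
  write_float_tiff(image$pixels, path)
  meta <- data.frame(key = c("mode", "units", "pixel_size_mm",
                             "origin_x_mm", "origin_y_mm"),
                     value = c(image$mode, image$units,
                               format(image$pixel_size, digits = 17),
                               format(image$origin[1], digits = 17),
                               format(image$origin[2], digits = 17)))
  write.csv(meta, paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}

#' Re-import an image written by [export_image()]
#'
#' @param path TIFF path (sidecar `<path>.meta.csv` must exist).
#' @return a [recon_image()].
#' @export
import_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  side <- paste0(path, ".meta.csv")
  if (!file.exists(side)) stop("missing sidecar: ", side, call. = FALSE)
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3) px <- px[, , 1]
  meta <- read.csv(side, stringsAsFactors = FALSE)
  val <- setNames(meta$value, meta$key)
  recon_image(px, pixel_size = as.numeric(val[["pixel_size_mm"]]),
              origin = c(as.numeric(val[["origin_x_mm"]]),
                         as.numeric(val[["origin_y_mm"]])),
              mode = val[["mode"]], units = val[["units"]])
}

# Config files ---------------------------------------------------------------

#' Read / write an acquisition configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns an [acquisition_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  acquisition_config(
    sampling_rate = y$sampling_rate, n_samples = y$n_samples,
    center_frequency = y$center_frequency,
    fractional_bandwidth = y$fractional_bandwidth,
    wavelengths = y$wavelengths, water_sos = y$water_sos,
    acquisition_delay = y$acquisition_delay
  )
}

#' @rdname read_config
#' @param config an [acquisition_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "acq_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
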