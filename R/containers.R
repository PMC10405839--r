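#' Acquisition configuration
#'
#' Bundles the acquisition parameters shared by all modes.  Defaults follow
#' the full-scale system: 40 MS/s sampling, 2030 samples per record, 5 MHz
#' centre frequency with 60% fractional bandwidth, and 11 optical
#' wavelengths from 740 to 940 nm in 20 nm steps.
#'
#' @param sampling_rate samples per second.
#' @param n_samples samples per record.
#' @param center_frequency array centre frequency, Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth (dimensionless).
#' @param wavelengths optical wavelengths in nm, ascending.
#' @param water_sos speed of sound of the coupling water, m/s.
#' @param acquisition_delay time of sample 1, s.
#' @return An object of class `acq_config`.
#' @export
acquisition_config <- function(sampling_rate = 40e6, n_samples = 2030,
                               center_frequency = 5e6,
                               fractional_bandwidth = 0.6,
                               wavelengths = seq(740, 940, by = 20),
                               water_sos = 1523,
                               acquisition_delay = 0) {
  if (n_samples <= 0 || n_samples != round(n_samples))
    stop("n_samples must be a positive integer", call. = FALSE)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly ascending", call. = FALSE)
  upper_edge <- center_frequency * (1 + fractional_bandwidth / 2)
  if (sampling_rate <= 2 * upper_edge)
    stop("sampling_rate must exceed twice the upper band edge (",
         format(2 * upper_edge), " Hz)", call. = FALSE)
  structure(
    list(sampling_rate = sampling_rate, n_samples = as.integer(n_samples),
         center_frequency = center_frequency,
         fractional_bandwidth = fractional_bandwidth,
         wavelengths = as.numeric(wavelengths), water_sos = water_sos,
         acquisition_delay = acquisition_delay),
    class = "acq_config"
  )
}

# Gaussian envelope width (s) of the band-limited transmit/receive pulse:
# a Gaussian spectrum centred at fc whose FWHM equals the -6 dB fractional
# bandwidth gives sigma_t = 1/(2*pi*sigma_f).
pulse_sigma <- function(config) {
  sigma_f <- config$fractional_bandwidth * config$center_frequency /
    (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

# Effective pulse duration (s): +-3 sigma support of the envelope.
pulse_duration <- function(config) 6 * pulse_sigma(config)

#' Evaluate the band-limited transmit pulse
#'
#' The short excitation filtered to the array band is modelled as a
#' zero-phase (cosine) carrier at the centre frequency under a Gaussian
#' envelope whose spectral FWHM equals the fractional bandwidth.  `t = 0`
#' is the wavelet maximum, i.e. the nominal arrival time.
#'
#' @param t times in seconds (vector).
#' @param config an [acquisition_config()].
#' @return pulse amplitude at `t` (a.u.).
#' @export
transmit_pulse <- function(t, config) {
  .cpp_pulse(t, config$center_frequency, pulse_sigma(config))
}

#' Time-resolved signal container
#'
#' Holds one acquisition: `data` is a 3D array `[frame_or_tx, element,
#' sample]`.  For `mode = "sta"` the first axis must equal the number of ring
#' elements (one transmission per element at full scale) unless a transmit
#' subset is recorded in `tx_indices`.
#'
#' @param mode `"msot"` or `"sta"`.
#' @param data numeric 3D array `[frame_or_tx, element, sample]`.
#' @param config an [acquisition_config()].
#' @param geometry a [make_ring_geometry()] object.
#' @param tx_indices for STA subsets: 1-based element index of each slice on
#'   the first axis. Default `NULL` means the full ring in order.
#' @param wavelength optical wavelength (nm) of an MSOT frame set, or `NA`.
#' @return An object of class `signal_set`.
#' @export
signal_set <- function(mode, data, config, geometry, tx_indices = NULL,
                       wavelength = NA_real_) {
  mode <- match.arg(mode, c("msot", "sta"))
  stopifnot(is.array(data), length(dim(data)) == 3,
            inherits(config, "acq_config"),
            inherits(geometry, "ring_geometry"))
  d <- dim(data)
  if (d[3] != config$n_samples)
    stop("sample axis (", d[3], ") does not match config n_samples (",
         config$n_samples, ")", call. = FALSE)
  if (d[2] != geometry$n_elements)
    stop("element axis does not match geometry", call. = FALSE)
  if (mode == "sta") {
    if (is.null(tx_indices)) {
      if (d[1] != geometry$n_elements)
        stop("sta data must have one transmission per element ",
             "(or provide tx_indices)", call. = FALSE)
      tx_indices <- seq_len(geometry$n_elements)
    } else if (length(tx_indices) != d[1]) {
      stop("tx_indices length must match the first data axis", call. = FALSE)
    }
  }
  structure(
    list(mode = mode, data = data, config = config, geometry = geometry,
         tx_indices = if (mode == "sta") as.integer(tx_indices) else NULL,
         wavelength = wavelength),
    class = "signal_set"
  )
}

#' @export
print.signal_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<signal_set> mode=%s, %d x %d x %d [frame/tx, element, sample]\n",
              x$mode, d[1], d[2], d[3]))
  invisible(x)
}

#' Reconstructed image container
#'
#' A 2D image with physical pixel geometry. `origin` is the physical (x, y)
#' coordinate (mm) of the centre of pixel `[1, 1]`; pixel `[i, j]` sits at
#' `origin + ((j-1)*pixel_size, (i-1)*pixel_size)`.
#'
#' @param pixels numeric matrix (rows = y, cols = x).
#' @param pixel_size pixel edge, mm.
#' @param origin length-2 numeric, mm.
#' @param mode one of `"msot"`, `"ruct"`, `"sos"`, `"chromophore"`.
#' @param units `"a.u."` or `"m/s"`.
#' @return An object of class `recon_image`.
#' @export
recon_image <- function(pixels, pixel_size, origin = c(0, 0),
                        mode = c("msot", "ruct", "sos", "chromophore"),
                        units = c("a.u.", "m/s")) {
  mode <- match.arg(mode)
  units <- match.arg(units)
  stopifnot(is.matrix(pixels), length(origin) == 2)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  if (mode == "sos") {
    fin <- pixels[is.finite(pixels)]
    if (length(fin) && (min(fin) < 1300 || max(fin) > 1700))
      stop("sos image values must lie in [1300, 1700] m/s", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         origin = as.numeric(origin), mode = mode, units = units),
    class = "recon_image"
  )
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %s [%s], %d x %d px @ %.3g mm\n", x$mode,
              x$units, nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' Square image grid centred on the ring axis
#'
#' @param n pixels per side.
#' @param pixel_size pixel edge, mm.
#' @param center grid centre (mm), default the ring origin.
#' @return list with `nx`, `ny`, `pixel_size`, `origin` (centre of pixel
#'   `[1, 1]`), class `image_grid`.
#' @export
image_grid <- function(n, pixel_size, center = c(0, 0)) {
  stopifnot(n >= 2, pixel_size > 0)
  half <- (n - 1) / 2 * pixel_size
  structure(
    list(nx = as.integer(n), ny = as.integer(n), pixel_size = pixel_size,
         origin = c(center[1] - half, center[2] - half)),
    class = "image_grid"
  )
}

# x and y coordinate vectors of grid pixel centres
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size,
       y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$pixel_size)
}
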