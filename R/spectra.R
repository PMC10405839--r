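#' Chromophore absorption spectra library
#'
#' Container for tabulated relative absorption spectra of the four
#' chromophores used in unmixing, in the fixed order (Hb, HbO2, melanin,
#' lipid).  Values are relative absorption coefficients (a.u./mm) on a nm
#' wavelength grid.
#'
#' @param wavelengths nm grid, strictly ascending.
#' @param absorption numeric matrix, one column per chromophore, columns
#'   named `hb`, `hbo2`, `melanin`, `lipid`; all values > 0.
#' @return object of class `spectra_library`.
#' @export
spectra_library <- function(wavelengths, absorption) {
  stopifnot(is.matrix(absorption),
            identical(colnames(absorption), c("hb", "hbo2", "melanin", "lipid")),
            nrow(absorption) == length(wavelengths))
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly ascending", call. = FALSE)
  if (any(absorption <= 0))
    stop("all absorption values must be positive", call. = FALSE)
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorption = absorption),
            class = "spectra_library")
}

#' Packaged chromophore spectra
#'
#' Loads the packaged reference spectra for Hb, HbO2, melanin and lipid on a
#' 1 nm grid over 700-1000 nm.  These are synthetic analytic approximations
#' of the literature near-infrared shapes (stored in
#' `extdata/chromophore_spectra_synthetic_v1.csv`): Hb exceeds HbO2 at
#' 740 nm and the order reverses by 900 nm (the NIR crossing), melanin
#' decreases monotonically with wavelength, and lipid has its absorption
#' maximum at 920 nm over the acquisition band.
#'
#' @return a [spectra_library()].
#' @examples
#' sp <- default_spectra()
#' wl <- seq(740, 940, 20)
#' wl[which.max(resample_spectra(sp, wl)$absorption[, "lipid"])]  # 920
#' @export
default_spectra <- function() {
  path <- system.file("extdata", "chromophore_spectra_synthetic_v1.csv",
                      package = "ringtomo", mustWork = TRUE)
  tab <- read.csv(path)
  m <- as.matrix(tab[, c("hb", "hbo2", "melanin", "lipid")])
  spectra_library(tab$wavelength_nm, m)
}

#' Resample a spectra library to a new wavelength grid
#'
#' Linear interpolation of each chromophore spectrum; the target grid must
#' lie within the library support.
#'
#' @param library a [spectra_library()].
#' @param wavelengths target nm grid.
#' @return a [spectra_library()] on the new grid.
#' @export
resample_spectra <- function(library, wavelengths) {
  stopifnot(inherits(library, "spectra_library"))
  if (min(wavelengths) < min(library$wavelengths) ||
      max(wavelengths) > max(library$wavelengths))
    stop("requested wavelengths outside spectra support [",
         min(library$wavelengths), ", ", max(library$wavelengths), "] nm",
         call. = FALSE)
  m <- vapply(colnames(library$absorption), function(ch) {
    approx(library$wavelengths, library$absorption[, ch],
           xout = wavelengths)$y
  }, numeric(length(wavelengths)))
  m <- matrix(m, nrow = length(wavelengths),
              dimnames = list(NULL, colnames(library$absorption)))
  spectra_library(wavelengths, m)
}

#' Spectra matrix on a wavelength grid
#'
#' The (n_wavelengths x 4) design matrix used by the linear unmixing solver.
#'
#' @inheritParams resample_spectra
#' @return numeric matrix with columns `hb`, `hbo2`, `melanin`, `lipid`.
#' @export
spectra_matrix <- function(library, wavelengths) {
  resample_spectra(library, wavelengths)$absorption
}
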