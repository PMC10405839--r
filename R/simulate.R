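# Forward acoustic simulation of the two acquisition modes.  Both use
# straight-ray kinematics, matching the inversion's path model, so analytic
# time-of-flight oracles are exact.

# Modified-Bessel disc fluence model shared by the forward simulation and
# the fluence correction: Phi(x) = I0(mu_eff * rho) / I0(mu_eff * R_eff)
# with rho the distance from the body-mask centroid and R_eff the radius of
# the equal-area disc.  Phi = 1 at the illuminated rim, < 1 in depth.
fluence_map <- function(body_mask, grid, mu_eff) {
  stopifnot(mu_eff > 0)
  if (sum(body_mask) < 10)
    stop("degenerate body mask (fewer than 10 pixels)", call. = FALSE)
  ax <- grid_axes(grid)
  idx <- which(body_mask, arr.ind = TRUE)
  cx <- mean(ax$x[idx[, 2]])
  cy <- mean(ax$y[idx[, 1]])
  R <- sqrt(sum(body_mask) * grid$pixel_size^2 / pi)
  X <- outer(rep(1, grid$ny), ax$x) - cx
  Y <- outer(ax$y, rep(1, grid$nx)) - cy
  rho <- pmin(sqrt(X^2 + Y^2), R)
  besselI(mu_eff * rho, 0) / besselI(mu_eff * R, 0)
}

# Initial pressure maps per wavelength: p0 = mu_a(x, lambda) * Phi(x); the
# Grueneisen coefficient and laser pulse energy are folded into the
# arbitrary-unit scale.
initial_pressure <- function(phantom, wavelengths, spectra, mu_eff) {
  A <- spectra_matrix(spectra, wavelengths)
  phi <- fluence_map(phantom$body_mask, phantom$grid, mu_eff)
  lapply(seq_along(wavelengths), function(w) {
    mua <- A[w, "hb"] * phantom$concentration$hb +
      A[w, "hbo2"] * phantom$concentration$hbo2 +
      A[w, "melanin"] * phantom$concentration$melanin +
      A[w, "lipid"] * phantom$concentration$lipid
    mua * phi
  })
}

shift_matrix <- function(m, di, dj) {
  out <- matrix(0, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di
  sj <- seq_len(ncol(m)) - dj
  oki <- si >= 1 & si <= nrow(m)
  okj <- sj >= 1 & sj <= ncol(m)
  out[which(oki), which(okj)] <- m[si[oki], sj[okj]]
  out
}

# Zero-phase band filter approximating the array's receive response,
# applied trace-wise to a (n x samples) matrix.
band_filter_traces <- function(m, fs, low, high) {
  ny <- fs / 2
  bf <- signal::butter(2, c(low, high) / ny, type = "pass")
  t(apply(m, 1, function(tr) signal::filtfilt(bf, tr)))
}

#' Simulate a multispectral optoacoustic acquisition
#'
#' Forward model: per wavelength the initial pressure is
#' `p0 = mu_a(x, lambda) * Phi(x)` with `mu_a` from the phantom
#' concentration maps times the chromophore spectra and `Phi` the
#' modified-Bessel disc fluence model (the same model used by
#' [correct_fluence()]).  Each element's time trace is the circular-arc
#' (2D spherical-mean) projection of `p0` at radius `c t`, convolved with
#' the array band response; white Gaussian noise of sd `noise_sd` is added.
#' A fraction `motion_fraction` of the repeated frames is corrupted by a
#' rigid phantom shift of at least 2 pixels to exercise motion rejection;
#' the corrupted frame indices are returned as ground truth.
#'
#' @param phantom a [generate_phantom()] phantom.
#' @param geometry a [make_ring_geometry()].
#' @param config an [acquisition_config()]; `config$wavelengths` are the
#'   simulated wavelengths.
#' @param spectra a [spectra_library()]; default [default_spectra()].
#' @param fluence_mu_eff effective attenuation coefficient (1/mm).
#' @param n_repeats frames per wavelength.
#' @param noise_sd additive white noise sd (a.u.).
#' @param motion_fraction fraction of frames corrupted by motion.
#' @param tissue_sos in-body sound speed used for the two-medium arrival
#'   times (default: mean of the phantom `sos_map` inside the body mask).
#' @return object of class `msot_acquisition`: list with `by_wavelength`
#'   (named list of [signal_set()], one per wavelength), `corrupted`
#'   (logical per frame) and `phantom_grid`.
#' @export
simulate_optoacoustic <- function(phantom, geometry, config,
                                  spectra = default_spectra(),
                                  fluence_mu_eff = 0.15, n_repeats = 1,
                                  noise_sd = 0, motion_fraction = 0,
                                  tissue_sos = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(geometry, "ring_geometry"))
  wl <- config$wavelengths
  if (min(wl) < min(spectra$wavelengths) || max(wl) > max(spectra$wavelengths))
    stop("requested wavelength outside spectra support", call. = FALSE)
  p0s <- initial_pressure(phantom, wl, spectra, fluence_mu_eff)
  g <- phantom$grid
  if (is.null(tissue_sos))
    tissue_sos <- if (any(phantom$body_mask))
      mean(phantom$sos_map[phantom$body_mask]) else config$water_sos
  # two-medium (water / tissue) arrival times, shared with the
  # dual-speed-of-sound back-projection
  delays <- .cpp_delay_table(g$ny, g$nx, g$origin[1], g$origin[2],
                             g$pixel_size, geometry$element_positions,
                             phantom$body_mask * 1, config$water_sos,
                             tissue_sos, g$pixel_size / 2)
  n_bad <- round(motion_fraction * n_repeats)
  corrupted <- rep(FALSE, n_repeats)
  if (n_bad > 0) corrupted[sample(n_repeats, n_bad)] <- TRUE
  shifts <- lapply(seq_len(n_repeats), function(f) {
    if (!corrupted[f]) c(0L, 0L)
    else {
      s <- c(0L, 0L)
      while (max(abs(s)) < 2) s <- sample(c(-4:-2, 2:4), 2, replace = TRUE)
      s
    }
  })
  out <- vector("list", length(wl))
  names(out) <- as.character(wl)
  for (w in seq_along(wl)) {
    arr <- array(0, dim = c(n_repeats, geometry$n_elements, config$n_samples))
    sino_clean <- NULL
    for (f in seq_len(n_repeats)) {
      p0 <- if (corrupted[f])
        shift_matrix(p0s[[w]], shifts[[f]][1], shifts[[f]][2])
      else p0s[[w]]
      if (corrupted[f] || is.null(sino_clean)) {
        sino <- .cpp_msot_project_delays(p0, g$origin[1], g$origin[2],
                                         g$pixel_size,
                                         geometry$element_positions, delays,
                                         config$sampling_rate,
                                         config$acquisition_delay,
                                         config$n_samples)
        if (max(abs(sino)) > 0) {
          # thermoelastic generation: the detected pressure is the time
          # derivative of the spherical-mean projection (this is also what
          # makes the universal back-projection weighting focus correctly)
          fs <- config$sampling_rate
          sino <- t(apply(sino, 1, function(tr)
            c(diff(tr), 0) * fs))
          sino <- band_filter_traces(sino, fs,
                                     0.1e6, config$center_frequency *
                                       (1 + config$fractional_bandwidth / 2))
        }
        if (!corrupted[f]) sino_clean <- sino
      } else {
        sino <- sino_clean
      }
      if (noise_sd > 0)
        sino <- sino + matrix(rnorm(length(sino), 0, noise_sd),
                              nrow(sino), ncol(sino))
      arr[f, , ] <- sino
    }
    out[[w]] <- signal_set("msot", arr, config, geometry,
                           wavelength = wl[w])
  }
  structure(list(by_wavelength = out, corrupted = corrupted,
                 phantom_grid = g),
            class = "msot_acquisition")
}

#' Simulate a synthetic transmit aperture (STA) acquisition
#'
#' One element transmits at a time while all elements receive.  The
#' transmission component of each trace is the band-limited transmit pulse
#' delayed by the straight-ray travel time through the phantom's
#' speed-of-sound map (line integral of slowness) and scaled by
#' `1/sqrt(path length)`; the reflection component sums, over the phantom's
#' point scatterers, pulses delayed by the two-leg straight-ray travel time
#' and scaled by reflectivity and two-leg geometric spreading.
#'
#' @param phantom a [generate_phantom()] phantom.
#' @param geometry a [make_ring_geometry()].
#' @param config an [acquisition_config()]; the record must be long enough
#'   to contain the diametric transmission arrival.
#' @param noise_sd additive white Gaussian noise sd (a.u.).
#' @param tx_indices transmitting elements (default: the full ring).
#' @param with_transmission include the through-transmission component.
#' @param with_reflection include the scatterer (pulse-echo) component.
#' @param rx_aperture_deg optionally record only receivers within this
#'   aperture (degrees of arc) around each transmitter, as when the
#'   acquisition stores only the channels the pulse-echo beamformer uses;
#'   `NULL` (default) records the full ring.
#' @return a [signal_set()] with `mode = "sta"` and data
#'   `[tx, element, sample]`.
#' @export
simulate_sta <- function(phantom, geometry, config, noise_sd = 0,
                         tx_indices = NULL, with_transmission = TRUE,
                         with_reflection = TRUE, rx_aperture_deg = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(geometry, "ring_geometry"))
  if (is.null(tx_indices)) tx_indices <- seq_len(geometry$n_elements)
  g <- phantom$grid
  c_min <- min(phantom$sos_map, config$water_sos)
  t_need <- 2 * geometry$radius * 1e-3 / c_min + 4.5 * pulse_sigma(config)
  t_end <- config$acquisition_delay + (config$n_samples - 1) /
    config$sampling_rate
  if (with_transmission && t_end < t_need)
    stop(sprintf(paste0("record too short for the diametric transmission ",
                        "arrival: need %.1f us, record ends at %.1f us; ",
                        "increase n_samples"),
                 t_need * 1e6, t_end * 1e6), call. = FALSE)
  scat <- if (with_reflection && nrow(phantom$scatterers) > 0)
    phantom$scatterers else matrix(0, 0, 3)
  ap_half <- if (is.null(rx_aperture_deg)) -1L else
    as.integer(ceiling(geometry$n_elements * rx_aperture_deg / 360 / 2))
  raw <- .cpp_sta_simulate(
    phantom$sos_map, g$origin[1], g$origin[2], g$pixel_size,
    geometry$element_positions, as.integer(tx_indices) - 1L,
    seq_len(geometry$n_elements) - 1L,
    scat[, 1:2, drop = FALSE], scat[, 3],
    config$water_sos, config$sampling_rate, config$acquisition_delay,
    config$n_samples, config$center_frequency, pulse_sigma(config),
    g$pixel_size / 2, with_transmission, ap_half
  )
  dim(raw) <- c(length(tx_indices), geometry$n_elements, config$n_samples)
  if (noise_sd > 0)
    raw <- raw + array(rnorm(length(raw), 0, noise_sd), dim = dim(raw))
  signal_set("sta", raw, config, geometry, tx_indices = tx_indices)
}
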