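# Optoacoustic image reconstruction: filtering, motion rejection, averaging,
# dual speed-of-sound back-projection, fluence correction, and display
# enhancement (CLAHE + vesselness compositing).

#' Zero-phase band-pass filter a signal set
#'
#' Applies a zero-phase Butterworth band-pass (via forward-backward
#' filtering) to every trace; DC is removed by construction.  Defaults are
#' the 0.1 and 6 MHz processing cut-offs.
#'
#' @param signals a [signal_set()].
#' @param low,high cut-off frequencies, Hz.
#' @param order filter order (per pass).
#' @return a filtered [signal_set()].
#' @export
bandpass <- function(signals, low = 0.1e6, high = 6e6, order = 4) {
  stopifnot(inherits(signals, "signal_set"))
  fs <- signals$config$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < sampling_rate/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  d <- signals$data
  dm <- dim(d)
  m <- matrix(aperm(d, c(3, 1, 2)), nrow = dm[3])
  m <- apply(m, 2, function(tr) signal::filtfilt(bf, tr))
  signals$data <- aperm(array(m, dim = c(dm[3], dm[1], dm[2])), c(2, 3, 1))
  signals
}

#' Reject motion-corrupted frames
#'
#' Computes the normalized cross-correlation of each frame's sinogram with
#' the pixel-wise median sinogram over frames; frames whose correlation
#' falls below `threshold` are flagged as motion-corrupted.
#'
#' @param frames a [signal_set()] with at least 3 frames on the first axis.
#' @param threshold correlation threshold (default 0.90).
#' @return list with integer vectors `kept` and `rejected` and the
#'   per-frame `correlation`.
#' @export
reject_motion_frames <- function(frames, threshold = 0.90) {
  stopifnot(inherits(frames, "signal_set"))
  d <- frames$data
  if (dim(d)[1] < 3)
    stop("need at least 3 frames for motion rejection", call. = FALSE)
  med <- apply(d, c(2, 3), median)
  mv <- as.vector(med)
  cc <- vapply(seq_len(dim(d)[1]), function(f) {
    x <- as.vector(d[f, , ])
    if (sd(x) == 0 || sd(mv) == 0) return(1)
    cor(x, mv)
  }, numeric(1))
  kept <- which(cc >= threshold)
  if (length(kept) == 0)
    stop("all frames rejected; lower the correlation threshold (",
         format(threshold), ")", call. = FALSE)
  list(kept = kept, rejected = which(cc < threshold), correlation = cc)
}

# Average frames of a signal set into an (element x sample) sinogram
average_frames <- function(signals, frames = NULL) {
  d <- signals$data
  if (is.null(frames)) frames <- seq_len(dim(d)[1])
  if (length(frames) == 1) d[frames, , ] else
    apply(d[frames, , , drop = FALSE], c(2, 3), mean)
}

#' Dual speed-of-sound back-projection
#'
#' Universal back-projection of an optoacoustic sinogram on a ring array
#' with a two-medium delay model: the travel time from pixel to element is
#' `len_water/c_water + len_tissue/c_tissue` along the straight segment,
#' where `len_tissue` is the in-body-mask portion.  The back-projected term
#' includes the time-derivative weighting `b(t) = p(t) - t p'(t)`; traces
#' are linearly interpolated.
#'
#' @param signals a [signal_set()] (frames averaged first) or an
#'   (element x sample) sinogram matrix plus `config`/`geometry` attributes
#'   taken from `signals`.
#' @param body_mask logical matrix on `grid`.
#' @param c_water,c_tissue speeds of sound (m/s), both in `[1300, 1700]`.
#' @param grid an [image_grid()].
#' @param frames optional frame subset to average before projection.
#' @return a [recon_image()] with `mode = "msot"`.
#' @export
backproject_dual_sos <- function(signals, body_mask, c_water, c_tissue,
                                 grid, frames = NULL) {
  stopifnot(inherits(signals, "signal_set"), inherits(grid, "image_grid"))
  if (!all(dim(body_mask) == c(grid$ny, grid$nx)))
    stop("body_mask dimensions do not match the grid", call. = FALSE)
  if (any(c(c_water, c_tissue) < 1300) || any(c(c_water, c_tissue) > 1700))
    stop("speeds of sound must lie in [1300, 1700] m/s", call. = FALSE)
  delays <- .cpp_delay_table(grid$ny, grid$nx, grid$origin[1], grid$origin[2],
                             grid$pixel_size,
                             signals$geometry$element_positions,
                             body_mask * 1, c_water, c_tissue,
                             grid$pixel_size / 2)
  backproject_with_delays(signals, delays, grid, frames)
}

# Core UBP given a precomputed delay table (reused across wavelengths)
backproject_with_delays <- function(signals, delays, grid, frames = NULL) {
  sino <- average_frames(signals, frames)
  cfg <- signals$config
  fs <- cfg$sampling_rate
  tt <- cfg$acquisition_delay + (seq_len(ncol(sino)) - 1) / fs
  dp <- t(apply(sino, 1, function(tr) {
    c(tr[2] - tr[1], (tr[-(1:2)] - tr[-((length(tr) - 1):length(tr))]) / 2,
      tr[length(tr)] - tr[length(tr) - 1]) * fs
  }))
  b <- sino - sweep(dp, 2, tt, `*`)
  px <- .cpp_backproject(b, delays, fs, cfg$acquisition_delay)
  recon_image(matrix(px, grid$ny, grid$nx), grid$pixel_size, grid$origin,
              mode = "msot", units = "a.u.")
}

#' Correct for light attenuation with a modified-Bessel disc model
#'
#' The fluence is modelled as `Phi(x) = I0(mu_eff*rho(x)) / I0(mu_eff*R)`
#' on a disc of effective radius `R` (equal-area fit to the body mask),
#' `rho` being the distance from the mask centroid and `I0` the modified
#' Bessel function of the first kind of order zero.  In-mask pixels are
#' divided by `max(Phi, 0.01)`; pixels outside the mask are unchanged.
#'
#' @param image a [recon_image()].
#' @param body_mask logical matrix on the image grid (>= 10 pixels).
#' @param mu_eff effective optical attenuation coefficient (1/mm).
#' @return corrected [recon_image()].
#' @export
correct_fluence <- function(image, body_mask, mu_eff) {
  stopifnot(inherits(image, "recon_image"))
  grid <- image_grid_of(image)
  phi <- fluence_map(body_mask, grid, mu_eff)
  px <- image$pixels
  px[body_mask] <- px[body_mask] / pmax(phi[body_mask], 0.01)
  image$pixels <- px
  image
}

image_grid_of <- function(image) {
  structure(list(nx = ncol(image$pixels), ny = nrow(image$pixels),
                 pixel_size = image$pixel_size,
                 origin = image$origin),
            class = "image_grid")
}

norm01 <- function(m) {
  rng <- range(m[is.finite(m)])
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

#' Frangi vesselness filter
#'
#' Hessian-eigenvalue vesselness for bright tubular structures, evaluated
#' over a set of Gaussian scales; the response is the maximum over scales.
#'
#' @param pixels numeric matrix.
#' @param scales_px Gaussian scales in pixels.
#' @param beta blob-ness sensitivity.
#' @param c structure-ness sensitivity; default half the maximum Hessian
#'   norm per scale.
#' @return vesselness matrix in `[0, 1]` scale-free units.
#' @export
frangi_vesselness <- function(pixels, scales_px, beta = 0.5, c = NULL) {
  best <- matrix(0, nrow(pixels), ncol(pixels))
  for (s in scales_px) {
    sm <- matrix(EBImage::imageData(EBImage::gblur(pixels, sigma = s)), nrow(pixels), ncol(pixels))
    # scale-normalized Hessian by central differences
    dxx <- sm * 0; dyy <- sm * 0; dxy <- sm * 0
    n <- nrow(sm); m <- ncol(sm)
    dyy[2:(n - 1), ] <- sm[3:n, ] - 2 * sm[2:(n - 1), ] + sm[1:(n - 2), ]
    dxx[, 2:(m - 1)] <- sm[, 3:m] - 2 * sm[, 2:(m - 1)] + sm[, 1:(m - 2)]
    dxy[2:(n - 1), 2:(m - 1)] <- (sm[3:n, 3:m] - sm[3:n, 1:(m - 2)] -
                                    sm[1:(n - 2), 3:m] +
                                    sm[1:(n - 2), 1:(m - 2)]) / 4
    dxx <- dxx * s^2; dyy <- dyy * s^2; dxy <- dxy * s^2
    tmp <- sqrt((dxx - dyy)^2 + 4 * dxy^2)
    l1 <- (dxx + dyy + tmp) / 2
    l2 <- (dxx + dyy - tmp) / 2
    # order so |lam1| <= |lam2|
    swap <- abs(l1) > abs(l2)
    lam1 <- ifelse(swap, l2, l1)
    lam2 <- ifelse(swap, l1, l2)
    S2 <- lam1^2 + lam2^2
    cc <- if (is.null(c)) sqrt(max(S2)) / 2 else c
    if (cc == 0) next
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    v[lam2 >= 0] <- 0 # bright ridges only
    best <- pmax(best, v)
  }
  best
}

#' Contrast enhancement and vessel compositing (display product)
#'
#' Applies contrast-limited adaptive histogram equalization (CLAHE) to the
#' masked image, computes Frangi vesselness over 0.1-0.5 mm scales, and
#' composes `normalized(equalized) + alpha * normalized(vesselness)`,
#' multiplied by the body mask for background suppression.  This is a
#' display product only; quantitative unmixing uses the unenhanced stack.
#'
#' @param image a [recon_image()].
#' @param body_mask logical matrix on the image grid.
#' @param alpha vesselness blend weight.
#' @param clip_limit CLAHE clip limit (fraction of tile histogram).
#' @param tiles CLAHE tile count per side.
#' @param frangi_scales_mm vesselness scales in mm.
#' @return a [recon_image()] (a.u.) with zero background.
#' @export
enhance_and_composite <- function(image, body_mask, alpha = 1,
                                  clip_limit = 0.01, tiles = 8,
                                  frangi_scales_mm = seq(0.1, 0.5, 0.1)) {
  stopifnot(inherits(image, "recon_image"))
  px <- image$pixels
  px[!is.finite(px)] <- 0
  x <- norm01(px * body_mask)
  eq <- ebi_mat(EBImage::clahe(x, nx = tiles, ny = tiles,
                                 limit = max(1, round(256 * clip_limit))))
  scales_px <- pmax(frangi_scales_mm / image$pixel_size, 0.5)
  ves <- frangi_vesselness(px * body_mask, scales_px)
  comp <- (norm01(eq) + alpha * norm01(ves)) * body_mask
  recon_image(comp, image$pixel_size, image$origin, mode = "msot",
              units = "a.u.")
}

#' Multispectral stack reconstruction
#'
#' Runs the per-wavelength pipeline band-pass -> motion rejection ->
#' frame averaging -> dual speed-of-sound back-projection -> fluence
#' correction, and stacks the corrected images.  Display enhancement
#' ([enhance_and_composite()]) is deliberately not applied to this stack:
#' histogram equalization is non-linear and would break the spectral
#' linearity the unmixing relies on.
#'
#' @param acq an `msot_acquisition` from [simulate_optoacoustic()], or a
#'   named list of per-wavelength [signal_set()]s.
#' @param body_mask logical matrix on `grid`.
#' @param grid an [image_grid()].
#' @param c_water,c_tissue back-projection speeds (m/s).
#' @param mu_eff fluence correction coefficient (1/mm).
#' @param low,high band-pass cut-offs (Hz).
#' @param motion_threshold frame-correlation threshold; motion rejection is
#'   skipped for acquisitions with fewer than 3 frames.
#' @return object of class `multispectral_stack`: list with `images`
#'   (array `[wavelength, y, x]`), `wavelengths`, `pixel_size`, `origin`
#'   and `body_mask`.
#' @export
reconstruct_stack <- function(acq, body_mask, grid, c_water = 1523,
                              c_tissue = 1540, mu_eff = 0.15,
                              low = 0.1e6, high = 6e6,
                              motion_threshold = 0.90) {
  sets <- if (inherits(acq, "msot_acquisition")) acq$by_wavelength else acq
  wl <- unname(vapply(sets, function(s) s$wavelength, numeric(1)))
  sets <- sets[order(wl)]
  wl <- sort(wl)
  cfg <- sets[[1]]$config
  missing_wl <- setdiff(cfg$wavelengths, wl)
  if (length(missing_wl))
    stop("missing wavelengths: ", paste(missing_wl, collapse = ", "),
         call. = FALSE)
  geom <- sets[[1]]$geometry
  delays <- .cpp_delay_table(grid$ny, grid$nx, grid$origin[1], grid$origin[2],
                             grid$pixel_size, geom$element_positions,
                             body_mask * 1, c_water, c_tissue,
                             grid$pixel_size / 2)
  phi_ok <- sum(body_mask) >= 10
  imgs <- array(0, dim = c(length(sets), grid$ny, grid$nx))
  for (w in seq_along(sets)) {
    s <- bandpass(sets[[w]], low, high)
    keep <- if (dim(s$data)[1] >= 3)
      reject_motion_frames(s, motion_threshold)$kept
    else seq_len(dim(s$data)[1])
    img <- backproject_with_delays(s, delays, grid, frames = keep)
    if (phi_ok) img <- correct_fluence(img, body_mask, mu_eff)
    imgs[w, , ] <- img$pixels
  }
  structure(list(images = imgs, wavelengths = wl,
                 pixel_size = grid$pixel_size, origin = grid$origin,
                 body_mask = body_mask),
            class = "multispectral_stack")
}

#' @export
print.multispectral_stack <- function(x, ...) {
  cat(sprintf("<multispectral_stack> %d wavelengths (%g-%g nm), %d x %d px\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              dim(x$images)[2], dim(x$images)[3]))
  invisible(x)
}
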