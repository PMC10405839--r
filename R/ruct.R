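# Reflection ultrasound computed tomography: per-emitter delay-and-sum over
# a neighbouring receive aperture, multi-view compounding, body segmentation
# and cross-sectional area.

#' Mute the direct transmitted arrival in an STA acquisition
#'
#' Pulse-echo beamforming is easily dominated by the direct (water-path)
#' transmitted wave between transmitter and receiver; this gates out a
#' window around the known water arrival time of every pair before
#' delay-and-sum.
#'
#' @param signals an STA [signal_set()].
#' @param guard_s half-width of the muted window around the water arrival
#'   (s); default two pulse durations.
#' @return the muted [signal_set()].
#' @export
mute_direct_arrival <- function(signals, guard_s = NULL) {
  stopifnot(inherits(signals, "signal_set"), signals$mode == "sta")
  cfg <- signals$config
  if (is.null(guard_s)) guard_s <- 2 * pulse_duration(cfg)
  pos <- signals$geometry$element_positions
  fs <- cfg$sampling_rate
  ns <- cfg$n_samples
  d <- signals$data
  for (a in seq_along(signals$tx_indices)) {
    te <- signals$tx_indices[a]
    dist <- sqrt(rowSums(sweep(pos, 2, pos[te, ])^2))
    tof <- dist * 1e-3 / cfg$water_sos
    k0 <- pmax(1, floor((tof - guard_s - cfg$acquisition_delay) * fs) + 1)
    k1 <- pmin(ns, ceiling((tof + guard_s - cfg$acquisition_delay) * fs) + 1)
    for (e in seq_len(nrow(pos)))
      if (k1[e] >= k0[e]) d[a, e, k0[e]:k1[e]] <- 0
  }
  signals$data <- d
  signals
}

# Receive aperture for one transmitter: round(n * aperture_deg/360)
# contiguous elements centred on it (even counts split short/long side),
# with a raised-cosine (Hann) receive apodization.
das_aperture <- function(geometry, tx_index, aperture_deg) {
  n <- geometry$n_elements
  n_ap <- round(n * aperture_deg / 360)
  if (n_ap > n) stop("aperture larger than the ring", call. = FALSE)
  if (n_ap < 1) stop("aperture must contain at least one element",
                     call. = FALSE)
  off <- seq.int(-floor((n_ap - 1) / 2), ceiling((n_ap - 1) / 2))
  idx <- ((tx_index - 1 + off) %% n) + 1
  apod <- 0.5 * (1 + cos(pi * off / (max(abs(off)) + 1)))
  list(indices = idx, apod = apod, offsets = off)
}

#' Single-transmission delay-and-sum image
#'
#' Low-contrast image from one STA transmission: receive channels are the
#' contiguous aperture (default 90 degrees, i.e. a quarter of the ring)
#' centred on the transmitter; each pixel sums the receiver traces sampled
#' at the two-way delay `(|x_tx - x| + |x - x_rx|)/sos` with linear
#' interpolation and Hann receive apodization.
#'
#' @param signals an STA [signal_set()].
#' @param tx_index transmitting element (must be among `tx_indices`).
#' @param grid an [image_grid()].
#' @param sos beamforming speed of sound (m/s); default the config water
#'   value.
#' @param aperture_deg receive aperture, degrees of arc (default 90; 128
#'   channels on a 512-element ring).
#' @return a linear (signed) [recon_image()] with `mode = "ruct"`.
#' @export
das_single <- function(signals, tx_index, grid, sos = NULL,
                       aperture_deg = 90) {
  stopifnot(inherits(signals, "signal_set"), signals$mode == "sta",
            inherits(grid, "image_grid"))
  if (is.null(sos)) sos <- signals$config$water_sos
  slot <- match(tx_index, signals$tx_indices)
  if (is.na(slot)) stop("tx_index ", tx_index, " not present in acquisition",
                        call. = FALSE)
  ap <- das_aperture(signals$geometry, tx_index, aperture_deg)
  px <- .cpp_das_single(as.vector(signals$data), dim(signals$data),
                        signals$geometry$element_positions,
                        slot - 1L, tx_index - 1L,
                        as.integer(ap$indices) - 1L, ap$apod,
                        grid$ny, grid$nx, grid$origin[1], grid$origin[2],
                        grid$pixel_size, sos,
                        signals$config$sampling_rate,
                        signals$config$acquisition_delay)
  recon_image(matrix(px, grid$ny, grid$nx), grid$pixel_size, grid$origin,
              mode = "ruct", units = "a.u.")
}

#' Compound low-contrast views into a high-contrast RUCT image
#'
#' Pixel-wise sum of the per-transmission images, followed by envelope
#' extraction (absolute value of the compounded image) and logarithmic
#' compression to a configurable dynamic range.
#'
#' @param images list of [das_single()] images sharing one grid.
#' @param dynamic_range_db display dynamic range (default 40 dB).
#' @return a log-compressed [recon_image()] (dB, max at 0); the linear
#'   compound is attached as attribute `"linear"`.
#' @export
compound <- function(images, dynamic_range_db = 40) {
  stopifnot(length(images) >= 1)
  ref <- images[[1]]
  lin <- ref$pixels * 0
  for (im in images) {
    if (!all(dim(im$pixels) == dim(lin)) ||
        im$pixel_size != ref$pixel_size ||
        !isTRUE(all.equal(im$origin, ref$origin)))
      stop("images do not share a common grid", call. = FALSE)
    lin <- lin + im$pixels
  }
  log_compress(lin, ref, dynamic_range_db)
}

log_compress <- function(lin, ref, dynamic_range_db) {
  env <- abs(lin)
  mx <- max(env)
  db <- if (mx > 0) 20 * log10(pmax(env, mx * 10^(-dynamic_range_db / 20 - 1)) / mx)
  else env
  db <- pmax(db, -dynamic_range_db)
  out <- recon_image(db, ref$pixel_size, ref$origin, mode = "ruct",
                     units = "a.u.")
  attr(out, "linear") <- lin
  attr(out, "dynamic_range_db") <- dynamic_range_db
  out
}

#' Full compounded RUCT reconstruction
#'
#' Delay-and-sum over every transmission in the acquisition and compound;
#' equivalent to summing [das_single()] over all transmitters but computed
#' in one pass.
#'
#' @inheritParams das_single
#' @param dynamic_range_db log-compression range, dB.
#' @param mute_direct gate out the direct transmitted arrival first
#'   (see [mute_direct_arrival()]).
#' @return a log-compressed [recon_image()] as in [compound()].
#' @export
ruct_reconstruct <- function(signals, grid, sos = NULL, aperture_deg = 90,
                             dynamic_range_db = 40, mute_direct = TRUE) {
  stopifnot(inherits(signals, "signal_set"), signals$mode == "sta")
  if (is.null(sos)) sos <- signals$config$water_sos
  if (mute_direct) signals <- mute_direct_arrival(signals)
  aps <- lapply(signals$tx_indices, function(tx)
    das_aperture(signals$geometry, tx, aperture_deg))
  apod <- aps[[1]]$apod
  rx_list <- lapply(aps, function(a) as.integer(a$indices) - 1L)
  px <- .cpp_das_compound(as.vector(signals$data), dim(signals$data),
                          signals$geometry$element_positions,
                          as.integer(signals$tx_indices) - 1L, rx_list, apod,
                          grid$ny, grid$nx, grid$origin[1], grid$origin[2],
                          grid$pixel_size, sos,
                          signals$config$sampling_rate,
                          signals$config$acquisition_delay)
  lin <- matrix(px, grid$ny, grid$nx)
  ref <- recon_image(lin, grid$pixel_size, grid$origin, "ruct", "a.u.")
  log_compress(lin, ref, dynamic_range_db)
}

#' Automatic body segmentation from a compounded RUCT image
#'
#' Stand-in for the manual skin-boundary segmentation, validated only
#' against synthetic ground truth.  The default `"contour"` method traces
#' the body outline in polar coordinates: for each ray from the
#' envelope-weighted centroid it locates the steepest descent of the
#' smoothed echo envelope (the transition from parenchymal speckle to the
#' water clutter floor), rejecting internal interfaces by requiring the
#' level outside the candidate edge to fall well below the speckle plateau,
#' then fits a smooth truncated-Fourier contour with trimmed least squares,
#' refines each radius at finer smoothing, and shrinks the contour by half
#' the pulse-echo point-spread width.  The `"otsu"` method is the classic
#' recipe (Otsu threshold on the log image, morphological closing, largest
#' connected component, hole filling); on desk-scale compounded images its
#' clutter floor makes it markedly less reliable.
#'
#' @param ruct a log-compressed RUCT [recon_image()] from
#'   [ruct_reconstruct()] or [compound()].
#' @param method `"contour"` (default) or `"otsu"`.
#' @param n_angles rays for the polar trace.
#' @param trim_mm outward point-spread compensation subtracted from the
#'   fitted contour radius (mm); the default is half the two-way
#'   point-spread width, calibrated once against synthetic ground truth.
#' @param feas_frac fraction of the speckle plateau the outside level must
#'   stay below for a candidate body edge.
#' @param closing_mm closing disc diameter for `method = "otsu"` (mm).
#' @return logical body mask (single filled region).
#' @export
auto_body_mask <- function(ruct, method = c("contour", "otsu"),
                           n_angles = 256, trim_mm = 0.27, feas_frac = 0.8,
                           closing_mm = 0.5) {
  stopifnot(inherits(ruct, "recon_image"))
  method <- match.arg(method)
  lin <- attr(ruct, "linear")
  if (is.null(lin)) {
    dr <- attr(ruct, "dynamic_range_db")
    if (is.null(dr)) dr <- max(1, -min(ruct$pixels[is.finite(ruct$pixels)]))
    lin <- 10^(pmax(ruct$pixels, -dr) / 20)
  }
  if (max(abs(lin)) == 0)
    stop("segmentation failure: empty foreground", call. = FALSE)
  if (method == "otsu") return(otsu_body_mask(ruct, closing_mm))
  contour_body_mask(lin, image_grid_of(ruct), n_angles, trim_mm, feas_frac)
}

otsu_body_mask <- function(ruct, closing_mm) {
  dr <- attr(ruct, "dynamic_range_db")
  if (is.null(dr)) dr <- max(1, -min(ruct$pixels[is.finite(ruct$pixels)]))
  x <- (ruct$pixels + dr) / dr
  x[x < 0] <- 0; x[x > 1] <- 1
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  bw <- x > th
  if (!any(bw)) stop("segmentation failure: empty foreground", call. = FALSE)
  brush_px <- max(3, 2 * round(closing_mm / ruct$pixel_size / 2) + 1)
  bw <- EBImage::closing(EBImage::Image(bw * 1),
                         EBImage::makeBrush(brush_px, shape = "disc"))
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(as.integer(lab))
  if (!length(tab) || max(tab) == 0)
    stop("segmentation failure: empty foreground", call. = FALSE)
  mask <- ebi_mat(EBImage::fillHull(
    EBImage::Image((lab == which.max(tab)) * 1))) > 0.5
  if (!any(mask)) stop("segmentation failure: empty mask", call. = FALSE)
  mask
}

# Polar steepest-descent contour tracing with robust Fourier smoothing.
contour_body_mask <- function(lin, grid, n_ang, trim_mm, feas_frac) {
  ps <- grid$pixel_size
  env <- abs(lin)
  sm <- ebi_mat(EBImage::gblur(env, sigma = 2))
  fine <- ebi_mat(EBImage::gblur(env, sigma = 1.5))
  ax <- grid_axes(grid)
  w <- sm - quantile(sm, 0.2); w[w < 0] <- 0
  if (sum(w) == 0)
    stop("segmentation failure: empty foreground", call. = FALSE)
  cx <- sum(outer(rep(1, grid$ny), ax$x) * w) / sum(w)
  cy <- sum(outer(ax$y, rep(1, grid$nx)) * w) / sum(w)
  th <- seq(0, 2 * pi, length.out = n_ang + 1)[-1]
  rmax <- min(grid$nx, grid$ny) / 2 * ps * 0.95
  rr <- seq(ps, rmax, by = ps / 4)
  dr <- ps / 4
  ray <- function(M, a) {
    xs <- cx + rr * cos(th[a]); ys <- cy + rr * sin(th[a])
    j <- round((xs - grid$origin[1]) / ps) + 1
    i <- round((ys - grid$origin[2]) / ps) + 1
    ok <- i >= 1 & i <= grid$ny & j >= 1 & j <= grid$nx
    v <- rep(NA_real_, length(rr))
    v[ok] <- M[cbind(i[ok], j[ok])]
    v
  }
  floorq <- quantile(sm, 0.15)
  platq <- quantile(sm, 0.97)
  feas_level <- floorq + feas_frac * (platq - floorq)
  steep <- function(v, lo, hi, fw, feas) {
    vs <- stats::filter(v, rep(1 / fw, fw))
    dv <- c(NA, diff(vs))
    sel <- which(!is.na(dv) & rr > lo & rr < hi)
    if (feas && length(sel)) {
      n2 <- round(2 / dr)
      outlev <- vapply(sel, function(k)
        mean(vs[min(length(vs), k + 2):min(length(vs), k + n2)],
             na.rm = TRUE), numeric(1))
      sel <- sel[!is.na(outlev) & outlev < feas_level]
    }
    if (!length(sel)) return(NA_real_)
    k <- sel[which.min(dv[sel])]
    if (k > 1 && k < length(dv) && !is.na(dv[k - 1]) && !is.na(dv[k + 1])) {
      den <- dv[k - 1] - 2 * dv[k] + dv[k + 1]
      if (is.finite(den) && den != 0)
        return(rr[k] +
                 max(-0.5, min(0.5, 0.5 * (dv[k - 1] - dv[k + 1]) / den)) * dr)
    }
    rr[k]
  }
  # Trimmed least-squares Fourier contour.  Trimming is asymmetric:
  # internal interfaces (liver capsule, dark speckle pockets) only ever
  # pull detections INWARD, so negative residuals are trimmed harder than
  # positive ones.
  fourier_fit <- function(rad, ord) {
    keep <- !is.na(rad)
    if (sum(keep) < 2 * (2 * ord + 1))
      stop("segmentation failure: too few boundary detections",
           call. = FALSE)
    X <- cbind(1, sapply(1:ord, function(k) cos(k * th)),
               sapply(1:ord, function(k) sin(k * th)))
    fit <- rep(median(rad, na.rm = TRUE), length(th))
    for (r in 1:4) {
      cf <- qr.solve(X[keep, , drop = FALSE], rad[keep])
      fit <- as.vector(X %*% cf)
      res <- rad - fit
      s <- mad(res[keep], na.rm = TRUE)
      nk <- !is.na(rad) & res > -1.5 * s & res < 2.5 * s
      if (sum(nk) < 2 * (2 * ord + 1)) break
      keep <- nk
    }
    fit
  }
  rad <- vapply(seq_len(n_ang), function(a)
    steep(ray(sm, a), 2, rmax - 1, 9, TRUE), numeric(1))
  fit1 <- fourier_fit(rad, 4)
  rad2 <- vapply(seq_len(n_ang), function(a)
    steep(ray(fine, a), fit1[a] - 1.5, fit1[a] + 1.5, 5, FALSE), numeric(1))
  fit2 <- pmax(fourier_fit(rad2, 6) - trim_mm, ps)
  Xg <- outer(rep(1, grid$ny), ax$x) - cx
  Yg <- outer(ax$y, rep(1, grid$nx)) - cy
  R <- sqrt(Xg^2 + Yg^2)
  A <- atan2(Yg, Xg) %% (2 * pi)
  ai <- pmin(pmax(round(A / (2 * pi) * n_ang), 1), n_ang)
  mask <- R <= matrix(fit2[ai], grid$ny, grid$nx)
  if (!any(mask))
    stop("segmentation failure: empty mask", call. = FALSE)
  mask
}

#' Cross-sectional area of a mask
#'
#' @param mask logical matrix (non-empty).
#' @param pixel_size pixel edge, mm.
#' @return area in mm^2 (pixel count times pixel area).
#' @export
area_mm2 <- function(mask, pixel_size) {
  n <- sum(mask)
  if (n == 0) stop("empty mask", call. = FALSE)
  n * pixel_size^2
}
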