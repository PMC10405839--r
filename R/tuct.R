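# Transmission ultrasound computed tomography: reference acquisition,
# matching-pursuit time-of-flight picking, and straight-ray travel-time
# tomography used to initialize the waveform inversion.

#' Reference (water-path) waveforms for the opposite-arc pairs
#'
#' Builds the per-pair reference description for acquisitions in water with
#' no sample in the field of view: for each emitter the opposite-arc
#' receiver set is enumerated, and each pair's reference waveform is the
#' band-limited transmit pulse delayed by the analytic water travel time
#' `d/c_water` and scaled by the `1/sqrt(d)` geometric spreading used by
#' the acquisition model.
#'
#' @param geometry a [make_ring_geometry()].
#' @param config an [acquisition_config()].
#' @param half_angle opposite-arc half-aperture (radians), default 60
#'   degrees (171 receivers on a 512-element ring).
#' @param emitters emitter subset (default all).
#' @return object of class `reference_set`: `pairs` (tx, rx), `ref_tof`
#'   (s), `amplitude`, `distance_mm`, plus `config` and `geometry`.
#' @export
acquire_reference <- function(geometry, config, half_angle = pi / 3,
                              emitters = seq_len(geometry$n_elements)) {
  pairs <- opposite_arc_pairs(geometry, half_angle, emitters)
  pos <- geometry$element_positions
  d <- sqrt(rowSums((pos[pairs[, 1], , drop = FALSE] -
                       pos[pairs[, 2], , drop = FALSE])^2))
  structure(
    list(pairs = pairs, ref_tof = d * 1e-3 / config$water_sos,
         amplitude = 1 / sqrt(pmax(d, 1)), distance_mm = d,
         config = config, geometry = geometry, half_angle = half_angle),
    class = "reference_set"
  )
}

#' Materialize reference waveforms as traces
#'
#' @param reference a [acquire_reference()] object.
#' @return matrix (pairs x samples) of the reference waveforms.
#' @export
reference_waveforms <- function(reference) {
  cfg <- reference$config
  g <- reference$geometry
  water <- matrix(1 / cfg$water_sos, 2, 2) # uniform slowness, zero pert
  .cpp_forward_waveforms(water, -1, -1, 1, g$element_positions,
                         reference$pairs - 1L, reference$ref_tof,
                         reference$amplitude, cfg$n_samples,
                         cfg$sampling_rate, cfg$acquisition_delay,
                         cfg$center_frequency, pulse_sigma(cfg),
                         1 / cfg$water_sos, 0, 1)
}

# Extract the per-pair measured traces (pairs x samples) from an STA set
pair_traces <- function(measured, pairs) {
  stopifnot(inherits(measured, "signal_set"), measured$mode == "sta")
  slots <- match(pairs[, 1], measured$tx_indices)
  if (anyNA(slots))
    stop("acquisition does not contain all required transmissions",
         call. = FALSE)
  d <- measured$data
  m <- matrix(0, nrow(pairs), dim(d)[3])
  for (q in seq_len(nrow(pairs)))
    m[q, ] <- d[slots[q], pairs[q, 2], ]
  m
}

#' Time-of-flight estimation by matching-pursuit decomposition
#'
#' Each measured pair trace is decomposed as a sum of scaled, time-shifted
#' copies of the reference waveform by iterative cross-correlation peak
#' extraction (at most `max_components`, stopping when the residual energy
#' falls below `resid_frac` of the trace energy or a component amplitude
#' falls below `amp_frac` of the first).  The time of flight is the minimum
#' retained shift, with parabolic sub-sample refinement of the correlation
#' peak.  Pairs whose decomposition fails (e.g. all-zero traces) are marked
#' invalid rather than raising an error; picks outside
#' `[0.8, 1.25] x reference` are likewise invalidated.
#'
#' @param measured an STA [signal_set()].
#' @param reference a [acquire_reference()] object on the same sampling
#'   grid.
#' @param window_half_s half-width of the search window around the
#'   reference TOF (s); default 3 pulse durations.
#' @param max_components,resid_frac,amp_frac decomposition controls.
#' @return object of class `tof_matrix`: `pairs`, `tof` (s), `valid`,
#'   `reference_tof`, `n_components`.
#' @export
estimate_tof <- function(measured, reference, window_half_s = NULL,
                         max_components = 5, resid_frac = 0.05,
                         amp_frac = 0.20) {
  cfg <- reference$config
  if (!isTRUE(all.equal(cfg$sampling_rate,
                        measured$config$sampling_rate)))
    stop("measured and reference sampling rates differ", call. = FALSE)
  if (is.null(window_half_s)) window_half_s <- 3 * pulse_duration(cfg)
  tr <- pair_traces(measured, reference$pairs)
  pick <- .cpp_tof_pick(tr, reference$ref_tof, cfg$sampling_rate,
                        measured$config$acquisition_delay,
                        cfg$center_frequency, pulse_sigma(cfg),
                        window_half_s, max_components, resid_frac, amp_frac)
  tof <- pick$tof
  valid <- pick$valid
  dur <- cfg$acquisition_delay + (cfg$n_samples - 1) / cfg$sampling_rate
  bad <- valid & (tof < 0.8 * reference$ref_tof |
                    tof > 1.25 * reference$ref_tof | tof <= 0 | tof > dur)
  valid[bad] <- FALSE
  tof[!valid] <- NA_real_
  structure(list(pairs = reference$pairs, tof = tof, valid = valid,
                 reference_tof = reference$ref_tof,
                 n_components = pick$n_components),
            class = "tof_matrix")
}

#' Slowness grid container
#'
#' @param slowness matrix (s/m), positive.
#' @param grid an [image_grid()].
#' @param water_slowness background slowness (s/m).
#' @param support logical matrix: pixels allowed to deviate from water.
#' @return object of class `slowness_grid`.
#' @export
slowness_grid <- function(slowness, grid, water_slowness, support = NULL) {
  stopifnot(all(slowness > 0))
  if (is.null(support)) support <- matrix(TRUE, grid$ny, grid$nx)
  structure(list(slowness = slowness, grid = grid,
                 water_slowness = water_slowness, support = support),
            class = "slowness_grid")
}

#' Convert a slowness grid to a speed-of-sound image
#'
#' @param sg a [slowness_grid()].
#' @return a [recon_image()] in m/s (`mode = "sos"`), clamped to
#'   `[1300, 1700]`.
#' @export
sos_image <- function(sg) {
  stopifnot(inherits(sg, "slowness_grid"))
  v <- pmin(pmax(1 / sg$slowness, 1300), 1700)
  recon_image(v, sg$grid$pixel_size, sg$grid$origin, mode = "sos",
              units = "m/s")
}

# slowness bounds corresponding to the [1300, 1700] m/s stabilization prior
.slowness_bounds <- c(1 / 1700, 1 / 1300)

#' Travel-time tomography initialization of the slowness grid
#'
#' Solves the straight-ray system `L dslowness = dtof` (path-length matrix
#' `L`, `dtof` = picked minus reference TOF) by damped SIRT sweeps
#' (simultaneous iterative reconstruction with Tikhonov shrinkage), adds the
#' water slowness back, and clamps the speed of sound to `[1300, 1700]` m/s.
#'
#' @param tof a [estimate_tof()] result (>= 20% valid pairs).
#' @param geometry a [make_ring_geometry()].
#' @param grid an [image_grid()].
#' @param water_sos water speed of sound (m/s).
#' @param support optional logical matrix restricting the update.
#' @param n_sweeps SIRT sweeps (default 20).
#' @param damping Tikhonov shrinkage per sweep.
#' @param relax relaxation factor.
#' @return a [slowness_grid()].
#' @export
initial_sos_from_tof <- function(tof, geometry, grid, water_sos = 1523,
                                 support = NULL, n_sweeps = 20,
                                 damping = 0.01, relax = 0.9) {
  stopifnot(inherits(tof, "tof_matrix"), inherits(grid, "image_grid"))
  ok <- which(tof$valid)
  if (length(ok) < 0.2 * nrow(tof$pairs))
    stop("fewer than 20% of pairs have valid picks", call. = FALSE)
  L <- path_matrix(geometry, grid, tof$pairs[ok, , drop = FALSE])
  dtof <- tof$tof[ok] - tof$reference_tof[ok]
  np <- grid$ny * grid$nx
  if (is.null(support)) support <- matrix(TRUE, grid$ny, grid$nx)
  sup <- as.vector(support)
  rs <- Matrix::rowSums(L)
  cs <- Matrix::colSums(L)
  rinv <- ifelse(rs > 0, 1 / rs, 0)
  cinv <- ifelse(cs > 0, 1 / cs, 0)
  x <- numeric(np)
  for (s in seq_len(n_sweeps)) {
    r <- dtof - as.vector(L %*% x)
    upd <- cinv * as.vector(Matrix::crossprod(L, rinv * r))
    x <- (x + relax * upd) * (1 - damping)
    x[!sup] <- 0
  }
  sl <- 1 / water_sos + x
  sl <- pmin(pmax(sl, .slowness_bounds[1]), .slowness_bounds[2])
  sl[!sup] <- 1 / water_sos
  slowness_grid(matrix(sl, grid$ny, grid$nx), grid, 1 / water_sos, support)
}

#' Straight-ray path-length matrix
#'
#' Sparse (pairs x pixels) matrix of bilinearly-distributed path lengths in
#' meters, so that `L %*% slowness_perturbation` is the travel-time
#' perturbation in seconds.  Pixels are column-major.
#'
#' @param geometry a [make_ring_geometry()].
#' @param grid an [image_grid()].
#' @param pairs integer matrix (tx, rx), 1-based.
#' @return a `dgCMatrix`.
#' @export
path_matrix <- function(geometry, grid, pairs) {
  tr <- .cpp_path_matrix(grid$ny, grid$nx, grid$origin[1], grid$origin[2],
                         grid$pixel_size, geometry$element_positions,
                         pairs - 1L, grid$pixel_size / 2)
  Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$w,
                       dims = c(nrow(pairs), grid$ny * grid$nx))
}
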