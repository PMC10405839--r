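# Gradient-descent waveform inversion of the speed-of-sound map.  The
# forward model predicts each pair's transmitted waveform by averaging the
# reference pulse over several straight/fan ray paths, each time-shifted by
# its travel time; the loss is the mean squared waveform error against the
# measured records.

# Lateral fan offsets (mm): n_paths paths spanning the first Fresnel-zone
# half-width at the mean pair distance (0 = straight ray, always included;
# n_paths is coerced to odd).
fan_offsets <- function(reference, n_paths) {
  if (n_paths < 1) stop("n_paths must be >= 1", call. = FALSE)
  if (n_paths %% 2 == 0) n_paths <- n_paths + 1
  if (n_paths == 1) return(0)
  cfg <- reference$config
  lambda_mm <- cfg$water_sos / cfg$center_frequency * 1e3
  rf <- 0.5 * sqrt(lambda_mm * mean(reference$distance_mm))
  seq(-rf, rf, length.out = n_paths)
}

#' Fan-path waveform prediction
#'
#' Predicts the transmitted waveform of every reference pair for a given
#' slowness map: each pair's trace is the average over `n_paths` paths
#' (the straight ray plus fan rays through control points laterally offset
#' within the first Fresnel-zone width) of the reference waveform shifted
#' by that path's travel time (reference water time plus the path integral
#' of the slowness perturbation).
#'
#' @param sg a [slowness_grid()].
#' @param reference a [acquire_reference()] object.
#' @param n_paths number of paths per pair (odd; default 7).
#' @return matrix (pairs x samples) of predicted traces.
#' @export
forward_waveforms <- function(sg, reference, n_paths = 7) {
  stopifnot(inherits(sg, "slowness_grid"))
  cfg <- reference$config
  g <- sg$grid
  .cpp_forward_waveforms(sg$slowness, g$origin[1], g$origin[2],
                         g$pixel_size,
                         reference$geometry$element_positions,
                         reference$pairs - 1L, reference$ref_tof,
                         reference$amplitude, cfg$n_samples,
                         cfg$sampling_rate, cfg$acquisition_delay,
                         cfg$center_frequency, pulse_sigma(cfg),
                         sg$water_slowness, fan_offsets(reference, n_paths),
                         g$pixel_size / 2)
}

# Window the measured traces around each pair's reference TOF.
fwi_windows <- function(measured, reference, window_half_s) {
  cfg <- reference$config
  fs <- cfg$sampling_rate
  t0 <- measured$config$acquisition_delay
  tr <- pair_traces(measured, reference$pairs)
  hw <- round(window_half_s * fs)
  W <- 2 * hw + 1
  m <- nrow(tr)
  win <- matrix(0, m, W)
  start <- integer(m)
  for (q in seq_len(m)) {
    c0 <- round((reference$ref_tof[q] - t0) * fs)
    s0 <- min(max(c0 - hw, 0), cfg$n_samples - W)
    start[q] <- s0
    win[q, ] <- tr[q, (s0 + 1):(s0 + W)]
  }
  list(win = win, start = start)
}

# One evaluation of the waveform loss (and optionally its gradient)
fwi_eval <- function(slowness, sg, reference, wins, offsets, want_grad) {
  cfg <- reference$config
  g <- sg$grid
  .cpp_fwi_loss_grad(slowness, g$origin[1], g$origin[2], g$pixel_size,
                     reference$geometry$element_positions,
                     reference$pairs - 1L, reference$ref_tof,
                     reference$amplitude, wins$win, wins$start,
                     cfg$sampling_rate, cfg$acquisition_delay,
                     cfg$center_frequency, pulse_sigma(cfg),
                     sg$water_slowness, offsets, sg$support * 1,
                     g$pixel_size / 2, want_grad)
}

#' Waveform inversion of the speed-of-sound map
#'
#' Gradient descent on the mean squared waveform error between the
#' fan-path forward model and the measured transmission records, starting
#' from a travel-time initialization.  The analytic gradient distributes
#' each path's time-shift sensitivity to the traversed pixels; a
#' backtracking line search (step halved until the loss decreases, at most
#' `max_halvings` times) guarantees a non-increasing loss history, and the
#' step is re-estimated each iteration from a Barzilai-Borwein secant
#' (pure fixed-step descent available via `bb_step = FALSE`).  The
#' speed of sound is clamped to `[1300, 1700]` m/s and pixels outside the
#' support stay at water.
#'
#' @param measured an STA [signal_set()].
#' @param init a [slowness_grid()] initialization (e.g.
#'   [initial_sos_from_tof()]).
#' @param reference a [acquire_reference()] object.
#' @param n_iterations gradient iterations (default 40).
#' @param step initial step size (units: slowness per gradient unit);
#'   default scales the first update to at most 5 m/s.
#' @param n_paths fan paths per pair (default 7).
#' @param window_half_s loss window half-width around the reference TOF;
#'   default 3 pulse durations.
#' @param max_halvings line-search halvings per iteration.
#' @param bb_step use the Barzilai-Borwein secant step after iteration 1.
#' @param precondition divide the gradient pixel-wise by the straight-ray
#'   coverage density (total path length per pixel), equalizing update
#'   magnitudes between densely and sparsely sampled pixels.
#' @return list with `slowness` (final [slowness_grid()]) and `state`
#'   (class `fwi_state`: `iteration`, `loss`, `step_size`, `loss_history`).
#' @export
fwi_reconstruct <- function(measured, init, reference, n_iterations = 40,
                            step = NULL, n_paths = 7, window_half_s = NULL,
                            max_halvings = 8, bb_step = TRUE,
                            precondition = TRUE) {
  stopifnot(inherits(init, "slowness_grid"), n_iterations >= 1)
  cfg <- reference$config
  if (is.null(window_half_s)) window_half_s <- 3 * pulse_duration(cfg)
  wins <- fwi_windows(measured, reference, window_half_s)
  offsets <- fan_offsets(reference, n_paths)
  sg <- init
  x <- sg$slowness
  sup <- sg$support
  pre <- NULL
  if (precondition) {
    g <- sg$grid
    L <- path_matrix(reference$geometry, g, reference$pairs)
    cov <- matrix(Matrix::colSums(L), g$ny, g$nx)
    pre <- 1 / pmax(cov, 0.05 * max(cov))
  }
  clamp <- function(m) {
    m <- pmin(pmax(m, .slowness_bounds[1]), .slowness_bounds[2])
    m[!sup] <- sg$water_slowness
    m
  }
  x <- clamp(x)
  ev <- fwi_eval(x, sg, reference, wins, offsets, TRUE)
  if (!is.finite(ev$loss))
    stop("non-finite waveform loss at initialization", call. = FALSE)
  loss <- ev$loss
  grad <- if (is.null(pre)) ev$grad else ev$grad * pre
  history <- loss
  prev_x <- NULL; prev_grad <- NULL
  step_size <- step
  for (it in seq_len(n_iterations)) {
    if (is.null(step_size)) {
      gmax <- max(abs(grad))
      # first update capped at ~10 m/s of speed change
      step_size <- if (gmax > 0) (10 / 1523^2) / gmax else 0
    } else if (bb_step && !is.null(prev_x)) {
      dx <- x - prev_x
      dg <- grad - prev_grad
      den <- sum(dg * dg)
      if (is.finite(den) && den > 0) {
        bb <- abs(sum(dx * dg)) / den
        if (is.finite(bb) && bb > 0) step_size <- bb
      }
    }
    if (step_size <= 0) break
    accepted <- FALSE
    s <- step_size
    for (h in 0:max_halvings) {
      cand <- clamp(x - s * grad)
      ev_c <- fwi_eval(cand, sg, reference, wins, offsets, FALSE)
      if (!is.finite(ev_c$loss))
        stop("non-finite waveform loss during line search", call. = FALSE)
      if (ev_c$loss < loss) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) break
    prev_x <- x; prev_grad <- grad
    x <- clamp(x - s * grad)
    step_size <- s
    ev <- fwi_eval(x, sg, reference, wins, offsets, TRUE)
    loss <- ev$loss
    grad <- if (is.null(pre)) ev$grad else ev$grad * pre
    history <- c(history, loss)
  }
  sg$slowness <- x
  state <- structure(list(iteration = length(history) - 1, loss = loss,
                          step_size = if (is.null(step_size)) 0 else step_size,
                          loss_history = history),
                     class = "fwi_state")
  list(slowness = sg, state = state)
}
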