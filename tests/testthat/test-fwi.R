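test_that("homogeneous forward waveforms reproduce the reference traces", {
  geom <- make_ring_geometry(16, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  grid <- image_grid(32, 1)
  water <- slowness_grid(matrix(1 / 1523, 32, 32), grid, 1 / 1523)
  # water medium: every fan path adds zero perturbation delay
  est <- forward_waveforms(water, ref, n_paths = 7)
  expect_equal(est, reference_waveforms(ref), tolerance = 1e-9)
})

test_that("single-path forward shifts by the slowness line integral", {
  geom <- make_ring_geometry(16, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  grid <- image_grid(64, 1)
  sl <- matrix(1 / 1480, 64, 64)        # uniformly slower than water
  sg <- slowness_grid(sl, grid, 1 / 1523)
  est <- forward_waveforms(sg, ref, n_paths = 1)
  fs <- cfg$sampling_rate
  q <- which.max(ref$distance_mm)
  # chord clipped to the grid box: integrate the perturbation exactly
  pert <- sl - 1 / 1523
  dtof <- ringtomo:::.cpp_pairs_dtof(pert, grid$origin[1], grid$origin[2],
                                     grid$pixel_size,
                                     geom$element_positions,
                                     ref$pairs[q, , drop = FALSE] - 1L,
                                     grid$pixel_size / 2)
  k <- which.max(abs(est[q, ]))
  t_exp <- ref$ref_tof[q] + dtof
  # the strongest carrier peak sits within a quarter period of the
  # envelope centre
  expect_lt(abs((k - 1) / fs - t_exp) * fs, 2.5)
})

test_that("fan paths place the earliest energy on the fastest path", {
  geom <- make_ring_geometry(16, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  grid <- image_grid(64, 0.6)
  # slow inclusion on the straight chord of pair q: fan paths that avoid it
  # are faster, so first energy arrives before the straight-ray time
  sl <- matrix(1 / 1523, 64, 64)
  ax <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size
  X <- outer(rep(1, grid$ny), ax); Y <- outer(ax, rep(1, grid$nx))
  sl[X^2 + Y^2 <= 4^2] <- 1 / 1400
  sg <- slowness_grid(sl, grid, 1 / 1523)
  q <- which(ref$pairs[, 1] == 1 & ref$pairs[, 2] == 9)  # diametric chord
  est <- forward_waveforms(sg, ref, n_paths = 7)
  # per-path travel times enumerated independently
  offs <- ringtomo:::fan_offsets(ref, 7)
  pert <- sl - 1 / 1523
  a <- geom$element_positions[1, ]; b <- geom$element_positions[9, ]
  mid <- (a + b) / 2
  nrm <- c(-(b - a)[2], (b - a)[1]); nrm <- nrm / sqrt(sum(nrm^2))
  path_tofs <- vapply(offs, function(o) {
    cp <- mid + o * nrm
    ref$ref_tof[q] + 1e-3 *
      (ringtomo:::.cpp_line_integral(pert, grid$origin[1], grid$origin[2],
                                     grid$pixel_size, a[1], a[2], cp[1],
                                     cp[2], grid$pixel_size / 2) +
         ringtomo:::.cpp_line_integral(pert, grid$origin[1], grid$origin[2],
                                       grid$pixel_size, cp[1], cp[2], b[1],
                                       b[2], grid$pixel_size / 2))
  }, numeric(1))
  fs <- cfg$sampling_rate
  sigma <- ringtomo:::pulse_sigma(cfg)
  # nothing arrives before the fastest enumerated path's pulse support
  tr <- abs(est[q, ])
  pre <- round((min(path_tofs) - 4.6 * sigma) * fs)
  expect_lt(max(tr[seq_len(pre)]), 1e-10 * max(tr))
  # the off-chord fan paths dodge the slow inclusion, so the fan estimate
  # carries energy earlier than the straight-ray-only estimate
  est1 <- forward_waveforms(sg, ref, n_paths = 1)
  tr1 <- abs(est1[q, ])
  onset <- function(v, lev) min(which(v > lev))
  lev <- 0.05 * max(tr1)
  expect_lt(onset(tr, lev), onset(tr1, lev))
  t_straight <- ref$ref_tof[q] +
    ringtomo:::.cpp_line_integral(pert, grid$origin[1], grid$origin[2],
                                  grid$pixel_size, a[1], a[2], b[1], b[2],
                                  grid$pixel_size / 2) * 1e-3
  expect_lt(min(path_tofs), t_straight)
})

test_that("the analytic gradient matches central finite differences", {
  geom <- make_ring_geometry(12, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg, emitters = 1:6)
  grid <- image_grid(12, 2.5)
  set.seed(99)
  sl0 <- matrix(1 / 1523, 12, 12)
  truth <- sl0 + matrix(rnorm(144, 0, 2e-6), 12, 12)
  sg <- slowness_grid(truth, grid, 1 / 1523)
  wins_meas <- ringtomo:::fwi_windows(
    signal_set("sta", {
      est <- forward_waveforms(sg, ref, n_paths = 3)
      d <- array(0, c(12, 12, cfg$n_samples))
      for (q in seq_len(nrow(ref$pairs)))
        d[ref$pairs[q, 1], ref$pairs[q, 2], ] <- est[q, ]
      d
    }, cfg, geom),
    ref, 3 * ringtomo:::pulse_duration(cfg))
  offs <- ringtomo:::fan_offsets(ref, 3)
  x <- sl0 + matrix(rnorm(144, 0, 1e-6), 12, 12)
  sgx <- slowness_grid(x, grid, 1 / 1523)
  ev <- ringtomo:::fwi_eval(x, sgx, ref, wins_meas, offs, TRUE)
  h <- 1e-9
  set.seed(100)
  pix <- sample(144, 20)
  for (p in pix) {
    xp <- x; xp[p] <- xp[p] + h
    xm <- x; xm[p] <- xm[p] - h
    lp <- ringtomo:::fwi_eval(xp, sgx, ref, wins_meas, offs, FALSE)$loss
    lm <- ringtomo:::fwi_eval(xm, sgx, ref, wins_meas, offs, FALSE)$loss
    fd <- (lp - lm) / (2 * h)
    if (abs(fd) > 1e-12)
      expect_equal(ev$grad[p], fd, tolerance = 1e-4)
  }
})

test_that("initializing at the truth leaves nothing to minimize", {
  geom <- make_ring_geometry(24, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  grid <- image_grid(48, 0.75)
  spec <- default_cohort_specs("exvivo")[[2]]
  ph <- generate_phantom(spec, 1, seed = 3, grid = grid)
  ph$scatterers <- ph$scatterers[0, , drop = FALSE]
  sta <- simulate_sta(ph, geom, cfg, noise_sd = 0)
  ref <- acquire_reference(geom, cfg)
  truth <- slowness_grid(1 / ph$sos_map, grid, 1 / 1523,
                         support = dilate_mask(ph$body_mask, 3))
  wins <- ringtomo:::fwi_windows(sta, ref,
                                 3 * ringtomo:::pulse_duration(cfg))
  ev <- ringtomo:::fwi_eval(truth$slowness, truth, ref, wins, 0, FALSE)
  energy <- mean(wins$win^2)
  expect_lt(ev$loss, 1e-12 * max(energy, 1e-30) / 1e-12 * 1e-6)
  # and the optimizer accepts no harmful step
  fw <- fwi_reconstruct(sta, truth, ref, n_iterations = 3, n_paths = 1)
  expect_lte(fw$state$loss, ev$loss + 1e-18)
})

test_that("waveform inversion improves on the travel-time initialization", {
  set.seed(55)
  geom <- make_ring_geometry(64, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  grid <- image_grid(64, 30 / 64)
  spec <- default_cohort_specs("exvivo")[[2]]
  ph <- generate_phantom(spec, 2, seed = 8, grid = grid)
  sta <- simulate_sta(ph, geom, cfg, noise_sd = 0.002)
  ref <- acquire_reference(geom, cfg)
  tof <- estimate_tof(sta, ref)
  sup <- dilate_mask(ph$body_mask, 3)
  init <- initial_sos_from_tof(tof, geom, grid, water_sos = 1523,
                               support = sup)
  fw <- fwi_reconstruct(sta, init, ref, n_iterations = 15)
  # loss history is monotone non-increasing under accepted steps
  expect_true(all(diff(fw$state$loss_history) <= 0))
  expect_lte(fw$state$loss, fw$state$loss_history[1])
  init_err <- abs(liver_mean_sos(sos_image(init), ph$liver_mask) -
                    ph$truth$liver_sos)
  fwi_err <- abs(liver_mean_sos(sos_image(fw$slowness), ph$liver_mask) -
                   ph$truth$liver_sos)
  expect_lt(fwi_err, init_err + 1)
  expect_lt(fwi_err / ph$truth$liver_sos, 0.015)
})
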