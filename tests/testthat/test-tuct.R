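test_that("reference water acquisitions carry the analytic travel times", {
  geom <- make_ring_geometry(128, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  per <- length(opposite_arc_receivers(geom, 1))
  expect_equal(nrow(ref$pairs), 128 * per)       # all arcs covered
  # diametric pair: 80 mm / 1523 m/s = 52.53 us
  dia <- which(ref$pairs[, 1] == 1 & ref$pairs[, 2] == 65)
  expect_equal(ref$ref_tof[dia] * 1e6, 52.53, tolerance = 1e-3)
  # amplitude decreases with pair distance
  ord <- order(ref$distance_mm)
  expect_true(all(diff(ref$amplitude[ord]) <= 1e-12))
})

test_that("reference waveforms peak at their stated travel time", {
  geom <- make_ring_geometry(32, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  w <- reference_waveforms(ref)
  q <- which.max(ref$distance_mm)
  k <- which.max(abs(w[q, ]))
  expect_lt(abs((k - 1) / cfg$sampling_rate - ref$ref_tof[q]) *
              cfg$sampling_rate, 2.5)
})

synthetic_shift_set <- function(geom, cfg, ref, shifts_samples) {
  # build measured traces as the reference pulse delayed by ref_tof + shift
  fs <- cfg$sampling_rate
  n <- cfg$n_samples
  d <- array(0, dim = c(geom$n_elements, geom$n_elements, n))
  tt <- (seq_len(n) - 1) / fs
  for (q in seq_len(nrow(ref$pairs))) {
    tof <- ref$ref_tof[q] + shifts_samples[q] / fs
    d[ref$pairs[q, 1], ref$pairs[q, 2], ] <-
      ref$amplitude[q] * transmit_pulse(tt - tof, cfg)
  }
  signal_set("sta", d, cfg, geom)
}

test_that("the matching-pursuit picker resolves sub-sample shifts", {
  geom <- make_ring_geometry(16, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  set.seed(44)
  shifts <- runif(nrow(ref$pairs), -2.5, 2.5)
  meas <- synthetic_shift_set(geom, cfg, ref, shifts)
  tof <- estimate_tof(meas, ref)
  expect_true(all(tof$valid))
  err <- (tof$tof - ref$ref_tof) * cfg$sampling_rate - shifts
  expect_lt(max(abs(err)), 0.05)

  # zero shift: pick returns the reference time (to well below a sample;
  # reference times falling between samples leave a small sub-sample
  # interpolation remainder)
  meas0 <- synthetic_shift_set(geom, cfg, ref, rep(0, nrow(ref$pairs)))
  tof0 <- estimate_tof(meas0, ref)
  expect_lt(max(abs(tof0$tof - ref$ref_tof)) * cfg$sampling_rate, 0.02)
})

test_that("overlapping double arrivals pick the earlier path", {
  geom <- make_ring_geometry(16, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  fs <- cfg$sampling_rate
  period <- 1 / cfg$center_frequency
  n <- cfg$n_samples
  tt <- (seq_len(n) - 1) / fs
  d <- array(0, dim = c(16, 16, n))
  for (q in seq_len(nrow(ref$pairs))) {
    t1 <- ref$ref_tof[q]
    t2 <- t1 + 2 * period
    d[ref$pairs[q, 1], ref$pairs[q, 2], ] <-
      ref$amplitude[q] * (transmit_pulse(tt - t1, cfg) +
                            0.8 * transmit_pulse(tt - t2, cfg))
  }
  meas <- signal_set("sta", d, cfg, geom)
  tof <- estimate_tof(meas, ref)
  # the pick is the earlier arrival, not an energy-weighted mean
  err <- (tof$tof - ref$ref_tof) * fs
  expect_lt(max(abs(err[tof$valid])), 1.0)
  expect_gt(mean(tof$valid), 0.9)
})

test_that("all-zero traces are marked invalid, not errors", {
  geom <- make_ring_geometry(16, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  meas <- signal_set("sta", array(0, c(16, 16, 2400)), cfg, geom)
  tof <- estimate_tof(meas, ref)
  expect_true(all(!tof$valid))
  expect_true(all(is.na(tof$tof)))
  expect_error(initial_sos_from_tof(tof, geom, image_grid(32, 1)),
               "20%")
})

test_that("zero travel-time perturbations invert to water everywhere", {
  geom <- make_ring_geometry(32, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  ref <- acquire_reference(geom, cfg)
  tof <- structure(list(pairs = ref$pairs, tof = ref$ref_tof,
                        valid = rep(TRUE, nrow(ref$pairs)),
                        reference_tof = ref$ref_tof,
                        n_components = rep(1L, nrow(ref$pairs))),
                   class = "tof_matrix")
  sg <- initial_sos_from_tof(tof, geom, image_grid(32, 1),
                             water_sos = 1523)
  expect_equal(unname(sg$slowness),
               matrix(1 / 1523, 32, 32), tolerance = 1e-12)
})

test_that("the path matrix satisfies the adjoint identity", {
  geom <- make_ring_geometry(32, 40)
  grid <- image_grid(24, 1.2)
  pairs <- opposite_arc_pairs(geom)
  L <- path_matrix(geom, grid, pairs)
  set.seed(7)
  x <- rnorm(ncol(L)); y <- rnorm(nrow(L))
  lhs <- sum((L %*% x) * y)
  rhs <- sum(x * as.vector(Matrix::crossprod(L, y)))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # row sums are chord lengths in meters (within the grid box)
  expect_true(all(Matrix::rowSums(L) <= 80e-3 + 1e-9))
})

test_that("travel-time tomography recovers a disc inclusion mean", {
  geom <- make_ring_geometry(128, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  grid <- image_grid(64, 30 / 64)
  ax <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size
  X <- outer(rep(1, grid$ny), ax); Y <- outer(ax, rep(1, grid$nx))
  disc <- X^2 + Y^2 <= 10^2
  sos <- matrix(1523, grid$ny, grid$nx); sos[disc] <- 1495
  ref <- acquire_reference(geom, cfg)
  # exact straight-ray travel times through the slowness field
  pert <- 1 / sos - 1 / 1523
  dtof <- ringtomo:::.cpp_pairs_dtof(pert, grid$origin[1], grid$origin[2],
                                     grid$pixel_size,
                                     geom$element_positions,
                                     ref$pairs - 1L, grid$pixel_size / 2)
  tof <- structure(list(pairs = ref$pairs, tof = ref$ref_tof + dtof,
                        valid = rep(TRUE, nrow(ref$pairs)),
                        reference_tof = ref$ref_tof,
                        n_components = rep(1L, nrow(ref$pairs))),
                   class = "tof_matrix")
  sg <- initial_sos_from_tof(tof, geom, grid, water_sos = 1523)
  rec <- sos_image(sg)
  got <- mean(rec$pixels[disc])
  expect_lt(abs(got - 1495) / 1495, 0.02)
})
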