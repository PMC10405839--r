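test_that("the receive aperture matches the printed channel counts", {
  g512 <- make_ring_geometry(512, 40)
  ap <- ringtomo:::das_aperture(g512, 1, 90)
  expect_length(ap$indices, 128)          # 128 neighbouring channels (90 deg)
  g128 <- make_ring_geometry(128, 40)
  expect_length(ringtomo:::das_aperture(g128, 5, 90)$indices, 32)
  expect_error(ringtomo:::das_aperture(g128, 1, 400), "aperture")
})

test_that("DAS images localize a single scatterer and are linear", {
  # a 32-channel aperture (128-element ring) for a usable single-view PSF;
  # pixels must sample the ~0.3 mm point-spread function
  geom <- tiny_geom(128)
  cfg <- tiny_config(n_samples = 2400)
  grid <- image_grid(128, 0.25)
  ph <- point_phantom(grid, 0, 0, value = 0)
  ph$scatterers <- cbind(x = 5, y = -3, reflectivity = 1)
  s <- simulate_sta(ph, geom, cfg, with_transmission = FALSE)

  single <- das_single(s, 1, grid)
  k <- which(abs(single$pixels) == max(abs(single$pixels)), arr.ind = TRUE)
  got <- c(grid$origin[1] + (k[1, 2] - 1) * grid$pixel_size,
           grid$origin[2] + (k[1, 1] - 1) * grid$pixel_size)
  expect_lt(max(abs(got - c(5, -3))), grid$pixel_size + 1e-9)

  # linearity of the beamformer
  s2 <- s; s2$data <- 2 * s2$data
  d2 <- das_single(s2, 1, grid)
  expect_equal(d2$pixels, 2 * single$pixels, tolerance = 1e-12)

  # zero signals beamform to a zero image
  s0 <- s; s0$data[] <- 0
  expect_true(all(das_single(s0, 1, grid)$pixels == 0))
  expect_error(das_single(s, 999, grid), "not present")
})

test_that("compounding sums views, compresses to dB, and sharpens the PSF", {
  geom <- tiny_geom(64)
  cfg <- tiny_config(n_samples = 2400)
  grid <- image_grid(128, 0.25)
  ph <- point_phantom(grid, 0, 0, value = 0)
  ph$scatterers <- cbind(x = 2, y = 1, reflectivity = 1)
  s <- simulate_sta(ph, geom, cfg, with_transmission = FALSE)

  one <- das_single(s, 1, grid)
  comp3 <- compound(list(one, one, one))
  expect_equal(attr(comp3, "linear"), 3 * one$pixels, tolerance = 1e-12)
  expect_equal(max(comp3$pixels), 0)              # dB, max at 0
  expect_gte(min(comp3$pixels), -40)

  full <- ruct_reconstruct(s, grid, mute_direct = FALSE)
  lin_full <- attr(full, "linear")
  lin_one <- abs(one$pixels)
  width <- function(m) sum(abs(m) > max(abs(m)) / 2)
  expect_lte(width(lin_full), 2 * width(lin_one))

  k <- which(abs(lin_full) == max(abs(lin_full)), arr.ind = TRUE)
  got <- c(grid$origin[1] + (k[1, 2] - 1) * grid$pixel_size,
           grid$origin[2] + (k[1, 1] - 1) * grid$pixel_size)
  expect_lt(max(abs(got - c(2, 1))), grid$pixel_size + 1e-9)

  shifted <- one
  shifted$pixels <- one$pixels[, c(2:ncol(one$pixels), 1)]
  dim_bad <- recon_image(one$pixels[1:10, ], one$pixel_size, one$origin,
                         "ruct", "a.u.")
  expect_error(compound(list(one, dim_bad)), "grid")
})

test_that("compounded localization stays within a pixel over placements", {
  set.seed(33)
  geom <- tiny_geom(48)
  cfg <- tiny_config(n_samples = 2400)
  grid <- image_grid(112, 0.25)
  for (rep in 1:6) {
    pos <- runif(2, -10, 10)
    ph <- point_phantom(grid, 0, 0, value = 0)
    ph$scatterers <- cbind(x = pos[1], y = pos[2], reflectivity = 1)
    s <- simulate_sta(ph, geom, cfg, with_transmission = FALSE)
    ru <- ruct_reconstruct(s, grid, mute_direct = FALSE)
    lin <- attr(ru, "linear")
    k <- which(abs(lin) == max(abs(lin)), arr.ind = TRUE)
    got <- c(grid$origin[1] + (k[1, 2] - 1) * grid$pixel_size,
             grid$origin[2] + (k[1, 1] - 1) * grid$pixel_size)
    expect_lt(max(abs(got - pos)), grid$pixel_size + 1e-9)
  }
})

test_that("quarter-turn rotation of the scene rotates the compound image", {
  geom <- tiny_geom(32)
  cfg <- tiny_config(n_samples = 2400)
  grid <- image_grid(48, 0.75)
  ph <- point_phantom(grid, 0, 0, value = 0)
  set.seed(4)
  sc <- cbind(x = runif(5, -8, 8), y = runif(5, -8, 8),
              reflectivity = runif(5, 0.5, 1))
  ph$scatterers <- sc
  s1 <- simulate_sta(ph, geom, cfg, with_transmission = FALSE)
  r1 <- ruct_reconstruct(s1, grid, mute_direct = FALSE)
  # rotate scatterers by 90 degrees (8 element pitches on a 32-ring)
  ph2 <- ph
  ph2$scatterers <- cbind(x = -sc[, 2], y = sc[, 1],
                          reflectivity = sc[, 3])
  s2 <- simulate_sta(ph2, geom, cfg, with_transmission = FALSE)
  r2 <- ruct_reconstruct(s2, grid, mute_direct = FALSE)
  # rot90 of [y, x] image: new[i, j] = old[j, n + 1 - i]
  lin1 <- attr(r1, "linear"); lin2 <- attr(r2, "linear")
  n <- nrow(lin1)
  rot <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) rot[j, n + 1 - i] <- lin1[i, j]
  expect_gt(cor(as.vector(rot), as.vector(lin2)), 0.98)
})

test_that("areas follow pixel counting and the disc oracle", {
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  expect_equal(area_mm2(mask, 0.5), 25)
  expect_error(area_mm2(mask & FALSE, 0.5), "empty")

  grid <- image_grid(128, 0.2)
  ax <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size
  X <- outer(rep(1, grid$ny), ax); Y <- outer(ax, rep(1, grid$nx))
  disc <- X^2 + Y^2 <= 10^2
  expect_equal(area_mm2(disc, 0.2), pi * 100, tolerance = 0.01)
})

test_that("automatic segmentation recovers the synthetic body outline", {
  set.seed(301)
  geom <- make_ring_geometry(128, 40)
  cfg <- acquisition_config(n_samples = 2400, water_sos = 1523)
  grid <- image_grid(128, 32 / 128)
  ph <- generate_phantom(default_cohort_specs("exvivo")[[1]], 1, seed = 1,
                         grid = grid)
  sta <- simulate_sta(ph, geom, cfg, noise_sd = 0.0005,
                      rx_aperture_deg = 90)
  ru <- ruct_reconstruct(sta, grid)
  m <- auto_body_mask(ru)
  expect_gte(dice_coef(m, ph$body_mask), 0.95)
  # single filled component
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  expect_equal(max(lab), 1)
  fh <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1)))
  filled <- matrix(fh > 0.5, nrow(m), ncol(m))
  expect_identical(filled, m)
  # an empty image cannot be segmented
  blank <- recon_image(matrix(0, 64, 64), 0.25, c(0, 0), "ruct", "a.u.")
  attr(blank, "linear") <- matrix(0, 64, 64)
  attr(blank, "dynamic_range_db") <- 40
  expect_error(auto_body_mask(blank), "segmentation failure")
})
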