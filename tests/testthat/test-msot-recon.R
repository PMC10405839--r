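make_tone_set <- function(freq, n = 1024, dc = 0) {
  g <- make_ring_geometry(4, 10)
  cfg <- acquisition_config(n_samples = n)
  tt <- (seq_len(n) - 1) / cfg$sampling_rate
  tr <- sin(2 * pi * freq * tt) + dc
  d <- array(rep(tr, each = 4), dim = c(1, 4, n))
  signal_set("msot", d, cfg, g)
}

test_that("band-pass keeps in-band tones and removes DC and out-of-band", {
  inband <- bandpass(make_tone_set(3e6))
  mid <- 300:700
  expect_equal(max(abs(inband$data[1, 1, mid])), 1, tolerance = 0.05)

  # steady-state DC suppression: the 0.1 MHz high-pass transient decays
  # over ~1/f_low, so use a long record and its interior
  dc <- bandpass(make_tone_set(3e6, n = 8192, dc = 1))
  expect_lt(abs(mean(dc$data[1, 1, 3000:5000])), 1e-3)

  hi <- bandpass(make_tone_set(10e6))
  atten <- 20 * log10(max(abs(hi$data[1, 1, mid])))
  expect_lt(atten, -20)          # > 20 dB attenuation at 10 MHz

  expect_error(bandpass(make_tone_set(3e6), low = 0, high = 6e6), "band")
  expect_error(bandpass(make_tone_set(3e6), low = 1e6, high = 30e6), "band")
})

test_that("motion rejection keeps identical frames and flags shifted ones", {
  g <- make_ring_geometry(8, 10)
  cfg <- acquisition_config(n_samples = 256)
  base <- sin(2 * pi * 3e6 * (0:255) / 40e6)
  d <- array(rep(base, each = 8 * 5), dim = c(5, 8, 256))
  s <- signal_set("msot", d, cfg, g)
  r <- reject_motion_frames(s)
  expect_length(r$rejected, 0)
  expect_equal(r$kept, 1:5)

  d2 <- d
  d2[3, , ] <- array(rnorm(8 * 256), dim = c(8, 256))
  r2 <- reject_motion_frames(signal_set("msot", d2, cfg, g))
  expect_equal(r2$rejected, 3L)
  expect_error(reject_motion_frames(signal_set("msot", d[1:2, , , drop = FALSE],
                                               cfg, g)), "3 frames")
  expect_error(reject_motion_frames(s, threshold = 1.5), "threshold")
})

test_that("motion rejection recovers the simulator's corruption labels", {
  set.seed(17)
  geom <- tiny_geom(24)
  cfg <- tiny_config(n_samples = 1400, wavelengths = 800)
  grid <- image_grid(48, 0.75)
  ph <- generate_phantom(default_cohort_specs("exvivo")[[2]], 1, seed = 6,
                         grid = grid)
  acq <- simulate_optoacoustic(ph, geom, cfg, n_repeats = 12,
                               noise_sd = 0.004, motion_fraction = 0.25)
  peak <- max(abs(acq$by_wavelength[[1]]$data))
  expect_lt(0.004, 0.1 * peak)      # noise within the stated regime
  r <- reject_motion_frames(acq$by_wavelength[[1]])
  expect_setequal(r$rejected, which(acq$corrupted))   # recall & precision 1
})

test_that("homogeneous back-projection localizes a point absorber", {
  geom <- tiny_geom(64)
  cfg <- tiny_config(n_samples = 1400, wavelengths = 800)
  grid <- image_grid(128, 0.25)
  ph <- point_phantom(grid, 4, -2)
  acq <- simulate_optoacoustic(ph, geom, cfg, noise_sd = 0)
  s <- bandpass(acq$by_wavelength[[1]])
  img <- backproject_dual_sos(s, ph$body_mask, 1523, 1523, grid)
  k <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
  loc <- point_phantom_loc(grid, 4, -2)
  got <- c(grid$origin[1] + (k[1, 2] - 1) * grid$pixel_size,
           grid$origin[2] + (k[1, 1] - 1) * grid$pixel_size)
  expect_lt(max(abs(got - loc)), grid$pixel_size + 1e-9)
})

test_that("the dual-speed delay model matters when media differ", {
  geom <- tiny_geom(64)
  cfg <- tiny_config(n_samples = 1400, wavelengths = 800)
  grid <- image_grid(128, 0.25)
  ph <- point_phantom(grid, 0, 0)
  # body: 24 mm disc of fast tissue around the absorber
  ax <- grid_coords <- list(
    x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size,
    y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$pixel_size)
  X <- outer(rep(1, grid$ny), ax$x); Y <- outer(ax$y, rep(1, grid$nx))
  body <- X^2 + Y^2 <= 12^2
  ph$body_mask <- body
  ph$sos_map[body] <- 1650
  acq <- simulate_optoacoustic(ph, geom, cfg, noise_sd = 0,
                               tissue_sos = 1650)
  s <- bandpass(acq$by_wavelength[[1]])
  peak_at <- function(img) {
    k <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
    c(grid$origin[1] + (k[1, 2] - 1) * grid$pixel_size,
      grid$origin[2] + (k[1, 1] - 1) * grid$pixel_size)
  }
  good <- backproject_dual_sos(s, body, 1523, 1650, grid)
  expect_lt(max(abs(peak_at(good))), grid$pixel_size + 1e-9)
  # ignoring the body (all-water delays) defocuses and displaces the peak
  none <- backproject_dual_sos(s, body & FALSE, 1523, 1650, grid)
  expect_gt(max(abs(peak_at(none))) + 1e-9, 2 * grid$pixel_size)
  expect_error(backproject_dual_sos(s, body[1:10, ], 1523, 1650, grid),
               "dimensions")
  expect_error(backproject_dual_sos(s, body, 1000, 1650, grid), "1300")
})

test_that("back-projection is linear in the signals", {
  geom <- tiny_geom(32)
  cfg <- tiny_config(n_samples = 1400, wavelengths = 800)
  grid <- image_grid(48, 0.75)
  ph <- point_phantom(grid, 3, 1)
  acq <- simulate_optoacoustic(ph, geom, cfg, noise_sd = 0)
  s <- bandpass(acq$by_wavelength[[1]])
  s3 <- s; s3$data <- 3 * s3$data
  i1 <- backproject_dual_sos(s, ph$body_mask, 1523, 1523, grid)
  i3 <- backproject_dual_sos(s3, ph$body_mask, 1523, 1523, grid)
  expect_equal(i3$pixels, 3 * i1$pixels, tolerance = 1e-9)
})

test_that("fluence correction follows the Bessel disc model", {
  grid <- image_grid(64, 0.5)
  ax <- list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size,
             y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$pixel_size)
  X <- outer(rep(1, grid$ny), ax$x); Y <- outer(ax$y, rep(1, grid$nx))
  body <- X^2 + Y^2 <= 12^2
  base <- matrix(1, grid$ny, grid$nx)

  # mu_eff -> 0: correction approaches identity (I0(0) = 1)
  img <- recon_image(base, grid$pixel_size, grid$origin, "msot", "a.u.")
  tiny <- correct_fluence(img, body, 1e-9)
  expect_equal(tiny$pixels, base, tolerance = 1e-6)

  # an image equal to the fluence pattern corrects to a uniform field
  mu <- 0.2
  R <- sqrt(sum(body) * grid$pixel_size^2 / pi)
  idx <- which(body, arr.ind = TRUE)
  cx <- mean(ax$x[idx[, 2]]); cy <- mean(ax$y[idx[, 1]])
  rho <- pmin(sqrt((X - cx)^2 + (Y - cy)^2), R)
  phi <- besselI(mu * rho, 0) / besselI(mu * R, 0)
  img2 <- recon_image(phi * 5, grid$pixel_size, grid$origin, "msot", "a.u.")
  corr <- correct_fluence(img2, body, mu)
  vals <- corr$pixels[body]
  expect_lt(sd(vals) / mean(vals), 0.05)
  # centre-to-edge correction factor is I0(mu R) by construction
  centre <- corr$pixels[which.min(rho)]
  expect_equal(centre / 5, 1, tolerance = 0.02)
  # sign never flips inside the mask
  expect_true(all(corr$pixels[body] > 0))
  expect_error(correct_fluence(img2, body & FALSE, mu), "degenerate")
})

test_that("vesselness is zero on constant images and finds vessel disks", {
  flat <- frangi_vesselness(matrix(5, 48, 48), scales_px = c(1, 2))
  expect_true(all(flat == 0))

  img <- matrix(0, 96, 96)
  centers <- list(c(25, 30), c(60, 70), c(75, 25))
  for (cc in centers) {
    ii <- pmax(1, cc[1] - 1):pmin(96, cc[1] + 1)
    img[ii, pmax(1, cc[2] - 1):pmin(96, cc[2] + 1)] <- 1
  }
  v <- frangi_vesselness(img, scales_px = c(1, 1.5, 2))
  found <- matrix(0, 0, 2)
  vv <- v
  for (k in 1:3) {
    idx <- which(vv == max(vv), arr.ind = TRUE)[1, ]
    found <- rbind(found, idx)
    vv[pmax(1, idx[1] - 5):pmin(96, idx[1] + 5),
       pmax(1, idx[2] - 5):pmin(96, idx[2] + 5)] <- -Inf
  }
  for (cc in centers) {
    d <- apply(found, 1, function(f) max(abs(f - cc)))
    expect_lte(min(d), 2)
  }
})

test_that("display compositing suppresses the background exactly", {
  set.seed(3)
  grid <- image_grid(64, 0.5)
  px <- matrix(abs(rnorm(64 * 64)), 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[16:48, 16:48] <- TRUE
  img <- recon_image(px, grid$pixel_size, grid$origin, "msot", "a.u.")
  comp <- enhance_and_composite(img, mask)
  expect_true(all(comp$pixels[!mask] == 0))
  expect_gt(max(comp$pixels[mask]), 0)
})

test_that("stack reconstruction keeps wavelengths and spectral fidelity", {
  set.seed(8)
  geom <- tiny_geom(64)
  cfg <- tiny_config(n_samples = 1400)
  grid <- image_grid(64, 0.5)
  # lipid-only inclusion inside a water-speed body
  ph <- point_phantom(grid, 0, 0, value = 0)
  ax <- list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size,
             y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$pixel_size)
  X <- outer(rep(1, grid$ny), ax$x); Y <- outer(ax$y, rep(1, grid$nx))
  ph$body_mask <- X^2 + Y^2 <= 13^2
  incl <- (X - 3)^2 + (Y + 2)^2 <= 2.5^2
  ph$concentration$lipid <- incl * 1
  acq <- simulate_optoacoustic(ph, geom, cfg, noise_sd = 0)
  stk <- reconstruct_stack(acq, ph$body_mask, grid, c_water = 1523,
                           c_tissue = 1523)
  expect_s3_class(stk, "multispectral_stack")
  expect_equal(dim(stk$images)[1], 11L)
  expect_equal(stk$wavelengths, seq(740, 940, 20))

  A <- spectra_matrix(default_spectra(), stk$wavelengths)
  core <- which(incl & ((X - 3)^2 + (Y + 2)^2 <= 1.2^2))
  spec_px <- apply(stk$images, 1, function(m) mean(m[core]))
  cosine <- sum(spec_px * A[, "lipid"]) /
    sqrt(sum(spec_px^2) * sum(A[, "lipid"]^2))
  expect_gt(cosine, 0.99)

  # single-frame averaging is the identity: same data twice gives same stack
  stk2 <- reconstruct_stack(acq, ph$body_mask, grid, c_water = 1523,
                            c_tissue = 1523)
  expect_identical(stk$images, stk2$images)

  # missing wavelengths are reported
  short <- acq$by_wavelength[1:9]
  expect_error(reconstruct_stack(short, ph$body_mask, grid),
               "missing wavelengths: 920, 940")
})
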