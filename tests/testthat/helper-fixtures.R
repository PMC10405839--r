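# Shared fixtures, built in code and cached for the session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small ring + config used by most signal-level tests
tiny_geom <- function(n = 64) make_ring_geometry(n, 40)

tiny_config <- function(n_samples = 2400, wavelengths = seq(740, 940, 20)) {
  acquisition_config(n_samples = n_samples, wavelengths = wavelengths,
                     water_sos = 1523)
}

# A single-pixel absorber phantom on a small grid (for arrival-time oracles)
point_phantom <- function(grid, x, y, value = 1, sos = 1523) {
  ax <- list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size,
             y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$pixel_size)
  j <- which.min(abs(ax$x - x)); i <- which.min(abs(ax$y - y))
  zero <- matrix(0, grid$ny, grid$nx)
  conc <- list(hb = zero, hbo2 = zero, melanin = zero, lipid = zero)
  conc$lipid[i, j] <- value
  body <- matrix(TRUE, grid$ny, grid$nx)
  structure(list(grid = grid, sos_map = matrix(sos, grid$ny, grid$nx),
                 concentration = conc,
                 scatterers = matrix(numeric(0), 0, 3,
                                     dimnames = list(NULL, c("x", "y",
                                                             "reflectivity"))),
                 body_mask = body, liver_mask = body & FALSE,
                 water_sos = sos,
                 truth = list(group = "control", section_index = 1,
                              liver_sos = sos, area_mm2 = NA, weight_g = NA,
                              lipid_contrast = 1, liver_lipid = 0,
                              vessels = NULL)),
            class = "phantom")
}

# Actual pixel centre of the point in point_phantom
point_phantom_loc <- function(grid, x, y) {
  ax <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pixel_size
  ay <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$pixel_size
  c(ax[which.min(abs(ax - x))], ay[which.min(abs(ay - y))])
}

# Dilate a logical mask by a disc brush (helper around EBImage)
dilate_mask <- function(mask, px) {
  d <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1),
                                          EBImage::makeBrush(2 * px + 1,
                                                             "disc")))
  matrix(d > 0.5, nrow(mask), ncol(mask))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

digest_vec <- function(x) sum(abs(as.vector(x))) + sum(as.vector(x)^2)

# Shared ex vivo MSOT reconstruction (used by unmixing + acceptance tests)
exvivo_msot_fixture <- function() {
  fixture("exvivo_msot", function() {
    set.seed(90210)
    geom <- make_ring_geometry(128, 40)
    cfg <- tiny_config(n_samples = 2030)
    grid <- image_grid(128, 32 / 128)
    specs <- default_cohort_specs("exvivo")
    run1 <- function(spec) {
      ph <- generate_phantom(spec, 1, seed = 5, grid = grid)
      acq <- simulate_optoacoustic(ph, geom, cfg, n_repeats = 1,
                                   noise_sd = 0)
      stk <- reconstruct_stack(acq, ph$body_mask, grid, c_water = 1523,
                               c_tissue = mean(ph$sos_map[ph$body_mask]))
      list(phantom = ph, stack = stk, maps = unmix_linear(stk))
    }
    list(control = run1(specs[[1]]), nafld = run1(specs[[2]]))
  })
}
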