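# Digital phantom and cohort generation.
#
# Phantoms carry co-registered speed-of-sound, chromophore-concentration and
# scatterer descriptions of a 2D cross-section, plus body/liver masks, so
# that every reconstruction stage can be exercised against known truth.

#' Cohort specification
#'
#' Describes one experimental group: the liver speed-of-sound and body-area
#' distributions, the group body weight, the disease lipid contrast (ratio of
#' liver lipid concentration to the control baseline), and the number of
#' cross-sections.  The packaged defaults ([default_cohort_specs()]) encode
#' the study group parameters.
#'
#' @param group group label, one of `control`, `nafld_24w`, `nafld_36w`,
#'   `exvivo_control`, `exvivo_nafld`.
#' @param liver_sos_mean,liver_sos_std liver speed of sound (m/s).
#' @param area_mean,area_std cross-sectional body area (mm^2).
#' @param weight_mean group body weight (g); the weight model is normal with
#'   a 10% coefficient of variation.
#' @param lipid_contrast liver lipid concentration relative to the control
#'   baseline (>= 1 for disease groups).
#' @param n_sections cross-sections in the group.
#' @param seed group-level seed component.
#' @param fov_mm field of view of the phantom grid (defaults: 32 mm for
#'   ex vivo groups, 48 mm otherwise).
#' @param tissue_sos non-liver (soft tissue / agarose) speed of sound, m/s.
#' @param tissue_sos_sd standard deviation of the smooth non-liver tissue
#'   heterogeneity (m/s); 0 for ex vivo groups by default.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(group, liver_sos_mean, liver_sos_std, area_mean,
                        area_std, weight_mean, lipid_contrast = 1,
                        n_sections = 20, seed = 1, fov_mm = NULL,
                        tissue_sos = 1540, tissue_sos_sd = NULL) {
  group <- match.arg(group, c("control", "nafld_24w", "nafld_36w",
                              "exvivo_control", "exvivo_nafld"))
  exvivo <- startsWith(group, "exvivo")
  if (is.null(fov_mm)) fov_mm <- if (exvivo) 32 else 48
  if (is.null(tissue_sos_sd)) tissue_sos_sd <- if (exvivo) 0 else 8
  stopifnot(liver_sos_mean > 0, liver_sos_std >= 0, area_mean > 0,
            area_std >= 0, weight_mean > 0, n_sections >= 1)
  if (grepl("nafld", group) && lipid_contrast < 1)
    stop("lipid_contrast must be >= 1 for disease groups", call. = FALSE)
  structure(
    list(group = group, liver_sos_mean = liver_sos_mean,
         liver_sos_std = liver_sos_std, area_mean = area_mean,
         area_std = area_std, weight_mean = weight_mean,
         lipid_contrast = lipid_contrast,
         n_sections = as.integer(n_sections), seed = as.integer(seed),
         fov_mm = fov_mm, exvivo = exvivo, tissue_sos = tissue_sos,
         tissue_sos_sd = tissue_sos_sd),
    class = "cohort_spec"
  )
}

#' Default study cohort specifications
#'
#' The in vivo layout is three groups of 20 cross-sections (4 mice x 5
#' sections each): control (liver SoS 1538 +- 18 m/s, area 333 +- 21 mm^2,
#' weight 30.7 g), NAFLD at 24 weeks (1475 +- 34 m/s, 562 +- 29 mm^2,
#' 42.3 g, lipid contrast 1.16) and NAFLD at 36 weeks (1473 +- 26 m/s,
#' 598 +- 25 mm^2, 42.9 g, lipid contrast 1.37).  The ex vivo layout is two
#' groups of 6 sections of excised livers in a 20 mm agarose cylinder:
#' control 1525 +- 15 m/s and NAFLD 1495 +- 12 m/s with lipid contrast 1.47.
#'
#' @param which `"invivo"` or `"exvivo"`.
#' @param seed group-level seed component propagated to every spec.
#' @return list of [cohort_spec()] objects.
#' @export
default_cohort_specs <- function(which = c("invivo", "exvivo"), seed = 1) {
  which <- match.arg(which)
  if (which == "invivo") {
    list(
      cohort_spec("control", 1538, 18, 333, 21, 30.7, 1.00, 20, seed),
      cohort_spec("nafld_24w", 1475, 34, 562, 29, 42.3, 1.16, 20, seed),
      cohort_spec("nafld_36w", 1473, 26, 598, 25, 42.9, 1.37, 20, seed)
    )
  } else {
    area <- pi * 10^2 # 20 mm agarose cylinder
    list(
      cohort_spec("exvivo_control", 1525, 15, area, 5, 1.5, 1.00, 6, seed),
      cohort_spec("exvivo_nafld", 1495, 12, area, 5, 1.5, 1.47, 6, seed)
    )
  }
}

# Deterministic 31-bit seed from (spec seed, section, user seed)
phantom_seed <- function(spec, section_index, seed) {
  as.integer((spec$seed * 2654435 + section_index * 97003 +
                seed * 7919 + 13) %% 2147483647L)
}

# Smooth random field with approximately unit sd (Gaussian-blurred white
# noise, correlation length sigma_px pixels)
smooth_field <- function(ny, nx, sigma_px) {
  z <- matrix(rnorm(ny * nx), ny, nx)
  f <- ebi_mat(EBImage::gblur(z, sigma = sigma_px))
  s <- sd(as.vector(f))
  if (s > 0) f / s else f
}

# Mask of a smoothly perturbed ellipse: centre (mm), semi-axes a, b (mm),
# rotation phi, low-order radial perturbation given by amp/phase vectors.
blob_mask <- function(grid, center, a, b, phi, pert_amp = numeric(0),
                      pert_phase = numeric(0)) {
  ax <- grid_axes(grid)
  X <- outer(rep(1, grid$ny), ax$x) - center[1]
  Y <- outer(ax$y, rep(1, grid$nx)) - center[2]
  Xr <- X * cos(phi) + Y * sin(phi)
  Yr <- -X * sin(phi) + Y * cos(phi)
  rho <- sqrt((Xr / a)^2 + (Yr / b)^2)
  f <- matrix(1, grid$ny, grid$nx)
  if (length(pert_amp)) {
    th <- atan2(Yr, Xr)
    for (k in seq_along(pert_amp))
      f <- f + pert_amp[k] * sin((k + 1) * th + pert_phase[k])
  }
  rho <= f
}

#' Generate one digital cross-section phantom
#'
#' Draws a body outline (smoothly perturbed ellipse for in vivo groups, a
#' 20 mm agarose-style cylinder for ex vivo groups) with area from
#' `N(area_mean, area_std^2)`, a smooth liver blob occupying 15-30% of the
#' body with constant speed of sound drawn from the group's liver SoS
#' distribution, non-liver tissue at the configurable soft-tissue default
#' (plus optional smooth heterogeneity), chromophore concentration maps with
#' a skin melanin rim, high-hemoglobin vessel disks and the group's liver
#' lipid contrast, and a random sub-resolution scatterer field plus strong
#' skin-interface scatterers.  Fully deterministic given
#' `(spec, section_index, seed)`; random draws are made in a fixed order so
#' that two specs differing only in distribution parameters yield paired
#' (geometrically identical) phantoms under the same seed.
#'
#' @param spec a [cohort_spec()].
#' @param section_index 1-based section number within the group.
#' @param seed integer user seed.
#' @param grid an [image_grid()]; default 128 pixels across the spec's field
#'   of view.
#' @param water_sos coupling water speed of sound (m/s).
#' @return object of class `phantom` with fields `grid`, `sos_map`,
#'   `concentration` (named list hb/hbo2/melanin/lipid), `scatterers`
#'   (matrix x, y, reflectivity), `body_mask`, `liver_mask` and `truth`.
#' @export
generate_phantom <- function(spec, section_index = 1, seed = 1, grid = NULL,
                             water_sos = 1523) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(grid)) grid <- image_grid(128, spec$fov_mm / 128)
  set.seed(phantom_seed(spec, section_index, seed))
  ps <- grid$pixel_size

  # --- fixed-order standard draws (pairing across specs) ---
  z_area <- rnorm(1)
  z_sos <- rnorm(1)
  z_weight <- rnorm(1)
  aspect <- runif(1, 1.1, 1.4)
  phi <- runif(1, 0, pi)
  jitter <- runif(2, -1, 1)
  body_pert <- runif(2, 0.01, 0.03)
  body_phase <- runif(2, 0, 2 * pi)
  liver_frac <- runif(1, 0.15, 0.30)
  liver_aspect <- runif(1, 1.2, 1.8)
  liver_phi <- runif(1, 0, pi)
  liver_off <- runif(2, -1, 1)
  liver_pert <- runif(2, 0.02, 0.06)
  liver_phase <- runif(2, 0, 2 * pi)

  area <- spec$area_mean + spec$area_std * z_area
  tries <- 0
  while (area <= 0 && tries < 10) {
    warning("sampled non-positive body area; resampling")
    area <- rnorm(1, spec$area_mean, spec$area_std)
    tries <- tries + 1
  }
  if (area <= 0) stop("could not sample a positive body area", call. = FALSE)
  liver_sos <- spec$liver_sos_mean + spec$liver_sos_std * z_sos
  weight <- spec$weight_mean * (1 + 0.10 * z_weight)

  if (spec$exvivo) {
    aspect <- 1
    phi <- 0
    body_pert <- body_pert * 0.2 # nearly circular agarose mould
  }
  a <- sqrt(area * aspect / pi)
  b <- sqrt(area / (aspect * pi))
  center <- jitter * min(1, 0.04 * spec$fov_mm)
  body_mask <- blob_mask(grid, center, a, b, phi, body_pert, body_phase)

  # liver: smooth blob inside the body
  lf <- liver_frac
  la <- sqrt(lf * area * liver_aspect / pi)
  lb <- sqrt(lf * area / (liver_aspect * pi))
  lcen <- center + c(liver_off[1] * 0.30 * a, liver_off[2] * 0.30 * b)
  liver_mask <- blob_mask(grid, lcen, la, lb, liver_phi, liver_pert,
                          liver_phase)
  body_inner <- blob_mask(grid, center, 0.90 * a, 0.90 * b, phi, body_pert,
                          body_phase)
  liver_mask <- liver_mask & body_inner

  # --- speed of sound ---
  sos <- matrix(water_sos, grid$ny, grid$nx)
  sos[body_mask] <- spec$tissue_sos
  if (spec$tissue_sos_sd > 0) {
    het <- smooth_field(grid$ny, grid$nx, sigma_px = max(2, 3 / ps))
    sos[body_mask] <- sos[body_mask] +
      spec$tissue_sos_sd * het[body_mask]
  }
  sos[liver_mask] <- liver_sos

  # --- chromophores ---
  zero <- matrix(0, grid$ny, grid$nx)
  conc <- list(hb = zero, hbo2 = zero, melanin = zero, lipid = zero)
  # lipid baselines are set so that a control liver spectrum decreases
  # monotonically over 740-940 nm while the disease lipid contrast lifts
  # the 920 nm bump above the hemoglobin decline (see methods vignette)
  if (spec$exvivo) {
    conc$hb[body_mask] <- 0.01
    conc$hbo2[body_mask] <- 0.01
    conc$lipid[body_mask] <- 0.002
    conc$melanin[body_mask] <- 0.005
    conc$hb[liver_mask] <- 0.30
    conc$hbo2[liver_mask] <- 0.30
    conc$melanin[liver_mask] <- 0.01
    conc$lipid[liver_mask] <- 0.030 * spec$lipid_contrast
  } else {
    conc$hb[body_mask] <- 0.30
    conc$hbo2[body_mask] <- 0.50
    conc$lipid[body_mask] <- 0.02
    # skin melanin rim
    rim <- body_mask & !blob_mask(grid, center, a - 0.5, b - 0.5, phi,
                                  body_pert, body_phase)
    conc$melanin[rim] <- 1.0
    conc$hb[liver_mask] <- 0.45
    conc$hbo2[liver_mask] <- 0.60
    conc$lipid[liver_mask] <- 0.04 * spec$lipid_contrast
  }
  # vessels: high-hemoglobin disks
  n_ves <- sample(3:5, 1)
  ax <- grid_axes(grid)
  vx <- numeric(0); vy <- numeric(0); vr <- numeric(0)
  for (v in seq_len(n_ves)) {
    pos <- center + c(runif(1, -0.6, 0.6) * a, runif(1, -0.6, 0.6) * b)
    r <- runif(1, 0.5, 1.2)
    X <- outer(rep(1, grid$ny), ax$x) - pos[1]
    Y <- outer(ax$y, rep(1, grid$nx)) - pos[2]
    disk <- (X^2 + Y^2 <= r^2) & body_mask
    # excised (ex vivo) tissue is largely exsanguinated
    conc$hb[disk] <- if (spec$exvivo) 0.6 else 1.5
    conc$hbo2[disk] <- if (spec$exvivo) 0.6 else 2.0
    vx <- c(vx, pos[1]); vy <- c(vy, pos[2]); vr <- c(vr, r)
  }
  for (ch in names(conc)) conc[[ch]][!body_mask] <- 0

  # --- scatterers ---
  # density ~3/mm^2 (capped to the 200-1000 range) keeps the pulse-echo
  # speckle fully developed (>~1.5 scatterers per resolution cell)
  n_scat <- min(1000L, max(200L, as.integer(round(3 * area))))
  in_idx <- which(body_mask)
  pick <- sample(in_idx, min(n_scat, length(in_idx)), replace = TRUE)
  sx <- ax$x[(pick - 1) %/% grid$ny + 1] + runif(length(pick), -ps/2, ps/2)
  sy <- ax$y[(pick - 1) %% grid$ny + 1] + runif(length(pick), -ps/2, ps/2)
  srefl <- 0.05 * abs(rnorm(length(pick)))
  # skin interface: scatterers on the parametric contour at ~0.4 mm arc
  # spacing, a few times brighter than the parenchymal speckle
  perim <- 2 * pi * sqrt((a^2 + b^2) / 2)
  th <- seq(0, 2 * pi, length.out = max(64, round(perim / 0.4)))[-1]
  f <- 1 + body_pert[1] * sin(2 * th + body_phase[1]) +
    body_pert[2] * sin(3 * th + body_phase[2])
  bx <- center[1] + cos(phi) * a * f * cos(th) - sin(phi) * b * f * sin(th)
  by <- center[2] + sin(phi) * a * f * cos(th) + cos(phi) * b * f * sin(th)
  brefl <- 0.15 * (1 + 0.05 * rnorm(length(th)))
  # liver boundary: weaker interface
  thl <- seq(0, 2 * pi, length.out = max(32, round(2 * pi * la / 0.8)))[-1]
  fl <- 1 + liver_pert[1] * sin(2 * thl + liver_phase[1]) +
    liver_pert[2] * sin(3 * thl + liver_phase[2])
  lx <- lcen[1] + cos(liver_phi) * la * fl * cos(thl) -
    sin(liver_phi) * lb * fl * sin(thl)
  ly <- lcen[2] + sin(liver_phi) * la * fl * cos(thl) +
    cos(liver_phi) * lb * fl * sin(thl)
  keep <- point_in_mask(lx, ly, grid, body_mask)
  scat <- rbind(
    cbind(x = sx, y = sy, reflectivity = srefl),
    cbind(x = bx, y = by, reflectivity = brefl),
    cbind(x = lx[keep], y = ly[keep],
          reflectivity = rep(0.1, sum(keep)))
  )

  structure(
    list(grid = grid, sos_map = sos, concentration = conc,
         scatterers = scat, body_mask = body_mask, liver_mask = liver_mask,
         water_sos = water_sos,
         truth = list(group = spec$group, section_index = section_index,
                      liver_sos = liver_sos, area_mm2 = area,
                      weight_g = weight,
                      lipid_contrast = spec$lipid_contrast,
                      liver_lipid = (if (spec$exvivo) 0.030 else 0.04) *
                        spec$lipid_contrast,
                      vessels = cbind(x = vx, y = vy, r = vr))),
    class = "phantom"
  )
}

point_in_mask <- function(x, y, grid, mask) {
  j <- round((x - grid$origin[1]) / grid$pixel_size) + 1
  i <- round((y - grid$origin[2]) / grid$pixel_size) + 1
  ok <- i >= 1 & i <= grid$ny & j >= 1 & j <= grid$nx
  ok[ok] <- mask[cbind(i[ok], j[ok])]
  ok
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s section %d: %d x %d px @ %.3g mm, liver SoS %.1f m/s\n",
              x$truth$group, x$truth$section_index, x$grid$ny, x$grid$nx,
              x$grid$pixel_size, x$truth$liver_sos))
  invisible(x)
}

#' Sample a ground-truth cohort table (no phantom rasterization)
#'
#' Draws the per-section ground-truth quantities (liver SoS, lipid level,
#' area, weight) for a list of cohort specs using the same per-section random
#' streams as [generate_phantom()], without building the image-domain
#' phantoms.  Used for cohort-level statistical properties.
#'
#' @param specs list of [cohort_spec()] objects with distinct group labels.
#' @param seed integer user seed.
#' @return data.frame with one row per section.
#' @export
sample_cohort_truth <- function(specs, seed = 1) {
  groups <- vapply(specs, `[[`, "", "group")
  if (anyDuplicated(groups))
    stop("duplicate group labels in cohort specs", call. = FALSE)
  rows <- lapply(specs, function(sp) {
    do.call(rbind, lapply(seq_len(sp$n_sections), function(k) {
      set.seed(phantom_seed(sp, k, seed))
      z <- rnorm(3) # area, sos, weight: same order as generate_phantom
      data.frame(
        section_id = paste0(sp$group, "_s", k),
        group = sp$group,
        mouse_id = paste0(sp$group, "_m", (k - 1) %/% 5 + 1),
        liver_sos = sp$liver_sos_mean + sp$liver_sos_std * z[2],
        lipid = (if (sp$exvivo) 0.030 else 0.04) * sp$lipid_contrast,
        area = sp$area_mean + sp$area_std * z[1],
        weight = sp$weight_mean * (1 + 0.10 * z[3]),
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, rows)
}

#' Generate a full synthetic cohort
#'
#' Emits `n_sections` phantoms per spec plus the ground-truth table.
#'
#' @inheritParams sample_cohort_truth
#' @param grid optional shared [image_grid()] passed to every phantom.
#' @return list with `phantoms` (list of [generate_phantom()] outputs, in
#'   table row order) and `truth` (data.frame).
#' @export
generate_cohort <- function(specs, seed = 1, grid = NULL) {
  truth <- sample_cohort_truth(specs, seed) # validates duplicates
  phantoms <- list()
  for (sp in specs)
    for (k in seq_len(sp$n_sections))
      phantoms[[paste0(sp$group, "_s", k)]] <-
        generate_phantom(sp, k, seed, grid = grid)
  list(phantoms = phantoms[truth$section_id], truth = truth)
}
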