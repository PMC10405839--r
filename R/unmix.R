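# Linear spectral unmixing of the multispectral stack into Hb, HbO2,
# melanin and lipid, plus ROI spectra and the background-removed liver
# lipid metric.

#' Linear spectral unmixing
#'
#' Per in-mask pixel solves `min || A c - s ||^2` over the four chromophore
#' concentrations `c`, with `A` the (wavelengths x 4) spectra matrix and `s`
#' the pixel spectrum.  With `nonneg = TRUE` (default) concentrations are
#' constrained to be non-negative (active-set NNLS); the unconstrained
#' solution is retained as an option for oracle comparisons.
#'
#' @param stack a [reconstruct_stack()] multispectral stack (>= 4
#'   wavelengths).
#' @param spectra a [spectra_library()].
#' @param nonneg constrain concentrations to be non-negative.
#' @return object of class `chromophore_maps`: named list `maps` of
#'   matrices (hb, hbo2, melanin, lipid), per-pixel `residual` norm,
#'   `body_mask`, `pixel_size`.
#' @export
unmix_linear <- function(stack, spectra = default_spectra(), nonneg = TRUE) {
  stopifnot(inherits(stack, "multispectral_stack"))
  if (length(stack$wavelengths) < 4)
    stop("need at least 4 wavelengths to unmix 4 chromophores",
         call. = FALSE)
  A <- spectra_matrix(spectra, stack$wavelengths)
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    cr <- abs(stats::cor(A))
    diag(cr) <- 0
    worst <- which(cr == max(cr), arr.ind = TRUE)[1, ]
    stop("spectra matrix is rank-deficient on this wavelength grid; ",
         "most collinear chromophores: ",
         paste(colnames(A)[worst], collapse = " ~ "), call. = FALSE)
  }
  ny <- dim(stack$images)[2]; nx <- dim(stack$images)[3]
  mask <- if (is.null(stack$body_mask)) matrix(TRUE, ny, nx) else
    stack$body_mask
  idx <- which(mask)
  S <- apply(stack$images, 1, function(m) m[idx]) # npix x nwl
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  # unconstrained least squares for all pixels at once
  C <- t(solve(crossprod(A), t(A) %*% t(S)))      # npix x 4
  resid <- S - C %*% t(A)
  if (nonneg) {
    bad <- which(apply(C, 1, function(r) any(r < -1e-12)))
    for (p in bad) {
      sol <- pracma::lsqnonneg(A, S[p, ])
      C[p, ] <- sol$x
      resid[p, ] <- S[p, ] - A %*% sol$x
    }
  }
  maps <- lapply(seq_len(4), function(k) {
    m <- matrix(0, ny, nx)
    m[idx] <- C[, k]
    m
  })
  names(maps) <- colnames(A)
  rn <- matrix(0, ny, nx)
  rn[idx] <- sqrt(rowSums(resid^2))
  structure(list(maps = maps, residual = rn, body_mask = mask,
                 pixel_size = stack$pixel_size),
            class = "chromophore_maps")
}

#' @export
print.chromophore_maps <- function(x, ...) {
  cat(sprintf("<chromophore_maps> %s; %d x %d px\n",
              paste(names(x$maps), collapse = ", "),
              nrow(x$residual), ncol(x$residual)))
  invisible(x)
}

#' Mean spectrum over a region of interest
#'
#' Arithmetic mean of the stack over the ROI pixels, per wavelength.
#'
#' @param stack a multispectral stack.
#' @param roi_mask logical matrix; must be non-empty.
#' @return named numeric vector (names = wavelengths, nm).
#' @export
roi_spectrum <- function(stack, roi_mask) {
  stopifnot(inherits(stack, "multispectral_stack"))
  idx <- which(roi_mask)
  if (length(idx) == 0) stop("empty ROI", call. = FALSE)
  sp <- apply(stack$images, 1, function(m) mean(m[idx]))
  setNames(sp, stack$wavelengths)
}

#' Background-removed liver lipid metric
#'
#' Average unmixed lipid signal in the liver after removing the non-distinct
#' absorption background: the background level is the median lipid value
#' over the body excluding the liver, and the metric is
#' `max(0, mean(lipid[liver]) - background)`.
#'
#' @param maps a [unmix_linear()] result.
#' @param liver_mask logical matrix (non-empty).
#' @param body_mask logical matrix; default the unmixing mask.
#' @return scalar lipid metric (a.u.).
#' @export
lipid_metric <- function(maps, liver_mask, body_mask = maps$body_mask) {
  stopifnot(inherits(maps, "chromophore_maps"))
  if (!any(liver_mask)) stop("empty liver mask", call. = FALSE)
  bg_idx <- which(body_mask & !liver_mask)
  if (length(bg_idx) == 0)
    stop("liver mask covers the entire body; background level undefined",
         call. = FALSE)
  bg <- median(maps$maps$lipid[bg_idx])
  max(0, mean(maps$maps$lipid[liver_mask]) - bg)
}

#' Melanin-saturation QC flag
#'
#' Mirrors the exclusion of sections with saturated melanin signal from skin
#' pigmentation: a section is flagged when the melanin map's maximum exceeds
#' `saturation_quantile` of its in-mask distribution by `factor`.
#'
#' @param maps a [unmix_linear()] result.
#' @param saturation_quantile reference quantile (default 0.99).
#' @param factor exclusion multiplier (default 10).
#' @return logical: `TRUE` when the section should be excluded.
#' @export
melanin_saturation_flag <- function(maps, saturation_quantile = 0.99,
                                    factor = 10) {
  m <- maps$maps$melanin[maps$body_mask]
  if (!length(m)) return(FALSE)
  q <- quantile(m, saturation_quantile, names = FALSE)
  q > 0 && max(m) > factor * median(m[m > 0])
}
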