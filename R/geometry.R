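#' Circular transducer ring geometry
#'
#' Builds the geometry of an n-element circular (ring) transducer array.
#' Element 1 sits on the +x axis and elements are ordered counter-clockwise
#' with uniform angular pitch `2*pi/n_elements`.
#'
#' @param n_elements number of elements (>= 4).
#' @param radius ring radius in mm.
#' @return An object of class `ring_geometry` with fields `n_elements`,
#'   `radius` (mm), `element_angles` (radians) and `element_positions`
#'   (n x 2 matrix, mm).
#' @examples
#' g <- make_ring_geometry(512, 40)
#' # chord between neighbouring elements: 2 r sin(pi/n)
#' sqrt(sum((g$element_positions[1, ] - g$element_positions[2, ])^2))
#' @export
make_ring_geometry <- function(n_elements, radius) {
  if (length(n_elements) != 1 || n_elements < 4 || n_elements != round(n_elements))
    stop("n_elements must be a single integer >= 4", call. = FALSE)
  if (length(radius) != 1 || !is.finite(radius) || radius <= 0)
    stop("radius must be a single positive number (mm)", call. = FALSE)
  n <- as.integer(n_elements)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  structure(
    list(
      n_elements = n,
      radius = radius,
      element_angles = ang,
      element_positions = cbind(x = radius * cos(ang), y = radius * sin(ang))
    ),
    class = "ring_geometry"
  )
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("<ring_geometry> %d elements, radius %.3g mm\n",
              x$n_elements, x$radius))
  invisible(x)
}

#' Receivers on the arc opposite a transmitting element
#'
#' Selects the receive elements used for through-transmission (speed of
#' sound) imaging: all elements whose angular distance to the point
#' diametrically opposite the emitter is at most `half_angle`.  On a uniform
#' ring this yields `2 * floor(n * half_angle / (2*pi)) + 1` receivers; the
#' default 60 degree half-angle gives 171 of 512 elements.
#'
#' @param geometry a [make_ring_geometry()] object.
#' @param emitter_index 1-based emitter element index.
#' @param half_angle half-aperture in radians, in (0, pi/2). Default `pi/3`.
#' @return Sorted integer vector of 1-based receiver indices.
#' @examples
#' g <- make_ring_geometry(512, 40)
#' length(opposite_arc_receivers(g, 1))  # 171
#' @export
opposite_arc_receivers <- function(geometry, emitter_index,
                                   half_angle = pi / 3) {
  stopifnot(inherits(geometry, "ring_geometry"))
  n <- geometry$n_elements
  if (length(emitter_index) != 1 || emitter_index < 1 || emitter_index > n ||
      emitter_index != round(emitter_index))
    stop("emitter_index out of range 1..", n, call. = FALSE)
  if (!(half_angle > 0 && half_angle < pi / 2))
    stop("half_angle must be in (0, pi/2)", call. = FALSE)
  opp <- geometry$element_angles[emitter_index] + pi
  d <- abs(((geometry$element_angles - opp + pi) %% (2 * pi)) - pi)
  sort(which(d <= half_angle + 1e-12))
}

#' All opposite-arc emitter-receiver pairs
#'
#' Enumerates, for every emitter of the ring (or a subset), the
#' [opposite_arc_receivers()] set, as a two-column matrix of 1-based
#' (emitter, receiver) indices.
#'
#' @inheritParams opposite_arc_receivers
#' @param emitters emitter indices (default all).
#' @return integer matrix with columns `tx`, `rx`.
#' @export
opposite_arc_pairs <- function(geometry, half_angle = pi / 3,
                               emitters = seq_len(geometry$n_elements)) {
  out <- lapply(emitters, function(e) {
    rx <- opposite_arc_receivers(geometry, e, half_angle)
    cbind(tx = rep.int(e, length(rx)), rx = rx)
  })
  do.call(rbind, out)
}
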