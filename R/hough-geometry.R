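#' Geometry and discretization of the 3D Hough space
#'
#' HT3D parameterizes image line *segments* by a triple (theta, d, p):
#' theta in \[0, pi) and d are the usual normal-form line parameters
#' (d = x cos(theta) + y sin(theta)), and p is the signed position of a point
#' along the line in a coordinate frame local to it. A Hough cell
#' (theta, d, p) then stands for the segment of line l(d, theta) running from
#' the lowest representable position p0 = -R up to p, with R half the image
#' diagonal. `hough_spec()` fixes the image geometry and the quantization
#' steps shared by the array-based detector and its spiking counterpart.
#'
#' @param width,height Image size in pixels.
#' @param delta_d Quantization step of d in pixels (>= 1).
#' @param delta_p Quantization step of p in pixels (>= 1); within a d-column
#'   the parameter space is still held at 1-pixel rows, `delta_p` selects the
#'   strided rows that form the pattern cells.
#' @param delta_theta Angular step in radians.
#' @param eta Number of Hough cells in a "full" piece of segment used by the
#'   corner/endpoint patterns (>= 2).
#'
#' @return An object of class `hough_spec`: a list with the supplied fields
#'   plus `R` (half diagonal), `n_theta` (orientation layers), `n_d`
#'   (d-columns), `n_rows` (1-pixel p-rows per column) and `n_p` (strided
#'   p-cells per column, so `n_p * delta_p == n_rows`).
#' @examples
#' sp <- hough_spec(64, 64, delta_d = 2, delta_p = 2, delta_theta = 0.1, eta = 6)
#' sp$n_theta
#' @export
hough_spec <- function(width, height, delta_d = 2, delta_p = 2,
                       delta_theta = 0.04, eta = 6) {
  stopifnot(width >= 1, height >= 1, delta_d >= 1, delta_p >= 1,
            delta_theta > 0, eta >= 2)
  delta_d <- as.integer(delta_d)
  delta_p <- as.integer(delta_p)
  R <- sqrt(width^2 + height^2) / 2
  n_theta <- num_orientation_steps(delta_theta)
  n_d <- floor(2 * R / delta_d) + 1L
  n_rows <- floor(2 * R) + 1L
  if (n_rows %% delta_p != 0L)
    n_rows <- n_rows + (delta_p - n_rows %% delta_p)
  n_p <- n_rows %/% delta_p
  structure(list(width = as.integer(width), height = as.integer(height),
                 R = R, delta_d = delta_d, delta_p = delta_p,
                 delta_theta = delta_theta, eta = as.integer(eta),
                 n_theta = n_theta, n_d = as.integer(n_d),
                 n_rows = as.integer(n_rows), n_p = as.integer(n_p)),
            class = "hough_spec")
}

#' @export
print.hough_spec <- function(x, ...) {
  cat(sprintf("hough_spec: %dx%d image (R = %.2f)\n", x$width, x$height, x$R))
  cat(sprintf("  steps: delta_d = %d, delta_p = %d, delta_theta = %.4f, eta = %d\n",
              x$delta_d, x$delta_p, x$delta_theta, x$eta))
  cat(sprintf("  sizes: %d orientation layers, %d d-columns, %d p-rows (%d cells)\n",
              x$n_theta, x$n_d, x$n_rows, x$n_p))
  invisible(x)
}

#' Round half away from zero
#'
#' Deterministic rounding used for all Hough quantization, so bin assignment
#' does not depend on the platform's round-half-to-even behavior.
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @keywords internal
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert pixel indices to centered image coordinates
#'
#' The Hough parameterization places the origin at the image center. Pixel
#' (px, py), with px in \[0, width) and py in \[0, height) and y growing
#' downward, maps to x = px - (width-1)/2, y = py - (height-1)/2 so that an
#' integer pixel grid is symmetric about the origin.
#'
#' @param px,py Pixel column/row indices (0-based), vectorized.
#' @param spec A [hough_spec()].
#' @return A list with numeric vectors `x` and `y`.
#' @export
image_to_centered <- function(px, py, spec) {
  if (any(px < 0 | px >= spec$width | py < 0 | py >= spec$height))
    stop("pixel coordinates out of image bounds")
  list(x = px - (spec$width - 1) / 2, y = py - (spec$height - 1) / 2)
}

#' Line parameters (d, p) of a centered point for an orientation
#'
#' d = x cos(theta) + y sin(theta) is the signed distance of the line through
#' (x, y) with normal direction theta; p = -x sin(theta) + y cos(theta) is the
#' position of the point along that line.
#'
#' @param x,y Centered coordinates (vectorized).
#' @param theta Orientation in radians, in \[0, pi).
#' @return A list with numeric vectors `d` and `p`.
#' @export
line_params <- function(x, y, theta) {
  list(d = x * cos(theta) + y * sin(theta),
       p = -x * sin(theta) + y * cos(theta))
}

#' Image-space center of a Hough position
#'
#' Inverse of [line_params()]: the centered image point at position p along
#' the line (theta, d). Exact inverse rotation, so
#' `hough_to_image_center(theta, line_params(x, y, theta))` recovers (x, y).
#'
#' @param theta Orientation in radians.
#' @param d,p Hough coordinates (vectorized).
#' @return A list with numeric vectors `x` and `y`.
#' @export
hough_to_image_center <- function(theta, d, p) {
  list(x = d * cos(theta) - p * sin(theta),
       y = d * sin(theta) + p * cos(theta))
}

#' Discretize continuous Hough coordinates
#'
#' theta maps to its layer by `floor(theta / delta_theta)` (layers are
#' left-closed, layer k representing the angle k * delta_theta); d maps to
#' column `round((d + R) / delta_d)`; p maps to its 1-pixel row
#' `round(p + R)`. Rounding is half-away-from-zero.
#'
#' @param theta,d,p Continuous coordinates (theta scalar or vector recycled).
#' @param spec A [hough_spec()].
#' @return A list of integer vectors `theta_idx`, `d_idx`, `row_idx`
#'   (all 0-based).
#' @export
discretize_hough <- function(theta, d, p, spec) {
  ti <- pmin(pmax(floor(theta / spec$delta_theta), 0), spec$n_theta - 1L)
  di <- round_half_up((d + spec$R) / spec$delta_d)
  ri <- round_half_up(p + spec$R)
  list(theta_idx = as.integer(ti), d_idx = as.integer(di),
       row_idx = as.integer(ri))
}

#' Continuous representatives of discrete Hough indices
#'
#' Returns the continuous coordinates the discrete indices stand for:
#' theta = theta_idx * delta_theta (the layer angle used in voting),
#' d = d_idx * delta_d - R, p = row_idx - R.
#'
#' @param theta_idx,d_idx,row_idx Integer indices (0-based, vectorized).
#' @param spec A [hough_spec()].
#' @return A list with numeric vectors `theta`, `d`, `p`.
#' @export
undiscretize_hough <- function(theta_idx, d_idx, row_idx, spec) {
  list(theta = theta_idx * spec$delta_theta,
       d = d_idx * spec$delta_d - spec$R,
       p = row_idx - spec$R)
}

#' Coarsest usable angular step for a pattern geometry
#'
#' A corner/endpoint pattern spans eta * delta_p pixel rows in one d-column;
#' an orientation error larger than `arctan(1 / (eta * delta_p))` would let a
#' straight segment drift out of its column across the pattern window, so this
#' is the upper bound on delta_theta.
#'
#' @param eta Cells per full pattern piece.
#' @param delta_p Row stride in pixels.
#' @return The bound in radians.
#' @examples
#' max_angular_step(6, 2) # ~0.083
#' @export
max_angular_step <- function(eta, delta_p) {
  stopifnot(eta * delta_p > 0)
  atan(1 / (eta * delta_p))
}

#' Number of orientation layers covering \[0, pi)
#'
#' @param delta_theta Angular step in radians (> 0).
#' @return `ceiling(pi / delta_theta)` as an integer.
#' @examples
#' num_orientation_steps(0.04) # 79
#' @export
num_orientation_steps <- function(delta_theta) {
  stopifnot(delta_theta > 0)
  as.integer(ceiling(pi / delta_theta))
}

#' Angle of an orientation layer
#' @param theta_idx Layer index (0-based, vectorized).
#' @param spec A [hough_spec()].
#' @return Angle(s) in radians.
#' @keywords internal
layer_angle <- function(theta_idx, spec) theta_idx * spec$delta_theta
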