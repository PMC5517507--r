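#' Build a posterior-pole surface model
#'
#' The phantom posterior pole is a sphere of radius `base_radius` tangent to
#' the coronal plane at the field centre (its deepest point), plus a single
#' Gaussian bump that adds localized posterior depth — the mechanism by which
#' the deepest point of the eyeball (DPE) is displaced away from the field
#' centre, emulating the localized elongation seen in myopic eyes.
#'
#' Depth is positive-posterior, in micrometers, with the tangency point of
#' the base sphere at depth 0; points away from the centre are anterior
#' (negative) on the base sphere.
#'
#' @param base_radius sphere radius in mm; `Inf` gives a flat base. Finite
#'   radii must exceed the half-diagonal of the field so the depth stays
#'   finite over the full 12 x 9 mm raster. The default (60 mm) is a
#'   gentle background curvature: en-face stacks are flattened at the RPE
#'   by the scanner software, so the residual sag across the field is far
#'   smaller than the raw globe curvature would give.
#' @param bump_center (x, y) of the bump in mm, canonical fundus frame
#' @param bump_amplitude extra posterior depth at the bump centre, um
#' @param bump_sigma Gaussian width of the bump, mm
#' @param axial_length axial length covariate, mm
#' @param field c(width, height) of the scanned field in mm; used for the
#'   dense-grid localisation of the true DPE
#' @param extra_bumps optional list of additional Gaussian bumps for
#'   detector stress tests, each `list(center, amplitude, sigma)`; the
#'   deepest point of the summed surface remains the defined truth
#' @param base_center (x, y) of the base-sphere tangency point, mm; the
#'   field centre by default. Re-scan fixation jitter shifts it together
#'   with the other anatomy.
#' @param dpe_grid_mm grid step for the true-DPE argmax search (<= 0.01 mm)
#' @return an object of class `surface_model` with the true DPE
#'   (`$true_dpe`: x mm, y mm, depth um) located by dense-grid argmax
#' @export
#' @examples
#' s <- build_surface(Inf, c(0, -2.7), 200, 2)
#' s$true_dpe  # (0, -2.7, 200)
build_surface <- function(base_radius = 60, bump_center = c(0, -2), bump_amplitude = 150,
                          bump_sigma = 2, axial_length = 24,
                          field = c(12, 9), extra_bumps = NULL,
                          base_center = c(0, 0), dpe_grid_mm = 0.01) {
  if (!(is.numeric(base_radius) && length(base_radius) == 1L &&
        (is.infinite(base_radius) || base_radius > 0))) {
    stop_pp("`base_radius` must be a positive number or Inf")
  }
  half_diag <- sqrt(sum((field / 2)^2))
  if (is.finite(base_radius) && base_radius <= half_diag) {
    stop_pp(sprintf(
      "`base_radius` (%.2f mm) must exceed the field half-diagonal (%.2f mm)",
      base_radius, half_diag))
  }
  assert_scalar_num(bump_amplitude, "bump_amplitude", nonneg = TRUE)
  assert_scalar_num(bump_sigma, "bump_sigma", positive = TRUE)
  assert_scalar_num(axial_length, "axial_length", positive = TRUE)
  if (length(bump_center) != 2L || !all(is.finite(bump_center))) {
    stop_pp("`bump_center` must be a finite (x, y) pair")
  }
  surface <- structure(
    list(base_radius = base_radius, bump_center = as.numeric(bump_center),
         bump_amplitude = bump_amplitude, bump_sigma = bump_sigma,
         axial_length = axial_length, field = as.numeric(field),
         extra_bumps = extra_bumps, base_center = as.numeric(base_center)),
    class = "surface_model")
  surface$true_dpe <- find_true_dpe(surface, grid_mm = dpe_grid_mm)
  surface
}

#' Evaluate posterior depth of a surface model
#'
#' @param surface a `surface_model`
#' @param x,y coordinates in mm (vectorised, recycled together)
#' @return depth in micrometers, positive posterior
#' @export
surface_depth <- function(surface, x, y) {
  bc <- surface$base_center %||% c(0, 0)
  r2 <- (x - bc[1])^2 + (y - bc[2])^2
  zb <- if (is.infinite(surface$base_radius)) {
    0
  } else {
    R <- surface$base_radius
    1000 * (sqrt(R^2 - r2) - R)
  }
  d2 <- (x - surface$bump_center[1])^2 + (y - surface$bump_center[2])^2
  z <- zb + surface$bump_amplitude * exp(-d2 / (2 * surface$bump_sigma^2))
  for (b in surface$extra_bumps) {
    d2 <- (x - b$center[1])^2 + (y - b$center[2])^2
    z <- z + b$amplitude * exp(-d2 / (2 * b$sigma^2))
  }
  z
}

## dense-grid argmax of the depth function; ground truth for recovery tests
find_true_dpe <- function(surface, grid_mm = 0.01) {
  xs <- seq(-surface$field[1] / 2, surface$field[1] / 2, by = grid_mm)
  ys <- seq(-surface$field[2] / 2, surface$field[2] / 2, by = grid_mm)
  best <- c(NA_real_, NA_real_, -Inf)
  ## row-blocked evaluation keeps the peak grid memory modest
  block <- 200L
  for (i0 in seq(1L, length(ys), by = block)) {
    yb <- ys[i0:min(i0 + block - 1L, length(ys))]
    z <- outer(yb, xs, function(yy, xx) surface_depth(surface, xx, yy))
    k <- which.max(z)
    if (z[k] > best[3]) {
      ij <- arrayInd(k, dim(z))
      best <- c(xs[ij[2]], yb[ij[1]], z[k])
    }
  }
  names(best) <- c("x", "y", "depth_um")
  best
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf(
    "surface_model: base radius %s mm, bump %.0f um (sigma %.2f mm) at (%.2f, %.2f) mm\n",
    format(x$base_radius), x$bump_amplitude, x$bump_sigma,
    x$bump_center[1], x$bump_center[2]))
  cat(sprintf("  true DPE: (%.3f, %.3f) mm, depth %.1f um\n",
              x$true_dpe[1], x$true_dpe[2], x$true_dpe[3]))
  invisible(x)
}
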