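#' Place disc and fovea landmarks on a surface
#'
#' The fovea sits at the origin of the canonical fundus frame. The disc
#' centre is placed `disc_offset` mm away on the nasal side so that the
#' disc-fovea angle (fovea inferior to the disc, inferior-positive) equals
#' `disc_fovea_angle_deg`. The disc margin is a circle of `disc_radius`
#' lying in the disc's local plane, tilted by `tilt_spec$tilt_deg` about an
#' axis perpendicular to `tilt_spec$direction_deg` (the inferior-positive
#' angle of the downhill, i.e. posterior, direction). Margin z-values are
#' the tilted-plane offsets added to the surface depth at the margin's
#' lateral position.
#'
#' @param surface a `surface_model`
#' @param disc_offset distance fovea to disc centre, mm
#' @param disc_radius disc radius, mm
#' @param disc_fovea_angle_deg disc-fovea angle, degrees (2-6 typical)
#' @param tilt_spec list with `tilt_deg` (0 <= t < 90) and `direction_deg`
#'   (inferior-positive angle, from the disc centre, of the direction in
#'   which the disc plane dips posteriorly)
#' @param laterality "right" or "left"; geometry is always constructed in
#'   the canonical right-eye frame, the label records the eye
#' @param n_margin number of margin points (>= 8)
#' @return an object of class `landmarks`
#' @export
place_landmarks <- function(surface, disc_offset = 4.5, disc_radius = 0.8,
                            disc_fovea_angle_deg = 4,
                            tilt_spec = list(tilt_deg = 0, direction_deg = 0),
                            laterality = c("right", "left"), n_margin = 36L) {
  laterality <- match.arg(laterality)
  assert_scalar_num(disc_offset, "disc_offset", positive = TRUE)
  assert_scalar_num(disc_radius, "disc_radius", positive = TRUE)
  if (disc_offset < disc_radius) {
    stop_pp("disc overlaps the fovea: `disc_offset` < `disc_radius`")
  }
  if (n_margin < 8L) stop_pp("`n_margin` must be >= 8")
  tilt <- tilt_spec$tilt_deg %||% 0
  direction <- tilt_spec$direction_deg %||% 0
  if (tilt < 0 || tilt >= 90) stop_pp("`tilt_spec$tilt_deg` must be in [0, 90)")

  phi <- disc_fovea_angle_deg * pi / 180
  disc_center <- c(-disc_offset * cos(phi), disc_offset * sin(phi))

  ## downhill unit vector and tilt axis (perpendicular, the long-axis
  ## direction of the projected margin ellipse)
  a <- direction * pi / 180
  dhat <- c(cos(a), -sin(a))
  ahat <- c(sin(a), cos(a))
  th <- tilt * pi / 180

  t <- seq(0, 2 * pi, length.out = n_margin + 1L)[-(n_margin + 1L)]
  lat <- cbind(disc_center[1] + disc_radius * cos(th) * cos(t) * dhat[1] +
                 disc_radius * sin(t) * ahat[1],
               disc_center[2] + disc_radius * cos(th) * cos(t) * dhat[2] +
                 disc_radius * sin(t) * ahat[2])
  z_plane <- 1000 * disc_radius * sin(th) * cos(t)
  z <- surface_depth(surface, lat[, 1], lat[, 2]) + z_plane

  structure(
    list(fovea = c(0, 0), disc_center = disc_center, disc_radius = disc_radius,
         disc_margin = cbind(x = lat[, 1], y = lat[, 2], z = z),
         disc_plane_tilt_axis = ahat, disc_plane_tilt_deg = tilt,
         tilt_direction_deg = direction, laterality = laterality),
    class = "landmarks")
}

#' Disc-fovea angle implied by a landmark set
#'
#' @param landmarks a `landmarks` object
#' @return angle in degrees, inferior-positive
#' @export
disc_fovea_angle <- function(landmarks) {
  angle_inferior_positive(landmarks$disc_center, landmarks$fovea)
}

#' Mirror landmarks about the vertical axis
#'
#' Used to express left-eye geometry in the canonical right-eye frame (and
#' vice versa): all x coordinates flip sign, the laterality label toggles.
#' Signed angles defined in the canonical frame are unchanged because they
#' are always computed after mirroring into that frame.
#'
#' @param landmarks a `landmarks` object
#' @return mirrored `landmarks`
#' @export
mirror_landmarks <- function(landmarks) {
  lm <- landmarks
  lm$fovea[1] <- -lm$fovea[1]
  lm$disc_center[1] <- -lm$disc_center[1]
  lm$disc_margin[, "x"] <- -lm$disc_margin[, "x"]
  lm$disc_plane_tilt_axis[1] <- -lm$disc_plane_tilt_axis[1]
  lm$tilt_direction_deg <- wrap180(180 - lm$tilt_direction_deg)
  lm$laterality <- if (identical(lm$laterality, "right")) "left" else "right"
  lm
}

#' @export
print.landmarks <- function(x, ...) {
  cat(sprintf("landmarks (%s eye): disc at (%.2f, %.2f) mm r=%.2f, tilt %.1f deg toward %.1f deg\n",
              x$laterality, x$disc_center[1], x$disc_center[2],
              x$disc_radius, x$disc_plane_tilt_deg, x$tilt_direction_deg))
  invisible(x)
}
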