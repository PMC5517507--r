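#' Classify the DPE location into the four coronal-plane regions
#'
#' An eye whose DPE centre lies within 3000 um of the fovea is `near_fovea`;
#' otherwise within 3000 um of the disc centre is `near_disc`; otherwise
#' the eye is `superior` or `inferior` according to the side of the
#' (extended) fovea-disc line on which the DPE lies. Both radii are
#' inclusive at exactly 3000 um; a DPE exactly on the line beyond both
#' radii classifies as `inferior`. When both radii contain the DPE the
#' fovea takes precedence (only possible for disc-fovea distances below
#' 6000 um, which the generator defaults avoid).
#'
#' @param dpe_center (x, y) of the DPE centre, mm, canonical frame
#' @param landmarks a `landmarks` object
#' @param radius_um region radius around fovea and disc (3000 um)
#' @return object of class `dpe_category`: `label` (factor with levels
#'   near_fovea, superior, inferior, near_disc), `distance_to_fovea_um`,
#'   `distance_to_disc_um`
#' @export
classify_dpe <- function(dpe_center, landmarks, radius_um = 3000) {
  d_fov <- sqrt(sum((dpe_center - landmarks$fovea)^2)) * 1000
  d_disc <- sqrt(sum((dpe_center - landmarks$disc_center)^2)) * 1000
  label <- if (d_fov <= radius_um) {
    "near_fovea"
  } else if (d_disc <= radius_um) {
    "near_disc"
  } else {
    u <- landmarks$fovea - landmarks$disc_center
    n <- c(u[2], -u[1])                       # inferior-pointing normal
    side <- sum((dpe_center - landmarks$fovea) * n)
    if (side >= 0) "inferior" else "superior" # on-line tie-break: inferior
  }
  structure(
    list(label = factor(label, levels = dpe_category_levels()),
         distance_to_fovea_um = d_fov, distance_to_disc_um = d_disc),
    class = "dpe_category")
}

#' The four DPE location categories, in reporting order
#' @return character vector
#' @export
dpe_category_levels <- function() c("near_fovea", "superior", "inferior", "near_disc")

#' Orthographic projection of a tilted circular disc
#'
#' A circle of radius r on a plane tilted by `tilt_deg` about `tilt_axis`
#' projects onto the coronal plane as an ellipse with long diameter 2r
#' (parallel to the tilt axis) and short diameter 2r cos(tilt) — the
#' foreshortening that makes a tilted disc look oval.
#'
#' @param disc_radius circle radius, mm
#' @param tilt_axis unit 2-vector of the tilt axis (long-axis direction)
#' @param tilt_deg tilt angle, 0 <= tilt < 90
#' @return list: `long_axis`, `short_axis` (diameters, mm), `ovality`,
#'   `orientation_deg` (long-axis orientation from image vertical)
#' @export
project_disc <- function(disc_radius, tilt_axis = c(0, 1), tilt_deg = 0) {
  assert_scalar_num(disc_radius, "disc_radius", positive = TRUE)
  if (tilt_deg < 0 || tilt_deg >= 90) stop_pp("`tilt_deg` must be in [0, 90)")
  tilt_axis <- tilt_axis / sqrt(sum(tilt_axis^2))
  list(long_axis = 2 * disc_radius,
       short_axis = 2 * disc_radius * cos(tilt_deg * pi / 180),
       ovality = 1 / cos(tilt_deg * pi / 180),
       orientation_deg = wrap90(atan2(tilt_axis[1], tilt_axis[2]) * 180 / pi))
}

#' Predicted torsion from the angle-addition identity
#'
#' The geometric model treats the disc-DPE angle as the sum of the disc
#' torsion and the disc-fovea angle, so predicted torsion is their
#' difference, wrapped to the (-90, 90] range of a line orientation.
#'
#' @param disc_dpe_angle_deg,disc_fovea_angle_deg angles in (-180, 180]
#' @return predicted torsion, degrees in (-90, 90]
#' @export
predict_torsion <- function(disc_dpe_angle_deg, disc_fovea_angle_deg) {
  wrap90(disc_dpe_angle_deg - disc_fovea_angle_deg)
}

#' Predicted ovality of a disc tilted by a given angle
#'
#' @param tilt_deg tilt angle, 0 <= tilt < 90
#' @return 1 / cos(tilt)
#' @export
predict_ovality <- function(tilt_deg) {
  if (any(tilt_deg < 0 | tilt_deg >= 90)) stop_pp("`tilt_deg` must be in [0, 90)")
  1 / cos(tilt_deg * pi / 180)
}
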