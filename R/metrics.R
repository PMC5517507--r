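#' Signed depth between two coronal sections
#'
#' Depth is counted in coronal sections and converted to micrometers at the
#' section pitch (2.6 um per section at the scanner default), so a
#' separation of one section is exactly one pitch.
#'
#' @param section_a,section_b 0-based section indices
#' @param section_pitch um per section
#' @return (section_a - section_b) * section_pitch, um, signed
#' @export
depth_between <- function(section_a, section_b, section_pitch = 2.6) {
  (section_a - section_b) * section_pitch
}

## depth-map lookup with nearest-valid fallback; radius_um limits the search
depth_at_point <- function(dmap, xy, what, radius_um = NULL) {
  pitch <- attr(dmap, "lateral_pitch")
  origin <- attr(dmap, "origin")
  col <- round((xy[1] - origin[1]) / pitch) + 1
  row <- round((origin[2] - xy[2]) / pitch) + 1
  if (col < 1 || col > ncol(dmap) || row < 1 || row > nrow(dmap)) {
    stop_pp(sprintf("%s at (%.2f, %.2f) mm lies outside the raster", what, xy[1], xy[2]))
  }
  v <- dmap[row, col]
  if (!is.na(v)) return(as.integer(v))
  ## nearest valid pixel within the fallback radius (100 um at the default
  ## raster; at least 2 pixels on coarser desk-scale rasters)
  radius_um <- radius_um %||% max(100, 2 * pitch * 1000)
  r_px <- ceiling(radius_um / (pitch * 1000))
  rows <- max(1, row - r_px):min(nrow(dmap), row + r_px)
  cols <- max(1, col - r_px):min(ncol(dmap), col + r_px)
  sub <- dmap[rows, cols, drop = FALSE]
  ok <- which(!is.na(sub), arr.ind = TRUE)
  if (nrow(ok) == 0L) {
    stop_pp(sprintf("%s falls in a missing-pixel region with no valid pixel within %.0f um",
                    what, radius_um))
  }
  d2 <- (rows[ok[, 1]] - row)^2 + (cols[ok[, 2]] - col)^2
  best <- ok[which.min(d2), , drop = FALSE]
  as.integer(sub[best])
}

#' Section index of the temporal disc-border interface
#'
#' The depth-map value at the most temporal (largest x, canonical frame)
#' disc-margin point; if that pixel was never segmented (it borders the BM
#' opening) the nearest valid pixel within the fallback radius is used.
#'
#' @param landmarks a `landmarks` object
#' @param dmap a [depth_map()]
#' @return 0-based section index
#' @export
temporal_border_section <- function(landmarks, dmap) {
  i <- which.max(landmarks$disc_margin[, "x"])
  depth_at_point(dmap, landmarks$disc_margin[i, c("x", "y")],
                 "temporal disc border")
}

#' Section index of the foveal interface
#'
#' @param landmarks a `landmarks` object
#' @param dmap a [depth_map()]
#' @return 0-based section index at the fovea landmark
#' @export
fovea_section <- function(landmarks, dmap) {
  depth_at_point(dmap, landmarks$fovea, "fovea")
}

#' In-plane distances and angles of the DPE relative to disc and fovea
#'
#' All quantities are measured in the coronal plane of the DPE, in the
#' canonical right-eye frame. Angles use the inferior-positive convention:
#' the disc-DPE angle is the signed angle at the disc centre between the
#' temporal horizontal meridian and the ray to the DPE, positive when the
#' DPE is inferior; the disc-fovea angle is defined identically with the
#' fovea as target.
#'
#' @param dpe a `dpe_result`
#' @param landmarks a `landmarks` object
#' @return list: `disc_dpe_distance_um`, `fovea_dpe_distance_um`,
#'   `disc_dpe_angle_deg`, `disc_fovea_angle_deg`, `degenerate` (TRUE when
#'   the DPE coincides with the disc centre, leaving its angle undefined)
#' @export
planar_metrics <- function(dpe, landmarks) {
  d_disc <- sqrt(sum((dpe$center - landmarks$disc_center)^2)) * 1000
  d_fov <- sqrt(sum((dpe$center - landmarks$fovea)^2)) * 1000
  degenerate <- d_disc == 0
  list(
    disc_dpe_distance_um = d_disc,
    fovea_dpe_distance_um = d_fov,
    disc_dpe_angle_deg = if (degenerate) NA_real_ else
      angle_inferior_positive(landmarks$disc_center, dpe$center),
    disc_fovea_angle_deg = angle_inferior_positive(landmarks$disc_center,
                                                   landmarks$fovea),
    degenerate = degenerate)
}

#' All six DPE-relative posterior-pole metrics
#'
#' Combines [planar_metrics()] with the two signed depths: the disc-DPE
#' depth (DPE section minus temporal-disc-border section, positive when the
#' DPE is posterior to the temporal border) and the fovea-DPE depth (DPE
#' section minus foveal-interface section), both converted at the section
#' pitch.
#'
#' @param dpe a `dpe_result`
#' @param landmarks a `landmarks` object
#' @param dmap a [depth_map()]
#' @return object of class `posterior_pole_metrics`
#' @export
posterior_pole_metrics <- function(dpe, landmarks, dmap) {
  pitch <- attr(dmap, "section_pitch_um")
  pm <- planar_metrics(dpe, landmarks)
  pm$disc_dpe_depth_um <- depth_between(dpe$section_index,
                                        temporal_border_section(landmarks, dmap),
                                        pitch)
  pm$fovea_dpe_depth_um <- depth_between(dpe$section_index,
                                         fovea_section(landmarks, dmap), pitch)
  structure(pm, class = "posterior_pole_metrics")
}

#' @export
print.posterior_pole_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("posterior_pole_metrics:\n  disc-DPE  %7.1f um, depth %7.1f um, angle %6.1f deg\n",
           "  fovea-DPE %7.1f um, depth %7.1f um; disc-fovea angle %.1f deg\n"),
    x$disc_dpe_distance_um, x$disc_dpe_depth_um, x$disc_dpe_angle_deg,
    x$fovea_dpe_distance_um, x$fovea_dpe_depth_um, x$disc_fovea_angle_deg))
  invisible(x)
}
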