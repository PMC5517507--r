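#' Fit an ellipse to disc-margin points
#'
#' Direct least-squares conic fit (eigen-solution of the ellipse-specific
#' constraint) to the 2D margin points, from which the longest and shortest
#' disc diameters (LD, SD), the ovality index LD/SD and the long-axis
#' orientation follow. Orientation is reported as degrees from the image
#' vertical, positive when the axis' superior end leans temporal (+x), in
#' (-90, 90]; it is numerically meaningless for near-circular margins, so
#' `orientation_defined` flags ovality >= 1.02.
#'
#' @param points n x 2 matrix of (x, y) margin points, n >= 5, not collinear
#' @return list: `long_axis`, `short_axis` (full diameters, input units),
#'   `ovality`, `orientation_deg`, `center`, `orientation_defined`
#' @export
fit_disc_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) stop_pp("ellipse fit needs >= 5 margin points")
  x <- points[, 1]
  y <- points[, 2]
  ## centre/scale for conditioning
  mx <- mean(x); my <- mean(y)
  sc <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (sc < .Machine$double.eps) stop_pp("degenerate margin: all points coincide")
  xs <- (x - mx) / sc
  ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop_pp("degenerate (collinear) margin points")
  T2 <- -solve(S3, t(S2))
  M0 <- S1 + S2 %*% T2
  M <- rbind(M0[3, ] / 2, -M0[2, ], M0[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0L) stop_pp("margin points do not define an ellipse")
  a1 <- vecs[, k[1]]
  conic <- c(a1, T2 %*% a1)          # A B C D E F in scaled frame
  if (conic[1] < 0) conic <- -conic  # normalise the quadratic form positive
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5]; FF <- conic[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + FF * B^2 - B * D * E - 4 * A * C * FF)
  root <- sqrt((A - C)^2 + B^2)
  semi1 <- -sqrt(num * (A + C + root)) / den
  semi2 <- -sqrt(num * (A + C - root)) / den
  semi_major <- max(semi1, semi2) * sc
  semi_minor <- min(semi1, semi2) * sc
  ## angle of the major axis from +x (standard maths orientation)
  psi <- if (abs(B) < 1e-12 && A <= C) {
    0
  } else if (abs(B) < 1e-12) {
    pi / 2
  } else {
    atan2(C - A - root, B)
  }
  psi_deg <- psi * 180 / pi
  orientation <- wrap90(90 - psi_deg)   # degrees from image vertical
  ovality <- semi_major / semi_minor
  list(long_axis = 2 * semi_major, short_axis = 2 * semi_minor,
       ovality = ovality, orientation_deg = orientation,
       center = c(cx * sc + mx, cy * sc + my),
       orientation_defined = ovality >= 1.02)
}

#' Optic disc torsion from the long-axis orientation
#'
#' Torsion is the signed deviation of the disc's long axis from the
#' fovea-referenced vertical meridian (the perpendicular, through the disc
#' centre, of the disc-fovea line). Positive torsion is inferotemporal:
#' the long axis rotated clockwise from the meridian in the canonical
#' right-eye frame. Near-circular discs have no meaningful long axis, so
#' below the ovality threshold torsion reports 0 with
#' `torsion_defined = FALSE`.
#'
#' @param long_axis_orientation_deg long-axis orientation from image
#'   vertical (as returned by [fit_disc_ellipse()])
#' @param landmarks a `landmarks` object (supplies the disc-fovea meridian)
#' @param ovality ovality index of the fitted margin
#' @param threshold definedness threshold on ovality
#' @return list: `torsion_deg` in (-90, 90], `torsion_defined`
#' @export
torsion <- function(long_axis_orientation_deg, landmarks, ovality = Inf,
                    threshold = 1.02) {
  if (is.finite(ovality) && ovality < threshold) {
    return(list(torsion_deg = 0, torsion_defined = FALSE))
  }
  meridian <- disc_fovea_angle(landmarks)  # meridian tilts with the disc-fovea line
  list(torsion_deg = wrap90(long_axis_orientation_deg - meridian),
       torsion_defined = TRUE)
}

#' Disc tilt from a cross-section along or across the disc-fovea axis
#'
#' Reproduces the cross-sectional protocol: the ONH plane is the chord
#' joining the two clinical disc-margin points on the scan line, the
#' reference plane is the chord joining the Bruch's-membrane interface
#' (depth map) at the same lateral positions, and tilt is the signed angle
#' between the two chords. The horizontal scan runs along the disc-fovea
#' axis (positive tilt = temporal margin deeper); the vertical scan runs
#' perpendicular through the disc centre (positive tilt = inferior margin
#' deeper).
#'
#' @param scan_line `"horizontal"` or `"vertical"`
#' @param landmarks a `landmarks` object (margin x, y, z; z in um)
#' @param dmap a [depth_map()] supplying the BM reference depths
#' @return tilt angle in degrees, signed
#' @export
tilt_from_cross_section <- function(scan_line = c("horizontal", "vertical"),
                                    landmarks, dmap) {
  scan_line <- match.arg(scan_line)
  u <- landmarks$fovea - landmarks$disc_center
  u <- u / sqrt(sum(u^2))                  # disc -> fovea: temporal positive
  if (scan_line == "vertical") u <- c(u[2], -u[1])  # inferior positive
  rel <- sweep(landmarks$disc_margin[, c("x", "y")], 2, landmarks$disc_center)
  proj <- rel %*% u
  perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
  pos <- which(proj > 0)
  neg <- which(proj < 0)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_pp(sprintf("no margin point on the %s side of the %s scan line",
                    if (length(pos) == 0L) "positive" else "negative", scan_line))
  }
  i_pos <- pos[which.min(perp[pos])]
  i_neg <- neg[which.min(perp[neg])]
  pitch <- attr(dmap, "section_pitch_um")
  onh_z <- landmarks$disc_margin[c(i_pos, i_neg), "z"]
  ref_z <- pitch * c(
    depth_at_point(dmap, landmarks$disc_margin[i_pos, c("x", "y")],
                   sprintf("%s-scan positive-side margin", scan_line)),
    depth_at_point(dmap, landmarks$disc_margin[i_neg, c("x", "y")],
                   sprintf("%s-scan negative-side margin", scan_line)))
  dl <- 1000 * (proj[i_pos] - proj[i_neg])   # lateral separation, um
  slope_onh <- (onh_z[1] - onh_z[2]) / dl
  slope_ref <- (ref_z[1] - ref_z[2]) / dl
  (atan(slope_onh) - atan(slope_ref)) * 180 / pi
}

#' Measure the full disc configuration of a volume
#'
#' Ellipse fit of the margin, torsion against the fovea-referenced
#' meridian, and horizontal/vertical tilt from the cross-section chords.
#'
#' @param volume a canonical-orientation `enface_volume` with landmarks
#' @param dmap a [depth_map()]
#' @return object of class `disc_config`: `long_axis_um`, `short_axis_um`,
#'   `ovality`, `torsion_deg`, `torsion_defined`, `h_tilt_deg`, `v_tilt_deg`
#' @export
disc_config <- function(volume, dmap) {
  lm <- volume$landmarks
  if (is.null(lm)) stop_pp("volume carries no landmarks")
  fit <- fit_disc_ellipse(lm$disc_margin[, c("x", "y")])
  tor <- torsion(fit$orientation_deg, lm, fit$ovality)
  structure(
    list(long_axis_um = 1000 * fit$long_axis,
         short_axis_um = 1000 * fit$short_axis,
         ovality = fit$ovality,
         torsion_deg = tor$torsion_deg, torsion_defined = tor$torsion_defined,
         h_tilt_deg = tilt_from_cross_section("horizontal", lm, dmap),
         v_tilt_deg = tilt_from_cross_section("vertical", lm, dmap)),
    class = "disc_config")
}

#' @export
print.disc_config <- function(x, ...) {
  cat(sprintf(
    "disc_config: LD %.0f um / SD %.0f um (ovality %.3f), torsion %.1f deg%s, tilt H %.1f / V %.1f deg\n",
    x$long_axis_um, x$short_axis_um, x$ovality, x$torsion_deg,
    if (x$torsion_defined) "" else " (undefined)", x$h_tilt_deg, x$v_tilt_deg))
  invisible(x)
}
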