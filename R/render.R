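#' Default rendering parameters
#'
#' The defaults reproduce the scanner geometry the analysis assumes: a
#' 12 x 9 mm lateral field rasterised at 512 x 384 pixels (23.4 um pitch)
#' and 1,000 coronal sections of 2.6 um, i.e. a 2.6 mm axial span. The
#' Bruch's membrane (BM) band is brighter than both the overlying retina
#' and the underlying choroid, so successive coronal sections show a
#' shrinking bright island around the deepest point. Speckle is
#' multiplicative log-normal with standard deviation `speckle_sd`.
#'
#' @return named list of parameters; pass overrides to [render_enface()]
#' @export
render_defaults <- function() {
  list(
    nx = 512L, ny = 384L, width_mm = 12, height_mm = 9,
    n_sections = 1000L, section_pitch_um = 2.6,
    band_um = 10.4,          # BM band thickness (4 sections at default pitch)
    reflectivity = c(retina = 0.40, bm = 0.85, choroid = 0.22, cup = 0.12),
    speckle_sd = 0.2,
    z_pad_um = 20,           # anterior padding before the shallowest surface point
    render_disc = TRUE,      # carve the BM opening at the disc
    quantize = TRUE          # snap to the 16-bit grid used by the TIFF writer
  )
}

#' Render a surface + landmarks into an en-face volume
#'
#' Produces the 3D coronal-section stack the detector consumes. For each
#' lateral pixel with rendered surface depth z, the BM band occupies the
#' sections whose depth lies in \[z, z + band\]; sections anterior to z show
#' retina-level reflectivity and sections posterior to the band show
#' choroid-level reflectivity. Inside the disc margin the band is absent
#' (BM opening) and the tissue posterior to the surface is rendered at cup
#' reflectivity. Depths are shifted so the shallowest surface point sits
#' `z_pad_um` behind section 0; section indices are 0-based and increase
#' posteriorly.
#'
#' @param surface a `surface_model`
#' @param landmarks a `landmarks` object (optional; `NULL` renders no disc)
#' @param render_params named list of overrides of [render_defaults()]
#' @param seed integer seed making the speckle reproducible; `NULL` uses the
#'   current RNG state
#' @return an object of class `enface_volume` with fields `intensities`
#'   (ny x nx x n_sections array), `lateral_pitch` (mm/pixel),
#'   `section_pitch_um`, `n_sections`, `origin` (x, y of the top-left pixel
#'   centre), `laterality`, `landmarks`, and `truth` (surface + z offset)
#' @export
render_enface <- function(surface, landmarks = NULL, render_params = list(),
                          seed = NULL) {
  p <- modifyList(render_defaults(), render_params)
  px <- p$width_mm / p$nx
  py <- p$height_mm / p$ny
  if (abs(px - py) > 1e-9) {
    stop_pp("anisotropic rasters are not supported: width_mm/nx must equal height_mm/ny")
  }
  if (p$band_um < 2 * p$section_pitch_um) {
    stop_pp("`band_um` must span at least 2 sections")
  }
  refl <- p$reflectivity
  if (!(refl[["bm"]] > refl[["choroid"]] && refl[["bm"]] > refl[["retina"]])) {
    stop_pp("reflectivities must satisfy bm > retina and bm > choroid")
  }
  if (p$speckle_sd < 0) stop_pp("`speckle_sd` must be >= 0")

  xs <- seq(-p$width_mm / 2 + px / 2, p$width_mm / 2 - px / 2, length.out = p$nx)
  ys <- seq(p$height_mm / 2 - py / 2, -p$height_mm / 2 + py / 2, length.out = p$ny)
  X <- matrix(xs, p$ny, p$nx, byrow = TRUE)
  Y <- matrix(ys, p$ny, p$nx)

  Z <- matrix(surface_depth(surface, as.vector(X), as.vector(Y)), p$ny, p$nx)
  z_offset <- p$z_pad_um - min(Z)       # rendered depth = Z + z_offset
  Zr <- Z + z_offset
  span <- p$n_sections * p$section_pitch_um
  over <- Zr + p$band_um > span
  if (any(over)) {
    k <- which(over)[1]
    ij <- arrayInd(k, dim(Zr))
    stop_pp(sprintf(
      "surface depth exceeds the axial span at pixel (row %d, col %d): %.1f + band %.1f > %.1f um",
      ij[1], ij[2], Zr[k], p$band_um, span))
  }

  in_disc <- matrix(FALSE, p$ny, p$nx)
  if (p$render_disc && !is.null(landmarks)) {
    th <- landmarks$disc_plane_tilt_deg * pi / 180
    a <- landmarks$tilt_direction_deg * pi / 180
    dhat <- c(cos(a), -sin(a))
    ahat <- landmarks$disc_plane_tilt_axis
    dx <- X - landmarks$disc_center[1]
    dy <- Y - landmarks$disc_center[2]
    u <- (dx * dhat[1] + dy * dhat[2]) / (landmarks$disc_radius * cos(th))
    v <- (dx * ahat[1] + dy * ahat[2]) / landmarks$disc_radius
    in_disc <- u^2 + v^2 <= 1
  }

  render <- function() {
    ## pre-quantised reflectivities keep noiseless volumes exactly on the
    ## 16-bit grid without a per-voxel rounding pass
    rq <- if (p$quantize) round(refl * 65535) / 65535 else refl
    vol <- array(0, dim = c(p$ny, p$nx, p$n_sections))
    d_bm <- rq[["bm"]] - rq[["retina"]]
    d_ch <- rq[["choroid"]] - rq[["bm"]]
    d_cup <- rq[["cup"]] - rq[["retina"]]
    any_disc <- any(in_disc)
    for (s in seq_len(p$n_sections)) {
      su <- (s - 1L) * p$section_pitch_um
      post <- su >= Zr                      # at or posterior to the interface
      band <- post & (su <= Zr + p$band_um)
      sec <- rq[["retina"]] + d_bm * post + d_ch * (post & !band)
      if (any_disc) sec[in_disc] <- rq[["retina"]] + d_cup * post[in_disc]
      if (p$speckle_sd > 0) {
        sec <- sec * exp(rnorm(length(sec), -p$speckle_sd^2 / 2, p$speckle_sd))
        sec[sec > 1] <- 1
        if (p$quantize) sec <- round(sec * 65535) / 65535
      }
      vol[, , s] <- sec
    }
    vol
  }
  vol <- if (is.null(seed)) render() else withr::with_seed(as.integer(seed), render())

  structure(
    list(intensities = vol, lateral_pitch = px,
         section_pitch_um = p$section_pitch_um, n_sections = p$n_sections,
         origin = c(xs[1], ys[1]),
         laterality = if (is.null(landmarks)) "right" else landmarks$laterality,
         landmarks = landmarks,
         truth = list(surface = surface, z_offset_um = z_offset)),
    class = "enface_volume")
}

#' Mirror a volume about the vertical axis
#'
#' Flips the intensity columns and all landmark x coordinates; used to turn
#' canonical right-eye phantoms into left-eye volumes and to canonicalize
#' left-eye volumes on ingestion.
#'
#' @param volume an `enface_volume`
#' @return mirrored `enface_volume` with toggled laterality
#' @export
mirror_volume <- function(volume) {
  v <- volume
  nx <- ncol(v$intensities)
  v$intensities <- v$intensities[, nx:1, , drop = FALSE]
  v$origin[1] <- -(v$origin[1] + (nx - 1) * v$lateral_pitch)
  if (!is.null(v$landmarks)) v$landmarks <- mirror_landmarks(v$landmarks)
  if (!is.null(v$truth$surface)) {
    v$truth$surface$bump_center[1] <- -v$truth$surface$bump_center[1]
    v$truth$surface$true_dpe[1] <- -v$truth$surface$true_dpe[1]
  }
  v$laterality <- if (identical(v$laterality, "right")) "left" else "right"
  v
}

#' Express a volume in the canonical right-eye frame
#'
#' Left-eye volumes are mirrored about the vertical axis; right-eye volumes
#' are returned unchanged. All measurement functions assume canonical
#' orientation.
#'
#' @param volume an `enface_volume`
#' @return an `enface_volume` with `laterality == "right"`
#' @export
canonicalize_volume <- function(volume) {
  if (identical(volume$laterality, "left")) mirror_volume(volume) else volume
}

#' @export
print.enface_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "enface_volume (%s eye): %d x %d pixels (%.1f um pitch), %d sections x %.1f um (span %.2f mm)\n",
    x$laterality, d[2], d[1], 1000 * x$lateral_pitch, x$n_sections,
    x$section_pitch_um, x$n_sections * x$section_pitch_um / 1000))
  invisible(x)
}
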