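## desk-scale rendering parameters shared across tests: 96 x 72 raster
## (125 um pixels) over the 12 x 9 mm field, short axial span, no speckle
## unless a test asks for it. The BM band is thickened with the pixel
## pitch (31.2 um = 12 sections) so the band ring on sloped surface
## regions stays resolvable at the coarse raster, as it is at the
## clinical 23 um pitch with the default band.
coarse_rp <- function(...) {
  modifyList(list(nx = 96L, ny = 72L, n_sections = 200L, speckle_sd = 0,
                  band_um = 31.2),
             list(...))
}

## flat-base single-bump phantom with landmarks; the workhorse fixture
make_phantom <- function(bump = c(0, -2.7), amp = 200, sigma = 2,
                         base_radius = Inf, tilt_deg = 0, direction_deg = 0,
                         disc_fovea_angle_deg = 4, rp = coarse_rp(),
                         seed = 1, render = TRUE) {
  s <- build_surface(base_radius, bump, amp, sigma)
  lm <- place_landmarks(s, disc_fovea_angle_deg = disc_fovea_angle_deg,
                        tilt_spec = list(tilt_deg = tilt_deg,
                                         direction_deg = direction_deg))
  v <- if (render) render_enface(s, lm, rp, seed = seed)
  list(surface = s, landmarks = lm, volume = v)
}

## cohort spec with every dispersion zeroed: draws equal the means
degenerate_cohort_spec <- function(class = "near_fovea") {
  spec <- default_cohort_spec()
  spec$disc_offset[2] <- 0
  spec$disc_radius[2] <- 0
  spec$disc_fovea_angle[2] <- 0
  spec$bump_sigma[2] <- 0
  for (g in names(spec$groups)) {
    spec$groups[[g]]$age[2] <- 0
    spec$groups[[g]]$se[2] <- 0
    spec$groups[[g]]$axial_length[2] <- 0
    spec$groups[[g]]$bump_amplitude[2] <- 0
    spec$groups[[g]]$tilt[2] <- 0
    probs <- setNames(rep(0, 4), names(spec$groups[[g]]$location_probs))
    probs[class] <- 1
    spec$groups[[g]]$location_probs <- probs
  }
  for (cl in names(spec$location_geometry)) {
    geo <- spec$location_geometry[[cl]]
    for (f in intersect(c("dist_fovea", "dist_disc", "angle"), names(geo))) {
      geo[[f]][2] <- 0
    }
    spec$location_geometry[[cl]] <- geo
  }
  spec
}
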