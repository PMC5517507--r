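test_that("segment_interface handles degenerate and clean sections", {
  ## uniform dark section: empty mask, not an error
  dark <- matrix(0.05, 72, 96)
  expect_false(any(segment_interface(dark, lateral_pitch = 0.125)))

  ## uniform speckled choroid: still empty under the contrast guard
  set.seed(8)
  spk <- 0.22 * exp(rnorm(72 * 96, 0, 0.2))
  expect_false(any(segment_interface(matrix(pmin(spk, 1), 72, 96),
                                     lateral_pitch = 0.125)))

  ## noiseless mid-bump section: mask equals the analytic level set of
  ## z(x, y) within a 1-pixel dilation
  ph <- make_phantom(bump = c(0, -1), amp = 300, sigma = 2, render = FALSE)
  rp <- coarse_rp()
  v <- render_enface(ph$surface, NULL, rp)
  mid <- 70L  # section inside the bump's depth range
  ## raw threshold mask (no smoothing/closing/area filter): at the coarse
  ## desk raster the mid-bump band ring is about one pixel wide, so the
  ## robustness filters would prune it — the raw mask is the level-set
  ## comparison
  mask <- segment_interface(v$intensities[, , mid + 1L],
                            list(median_size = 0L, closing_radius_px = 0L,
                                 min_area_mm2 = 0),
                            lateral_pitch = v$lateral_pitch)
  ax <- poleprofile:::pixel_axes(v)
  Z <- outer(ax$y, ax$x, function(yy, xx) surface_depth(ph$surface, xx, yy))
  zr <- Z - min(Z) + render_defaults()$z_pad_um
  su <- mid * v$section_pitch_um
  analytic <- su >= zr & su <= zr + coarse_rp()$band_um
  grown <- EBImage::dilate(analytic, EBImage::makeBrush(3, "box")) > 0
  shrunk <- EBImage::erode(analytic, EBImage::makeBrush(3, "box")) > 0
  expect_true(all(mask[shrunk]))        # no erosion beyond 1 pixel
  expect_true(all(!mask[!grown]))       # no growth beyond 1 pixel
})

test_that("segmentation of speckled sections stays close to the clean mask", {
  ph <- make_phantom(bump = c(0, -1), amp = 300, sigma = 2, render = FALSE)
  rp <- coarse_rp(nx = 288L, ny = 216L)   # 42 um pixels resolve the island
  clean <- render_enface(ph$surface, NULL, rp)
  noisy <- render_enface(ph$surface, NULL, modifyList(rp, list(speckle_sd = 0.3)),
                         seed = 21)
  ## compare on a near-peak section, where the interface island is the
  ## wide shrinking cap the examiner actually tracks
  p <- render_defaults()
  top <- floor((p$z_pad_um + 300) / clean$section_pitch_um) - 8L
  m_clean <- segment_interface(clean$intensities[, , top + 1L],
                               list(threshold = volume_threshold(clean)),
                               lateral_pitch = clean$lateral_pitch)
  m_noisy <- segment_interface(noisy$intensities[, , top + 1L],
                               list(threshold = volume_threshold(noisy)),
                               lateral_pitch = noisy$lateral_pitch)
  dice <- 2 * sum(m_clean & m_noisy) / (sum(m_clean) + sum(m_noisy))
  expect_gte(dice, 0.9)
})

test_that("the depth map reproduces the rasterised surface", {
  ## flat noiseless surface: constant map
  flat <- make_phantom(amp = 0, rp = coarse_rp(n_sections = 30))
  dm <- depth_map(flat$volume)
  lmk <- flat$landmarks
  ax <- poleprofile:::pixel_axes(flat$volume)
  dx <- outer(ax$y * 0, ax$x - lmk$disc_center[1], "+")
  dy <- outer(ax$y - lmk$disc_center[2], ax$x * 0, "+")
  outside <- (dx^2 + dy^2) > (lmk$disc_radius * 1.3)^2
  expect_identical(length(unique(dm[outside])), 1L)

  ## rendered bump: the unsmoothed map equals rasterised z / pitch within
  ## 1 section (mask smoothing trades this pointwise bound for robustness)
  ph <- make_phantom(bump = c(1.5, 0.5), amp = 350, sigma = 1.8)
  dm <- depth_map(ph$volume, list(median_size = 0L, closing_radius_px = 0L,
                                  min_area_mm2 = 0))
  v <- ph$volume
  ax <- poleprofile:::pixel_axes(v)
  Z <- outer(ax$y, ax$x, function(yy, xx) surface_depth(ph$surface, xx, yy))
  zr <- Z - min(Z) + render_defaults()$z_pad_um
  expected <- floor((zr + coarse_rp()$band_um) / v$section_pitch_um)
  lmk <- ph$landmarks
  dx <- outer(ax$y * 0, ax$x - lmk$disc_center[1], "+")
  dy <- outer(ax$y - lmk$disc_center[2], ax$x * 0, "+")
  outside <- (dx^2 + dy^2) > (lmk$disc_radius * 1.3)^2
  interior <- outside
  interior[c(1, nrow(dm)), ] <- FALSE   # border pixels see edge effects of
  interior[, c(1, ncol(dm))] <- FALSE   # the mask smoothing
  expect_true(all(abs(dm[interior] - expected[interior]) <= 1))

  ## pixels never segmented are missing; a dark corner does not move the DPE
  v2 <- ph$volume
  v2$intensities[1:10, 1:10, ] <- 0
  dm2 <- depth_map(v2)
  expect_true(all(is.na(dm2[2:9, 2:9])))
  d1 <- locate_dpe(ph$volume)
  d2 <- locate_dpe(v2)
  expect_identical(d2$section_index, d1$section_index)
  expect_equal(d2$center, d1$center)
})

test_that("locate_dpe recovers ground truth and flags degeneracies", {
  ## noiseless single bump: within 1 pixel laterally, 1 section in depth
  ph <- make_phantom(bump = c(-1.2, -2.1), amp = 260, sigma = 1.7)
  d <- locate_dpe(ph$volume)
  expect_lt(max(abs(d$center - ph$surface$true_dpe[1:2])),
            ph$volume$lateral_pitch + 1e-9)
  dm <- depth_map(ph$volume)
  ref <- dm[2, 2]   # far-corner background depth
  relief <- (d$section_index - ref) * ph$volume$section_pitch_um
  expect_lt(abs(relief - ph$surface$true_dpe[3]), ph$volume$section_pitch_um + 1e-9)

  ## two bumps: the deeper one (200 um) wins over the 120 um one
  s2 <- build_surface(Inf, c(-2, -1), 200, 1.5,
                      extra_bumps = list(list(center = c(2, 1),
                                              amplitude = 120, sigma = 1.5)))
  expect_lt(sqrt(sum((s2$true_dpe[1:2] - c(-2, -1))^2)), 0.05)
  lm2 <- place_landmarks(s2)
  v2 <- render_enface(s2, lm2, coarse_rp())
  d2 <- locate_dpe(v2)
  expect_lt(sqrt(sum((d2$center - s2$true_dpe[1:2])^2)), 2 * v2$lateral_pitch)

  ## flat surface: common section, centre near the field centroid, flagged
  flat <- make_phantom(amp = 0, rp = coarse_rp(n_sections = 30))
  df <- locate_dpe(flat$volume)
  expect_true("low_relief" %in% df$quality)
  expect_lt(abs(df$center[2]), 0.5)    # near the field mid-height

  ## no interface anywhere: detection error
  dark <- flat$volume
  dark$intensities[] <- 0.01
  expect_error(locate_dpe(dark), "no interface")
})

test_that("the detector is translation-equivariant", {
  rp <- coarse_rp()
  base <- make_phantom(bump = c(0, -1), amp = 220, sigma = 1.6, rp = rp)
  shift <- c(0.5, 0.75)   # multiples of the 0.125 mm pixel pitch
  moved <- make_phantom(bump = c(0, -1) + shift, amp = 220, sigma = 1.6, rp = rp)
  d0 <- locate_dpe(base$volume)
  d1 <- locate_dpe(moved$volume)
  expect_lt(max(abs((d1$center - d0$center) - shift)),
            base$volume$lateral_pitch + 1e-9)
})

test_that("detected depth is monotone in bump amplitude", {
  rp <- coarse_rp()
  depths <- vapply(c(50, 120, 200, 300, 400), function(a) {
    ph <- make_phantom(bump = c(0.5, -0.5), amp = a, sigma = 1.8, rp = rp)
    locate_dpe(ph$volume)$section_index
  }, numeric(1))
  expect_true(all(diff(depths) >= 0))
})

test_that("detected centres are stable across seeded speckle re-scans", {
  spec <- degenerate_cohort_spec()
  rp <- coarse_rp(n_sections = 350, speckle_sd = 0.2)
  eyes <- simulate_cohort(spec, n = 10, seed = 31, render = FALSE)
  truth <- eyes[[10]]$truth
  centers <- t(vapply(1:20, function(i) {
    r <- rescan(truth, list(lateral_sd_mm = 0), seed = 300 + i,
                render_params = rp)
    locate_dpe(r$volume)$center
  }, numeric(2)))
  expect_lt(sd(centers[, 1]) * 1000, 100)   # SD under 100 um per axis
  expect_lt(sd(centers[, 2]) * 1000, 100)
})
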