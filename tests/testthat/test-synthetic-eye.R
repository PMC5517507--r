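test_that("surface depth and true-DPE localisation follow the bump geometry", {
  ## no bump: the base tangency point is the deepest point at depth 0
  s0 <- build_surface(12, c(0, 0), 0, 1)
  expect_equal(unname(s0$true_dpe), c(0, 0, 0), tolerance = 1e-6)

  ## flat base: the bump is the maximum, exactly at its centre
  s1 <- build_surface(Inf, c(0, -2.7), 200, 2)
  expect_equal(unname(s1$true_dpe), c(0, -2.7, 200), tolerance = 1e-9)

  ## curved base: dense-grid argmax is the oracle for the summed surface
  s2 <- build_surface(12, c(1.5, -2.0), 150, 1.5)
  xs <- seq(-6, 6, by = 0.01)
  ys <- seq(-4.5, 4.5, by = 0.01)
  best <- c(NA, NA, -Inf)
  for (yy in split(ys, ceiling(seq_along(ys) / 150))) {
    z <- outer(yy, xs, function(a, b) surface_depth(s2, b, a))
    k <- which.max(z)
    if (z[k] > best[3]) {
      ij <- arrayInd(k, dim(z))
      best <- c(xs[ij[2]], yy[ij[1]], z[k])
    }
  }
  expect_equal(unname(s2$true_dpe[1:2]), best[1:2], tolerance = 0.011)
  expect_equal(unname(s2$true_dpe[3]), best[3], tolerance = 0.01)
})

test_that("surface parameter validation rejects bad inputs", {
  expect_error(build_surface(Inf, c(0, 0), 100, 0), "bump_sigma")
  expect_error(build_surface(Inf, c(0, 0), -5, 1), "bump_amplitude")
  expect_error(build_surface(-3, c(0, 0), 100, 1), "base_radius")
  expect_error(build_surface(5, c(0, 0), 100, 1), "half-diagonal")
})

test_that("landmark placement reproduces the requested disc-fovea geometry", {
  s <- build_surface(Inf, c(0, -2), 100, 2)
  ## the recomputed disc-fovea angle equals the input to machine precision,
  ## including the reported near-fovea subgroup mean used as canonical input
  for (dfa in c(2, 4, 6.4)) {
    lm <- place_landmarks(s, disc_fovea_angle_deg = dfa)
    expect_equal(disc_fovea_angle(lm), dfa, tolerance = 1e-9)
  }
  lm <- place_landmarks(s)
  expect_gte(nrow(lm$disc_margin), 8)
  expect_error(place_landmarks(s, disc_offset = 0.5, disc_radius = 0.8),
               "overlap")

  ## untilted disc: all margin depths follow the surface, no plane offset
  z_surf <- surface_depth(s, lm$disc_margin[, "x"], lm$disc_margin[, "y"])
  expect_equal(unname(lm$disc_margin[, "z"]), unname(z_surf), tolerance = 1e-9)
})

test_that("tilted margin circles live in the disc plane (sin/cos geometry)", {
  s <- build_surface(Inf, c(0, 0), 0, 1)
  r <- 0.8
  th <- 10
  lm <- place_landmarks(s, disc_radius = r,
                        tilt_spec = list(tilt_deg = th, direction_deg = 0))
  ## z span along the tilt direction is 2 r sin(tilt); lateral span is
  ## 2 r cos(tilt), so chord-measured tilt recovers the plane tilt exactly
  expect_equal(max(lm$disc_margin[, "z"]) - min(lm$disc_margin[, "z"]),
               2 * r * 1000 * sin(th * pi / 180), tolerance = 1e-6)
  dhat <- c(1, 0)
  proj <- (lm$disc_margin[, "x"] - lm$disc_center[1]) * dhat[1]
  expect_equal(max(proj) - min(proj), 2 * r * cos(th * pi / 180),
               tolerance = 1e-6)
  slope <- (2 * r * 1000 * sin(th * pi / 180)) / (2 * r * 1000 * cos(th * pi / 180))
  expect_equal(atan(slope) * 180 / pi, th, tolerance = 1e-9)
})

test_that("mirroring landmarks twice is the identity and flips x once", {
  s <- build_surface(Inf, c(1, -2), 150, 2)
  lm <- place_landmarks(s, tilt_spec = list(tilt_deg = 8, direction_deg = 25))
  ml <- mirror_landmarks(lm)
  expect_identical(ml$laterality, "left")
  expect_equal(ml$disc_center[1], -lm$disc_center[1])
  expect_equal(ml$disc_margin[, "z"], lm$disc_margin[, "z"])
  back <- mirror_landmarks(ml)
  expect_equal(back$disc_center, lm$disc_center)
  expect_equal(back$disc_margin, lm$disc_margin)
  expect_equal(back$tilt_direction_deg, lm$tilt_direction_deg)
})

test_that("rendering honours the layer model and is seed-deterministic", {
  ## flat surface, no noise: within a layer every section is uniform and
  ## the deepest section containing band signal is shared by all pixels
  ph <- make_phantom(amp = 0, rp = coarse_rp(n_sections = 40), render = FALSE)
  v <- render_enface(ph$surface, NULL, coarse_rp(n_sections = 40))
  rng <- apply(v$intensities, 3, function(m) diff(range(m)))
  expect_true(all(rng < 1e-12))
  refl <- render_defaults()$reflectivity
  bm_q <- round(refl[["bm"]] * 65535) / 65535
  last_bm <- max(which(apply(v$intensities, 3, max) == bm_q))
  expect_true(all(v$intensities[, , last_bm] == bm_q))

  ## single bump, no noise: the last section with band signal contains
  ## exactly the pixels of the analytic level set of z(x, y)
  ph <- make_phantom(bump = c(1, -1), amp = 300, sigma = 1.8)
  v <- ph$volume
  p <- modifyList(render_defaults(), coarse_rp())
  bright <- v$intensities == bm_q
  last <- max(which(apply(bright, 3, any)))
  ax <- poleprofile:::pixel_axes(v)
  Z <- outer(ax$y, ax$x, function(yy, xx) surface_depth(ph$surface, xx, yy))
  zr <- Z - min(Z) + p$z_pad_um
  analytic <- zr + p$band_um >= (last - 1) * v$section_pitch_um
  rendered <- bright[, , last]
  ## exclude the carved disc opening from the comparison
  lmk <- ph$landmarks
  dx <- outer(ax$y * 0, ax$x - lmk$disc_center[1], "+")
  dy <- outer(ax$y - lmk$disc_center[2], ax$x * 0, "+")
  outside <- (dx^2 + dy^2) > (lmk$disc_radius * 1.2)^2
  expect_identical(rendered[outside], analytic[outside])

  ## same seed twice: bit-identical; different seed with speckle: not
  rp <- coarse_rp(speckle_sd = 0.2, n_sections = 60)
  s <- build_surface(Inf, c(0, 0), 100, 2)
  v1 <- render_enface(s, NULL, rp, seed = 42)
  v2 <- render_enface(s, NULL, rp, seed = 42)
  v3 <- render_enface(s, NULL, rp, seed = 43)
  expect_identical(v1$intensities, v2$intensities)
  expect_false(identical(v1$intensities, v3$intensities))
})

test_that("rendering rejects surfaces exceeding the axial span", {
  s <- build_surface(Inf, c(0, 0), 800, 2)
  expect_error(render_enface(s, NULL, coarse_rp(n_sections = 100)),
               "axial span")
})

test_that("a degenerate cohort spec reproduces its means exactly", {
  spec <- degenerate_cohort_spec()
  eyes <- simulate_cohort(spec, n = 10, seed = 5, render = FALSE)
  groups <- vapply(eyes, function(e) e$truth$group, character(1))
  em <- eyes[[which(groups == "emmetropic")[1]]]$truth
  my <- eyes[[which(groups == "myopic")[1]]]$truth
  expect_equal(em$covariates$age_years, spec$groups$emmetropic$age[1])
  expect_equal(em$covariates$axial_length_mm,
               spec$groups$emmetropic$axial_length[1])
  expect_equal(my$covariates$se_diopter, spec$groups$myopic$se[1])
  expect_equal(my$surface$bump_sigma, spec$bump_sigma[1])
  expect_equal(my$landmarks$disc_radius, spec$disc_radius[1])
  expect_equal(disc_fovea_angle(my$landmarks), spec$disc_fovea_angle[1],
               tolerance = 1e-9)
})

test_that("cohort draws respect group thresholds and the reference split", {
  eyes <- simulate_cohort(n = 165, seed = 3, render = FALSE)
  groups <- vapply(eyes, function(e) e$truth$group, character(1))
  expect_identical(as.integer(table(groups)[c("emmetropic", "myopic")]),
                   c(40L, 125L))
  for (e in eyes) {
    al <- e$truth$covariates$axial_length_mm
    se <- e$truth$covariates$se_diopter
    expect_lte(al, 30)
    if (e$truth$group == "myopic") {
      expect_true(al > 24 && se < -2)
    } else {
      expect_true(al < 24 && se > 0.5)
    }
  }
  ## inferiorly displaced bumps give positive mean disc-DPE angles
  ang <- vapply(eyes, function(e) {
    angle_inferior_positive(e$truth$landmarks$disc_center, e$truth$true_dpe[1:2])
  }, numeric(1))
  cats <- vapply(eyes, function(e) as.character(e$truth$true_category),
                 character(1))
  expect_gt(mean(ang[cats == "inferior"]), 0)
  if (any(cats == "superior")) expect_lt(mean(ang[cats == "superior"]), 0)
})

test_that("rescan reproduces anatomy with fresh noise and tracks jitter", {
  spec <- degenerate_cohort_spec()
  rp <- coarse_rp(n_sections = 350, speckle_sd = 0)
  eyes <- simulate_cohort(spec, n = 2, seed = 9, render = TRUE,
                          render_params = rp)
  my <- eyes[[2]]
  ## jitter 0, noise 0: bit-identical re-render
  r0 <- rescan(my$truth, list(lateral_sd_mm = 0), seed = 77, render_params = rp)
  expect_identical(r0$volume$intensities, my$volume$intensities)

  ## jitter 0, noise > 0, two seeds: volumes differ, detected DPE agrees
  rp_n <- modifyList(rp, list(speckle_sd = 0.2))
  ra <- rescan(my$truth, list(lateral_sd_mm = 0), seed = 101, render_params = rp_n)
  rb <- rescan(my$truth, list(lateral_sd_mm = 0), seed = 102, render_params = rp_n)
  expect_false(identical(ra$volume$intensities, rb$volume$intensities))
  da <- locate_dpe(ra$volume)
  db <- locate_dpe(rb$volume)
  expect_lt(sqrt(sum((da$center - db$center)^2)), 2 * ra$volume$lateral_pitch)

  ## drawn fixation offset moves the detected DPE by about the offset
  rj <- rescan(my$truth, list(lateral_sd_mm = 0.2), seed = 55, render_params = rp)
  d0 <- locate_dpe(my$volume)
  dj <- locate_dpe(rj$volume)
  expect_lt(max(abs(unname(dj$center - d0$center) - unname(rj$offset_mm))),
            1.5 * rj$volume$lateral_pitch)
})
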