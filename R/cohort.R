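## truncated-normal draw by rejection; sd = 0 returns the mean exactly
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  for (i in 1:1000) {
    out[need] <- rnorm(length(need), mean, sd)
    need <- which(out < lo | out > hi)
    if (length(need) == 0L) return(out)
  }
  pmin(pmax(out, lo), hi)
}

#' Default cohort simulation parameters
#'
#' Per-group distributions shaped like the reference cohort: emmetropic
#' eyes (axial length < 24 mm, SE > 0.5 D) with the deepest point mostly
#' near the disc, and myopic eyes (axial length > 24 mm, SE < -2 D, capped
#' at 30 mm) with the deepest point predominantly in the inferior
#' hemisphere, larger bump amplitudes and stronger disc tilt. Values are
#' `c(mean, sd)` pairs unless noted; DPE location classes are drawn from
#' `location_probs` and the bump is placed by rejection sampling inside the
#' drawn class region.
#'
#' @return nested list consumed by [simulate_cohort()]
#' @export
default_cohort_spec <- function() {
  list(
    base_radius = 60,          # mm; residual curvature of the flattened stack
    disc_offset = c(4.5, 0.25),
    disc_radius = c(0.8, 0.08),
    disc_fovea_angle = c(7, 3), disc_fovea_angle_range = c(0.5, 15),
    bump_sigma = c(2, 0.3), bump_sigma_range = c(1.5, 3),
    groups = list(
      emmetropic = list(
        prop = 40 / 165,
        age = c(59.75, 11.88),
        se = c(0.243, 1.39), se_range = c(0.51, 6),
        axial_length = c(23.11, 0.62), axial_length_range = c(21, 23.99),
        prop_right = 26 / 40,
        location_probs = c(near_fovea = 0.225, superior = 0.075,
                           inferior = 0.225, near_disc = 0.475),
        bump_amplitude = c(120, 50), bump_amplitude_range = c(30, 380),
        tilt = c(4, 3), tilt_range = c(0, 20)),
      myopic = list(
        prop = 125 / 165,
        age = c(43.70, 11.96),
        se = c(-4.34, 3.54), se_range = c(-15, -2.01),
        axial_length = c(26.02, 1.33), axial_length_range = c(24.01, 30),
        prop_right = 55 / 125,
        location_probs = c(near_fovea = 0.312, superior = 0.056,
                           inferior = 0.432, near_disc = 0.200),
        bump_amplitude = c(250, 80), bump_amplitude_range = c(30, 380),
        tilt = c(12, 6), tilt_range = c(0, 25))),
    ## disc-DPE polar geometry per location class: c(mean, sd) of the
    ## inferior-positive angle and of the distance (mm) from the landmark
    location_geometry = list(
      near_fovea = list(dist_fovea = c(1.0, 0.4), dist_range = c(0.2, 2.9)),
      near_disc = list(dist_disc = c(1.9, 0.5), dist_range = c(0.9, 2.9)),
      inferior = list(angle = c(37, 15), dist_disc = c(3.9, 1.0),
                      dist_range = c(3.1, 5.6)),
      superior = list(angle = c(-23, 8), dist_disc = c(3.6, 0.9),
                      dist_range = c(3.1, 5.6))))
}

draw_bump_center <- function(class, geom, landmarks) {
  g <- geom[[class]]
  for (i in 1:200) {
    p <- switch(class,
      near_fovea = {
        r <- rnorm_trunc(1, g$dist_fovea[1], g$dist_fovea[2],
                         g$dist_range[1], g$dist_range[2])
        a <- runif(1, 0, 2 * pi)
        landmarks$fovea + r * c(cos(a), sin(a))
      },
      near_disc = {
        r <- rnorm_trunc(1, g$dist_disc[1], g$dist_disc[2],
                         g$dist_range[1], g$dist_range[2])
        a <- runif(1, 0, 2 * pi)
        landmarks$disc_center + r * c(cos(a), sin(a))
      },
      {
        al <- rnorm(1, g$angle[1], g$angle[2])
        r <- rnorm_trunc(1, g$dist_disc[1], g$dist_disc[2],
                         g$dist_range[1], g$dist_range[2])
        landmarks$disc_center +
          r * c(cos(al * pi / 180), -sin(al * pi / 180))
      })
    if (abs(p[1]) > 5 || abs(p[2]) > 3.4) next   # keep the bump well inside the field
    if (as.character(classify_dpe(p, landmarks)$label) == class) return(p)
  }
  stop_pp(sprintf("could not place a bump in the %s region", class))
}

## analytic chord-based tilt truth: same margin-point selection as the
## measurement, but exact surface depths instead of the rasterised map
chord_tilt_truth <- function(surface, landmarks, scan_line) {
  u <- landmarks$fovea - landmarks$disc_center
  u <- u / sqrt(sum(u^2))
  if (scan_line == "vertical") u <- c(u[2], -u[1])
  rel <- sweep(landmarks$disc_margin[, c("x", "y")], 2, landmarks$disc_center)
  proj <- rel %*% u
  perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
  i_pos <- which(proj > 0)[which.min(perp[proj > 0])]
  i_neg <- which(proj < 0)[which.min(perp[proj < 0])]
  onh_z <- landmarks$disc_margin[c(i_pos, i_neg), "z"]
  ref_z <- surface_depth(surface,
                         landmarks$disc_margin[c(i_pos, i_neg), "x"],
                         landmarks$disc_margin[c(i_pos, i_neg), "y"])
  dl <- 1000 * (proj[i_pos] - proj[i_neg])
  (atan((onh_z[1] - onh_z[2]) / dl) - atan((ref_z[1] - ref_z[2]) / dl)) * 180 / pi
}

## analytic disc-configuration truth for a tilted disc
disc_truth <- function(surface, landmarks) {
  th <- landmarks$disc_plane_tilt_deg * pi / 180
  phi <- disc_fovea_angle(landmarks)
  ovality <- 1 / cos(th)
  list(
    true_ovality = ovality,
    true_torsion_deg = if (ovality >= 1.02) {
      wrap90(landmarks$tilt_direction_deg - phi)
    } else 0,
    true_h_tilt_deg = chord_tilt_truth(surface, landmarks, "horizontal"),
    true_v_tilt_deg = chord_tilt_truth(surface, landmarks, "vertical"))
}

#' Simulate a cohort of ground-truthed eyes
#'
#' Draws per-eye parameters from the group distributions of `cohort_spec`,
#' builds the surface and landmarks, records the full ground truth and
#' (optionally) renders the en-face volume. Group sizes follow the
#' configured group proportions; left eyes are rendered mirrored. Draws violating a
#' group's axial-length/SE thresholds (including the 30 mm exclusion) are
#' resampled inside the truncated distributions; the disc plane is tilted
#' toward the bump (the localized elongation pulling on the disc).
#'
#' @param cohort_spec see [default_cohort_spec()]
#' @param n number of eyes
#' @param seed integer seed; every draw is reproducible under it
#' @param render render volumes (set `FALSE` for truth-only cohorts)
#' @param render_params overrides of [render_defaults()]
#' @return list of eyes, each a list with `truth` (class `eye_truth`) and
#'   `volume` (an `enface_volume` or `NULL`)
#' @export
simulate_cohort <- function(cohort_spec = default_cohort_spec(), n = 165,
                            seed = 1, render = TRUE, render_params = list()) {
  if (n < 1L) stop_pp("`n` must be >= 1")
  spec <- cohort_spec
  n_em <- round(n * spec$groups$emmetropic$prop)
  groups <- rep(c("emmetropic", "myopic"), c(n_em, n - n_em))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      g <- spec$groups[[groups[i]]]
      age <- rnorm_trunc(1, g$age[1], g$age[2], 18, 90)
      se <- rnorm_trunc(1, g$se[1], g$se[2], g$se_range[1], g$se_range[2])
      al <- rnorm_trunc(1, g$axial_length[1], g$axial_length[2],
                        g$axial_length_range[1], g$axial_length_range[2])
      laterality <- if (g$prop_right == 1 ||
                        (g$prop_right > 0 && runif(1) < g$prop_right)) {
        "right"
      } else "left"
      disc_offset <- rnorm_trunc(1, spec$disc_offset[1], spec$disc_offset[2],
                                 3.5, 5.5)
      disc_radius <- rnorm_trunc(1, spec$disc_radius[1], spec$disc_radius[2],
                                 0.6, 1.1)
      dfa <- rnorm_trunc(1, spec$disc_fovea_angle[1], spec$disc_fovea_angle[2],
                         spec$disc_fovea_angle_range[1],
                         spec$disc_fovea_angle_range[2])
      flat <- build_surface(spec$base_radius, c(0, 0), 0, 1, axial_length = al)
      lm0 <- place_landmarks(flat, disc_offset, disc_radius, dfa,
                             tilt_spec = list(tilt_deg = 0, direction_deg = 0),
                             laterality = "right")
      class <- sample(names(g$location_probs), 1, prob = g$location_probs)
      ## bump_amplitude is drawn as relief above the local base depth, so
      ## the bump peak (not the base tangency point) is the deepest point;
      ## redraw until the true DPE falls in the intended location class
      R <- spec$base_radius
      surface <- NULL
      for (try in 1:20) {
        bump <- draw_bump_center(class, spec$location_geometry, lm0)
        relief <- rnorm_trunc(1, g$bump_amplitude[1], g$bump_amplitude[2],
                              g$bump_amplitude_range[1], g$bump_amplitude_range[2])
        zb <- if (is.finite(R)) 1000 * (sqrt(R^2 - sum(bump^2)) - R) else 0
        amp <- relief - zb
        sig <- rnorm_trunc(1, spec$bump_sigma[1], spec$bump_sigma[2],
                           spec$bump_sigma_range[1], spec$bump_sigma_range[2])
        cand <- build_surface(R, bump, amp, sig, axial_length = al)
        if (as.character(classify_dpe(cand$true_dpe[1:2], lm0)$label) == class) {
          surface <- cand
          break
        }
      }
      if (is.null(surface)) surface <- cand   # keep the last draw; the
                                              # recorded true category stays honest
      tilt <- rnorm_trunc(1, g$tilt[1], g$tilt[2], g$tilt_range[1], g$tilt_range[2])
      direction <- angle_inferior_positive(lm0$disc_center, bump)
      landmarks <- place_landmarks(surface, disc_offset, disc_radius, dfa,
                                   tilt_spec = list(tilt_deg = tilt,
                                                    direction_deg = direction),
                                   laterality = "right")
      truth <- eye_truth(surface, landmarks, group = groups[i],
                         covariates = list(age_years = age, se_diopter = se,
                                           axial_length_mm = al),
                         laterality = laterality,
                         id = sprintf("eye%03d", i))
      volume <- NULL
      if (render) {
        volume <- render_enface(surface, landmarks, render_params,
                                seed = sample.int(2^30, 1))
        if (laterality == "left") volume <- mirror_volume(volume)
      }
      list(truth = truth, volume = volume)
    })
  })
}

#' Assemble the ground-truth manifest of one phantom eye
#'
#' Validates that the covariates respect the group's inclusion thresholds
#' (axial length vs 24 mm, SE vs -2 D / +0.5 D, the 30 mm exclusion) and
#' that the stored true DPE is the dense-grid argmax of the surface.
#'
#' @param surface a `surface_model`
#' @param landmarks a `landmarks` object (canonical frame)
#' @param group "emmetropic" or "myopic"
#' @param covariates list with `age_years`, `se_diopter`, `axial_length_mm`
#' @param laterality "right" or "left"
#' @param id identifier string
#' @return object of class `eye_truth`
#' @export
eye_truth <- function(surface, landmarks, group = c("myopic", "emmetropic"),
                      covariates, laterality = "right", id = "eye") {
  group <- match.arg(group)
  al <- covariates$axial_length_mm
  se <- covariates$se_diopter
  if (al > 30) stop_pp("axial length over 30 mm is excluded")
  if (group == "myopic" && !(al > 24 && se < -2)) {
    stop_pp("myopic eyes require axial length > 24 mm and SE < -2 D")
  }
  if (group == "emmetropic" && !(al < 24 && se > 0.5)) {
    stop_pp("emmetropic eyes require axial length < 24 mm and SE > 0.5 D")
  }
  dt <- disc_truth(surface, landmarks)
  structure(
    c(list(id = id, surface = surface, landmarks = landmarks,
           true_dpe = surface$true_dpe, group = group,
           covariates = covariates, laterality = laterality,
           true_category = classify_dpe(surface$true_dpe[1:2], landmarks)$label),
      dt),
    class = "eye_truth")
}

#' Re-scan a phantom eye
#'
#' Renders an independent speckle realisation of the same anatomy,
#' optionally translated by a random fixation offset — the second visit of
#' an intervisit reproducibility series.
#'
#' @param truth an `eye_truth`
#' @param jitter_spec list: `lateral_sd_mm` (per-axis SD of the fixation
#'   offset; 0 = perfect refixation)
#' @param seed integer seed for offset and speckle
#' @param render_params overrides of [render_defaults()] (use the same
#'   values as the first visit)
#' @return list: `volume` (an `enface_volume`), `truth` (the shifted
#'   truth), `offset_mm` (the drawn fixation offset)
#' @export
rescan <- function(truth, jitter_spec = list(lateral_sd_mm = 0.05), seed = 1,
                   render_params = list()) {
  sd_mm <- jitter_spec$lateral_sd_mm %||% 0
  withr::with_seed(as.integer(seed), {
    offset <- if (sd_mm > 0) rnorm(2, 0, sd_mm) else c(0, 0)
    t2 <- shift_eye(truth, offset)
    vol <- render_enface(t2$surface, t2$landmarks, render_params,
                         seed = sample.int(2^30, 1))
    if (truth$laterality == "left") vol <- mirror_volume(vol)
    list(volume = vol, truth = t2, offset_mm = offset)
  })
}

## translate the whole anatomy (fixation offset)
shift_eye <- function(truth, offset) {
  t2 <- truth
  t2$surface$bump_center <- t2$surface$bump_center + offset
  t2$surface$base_center <- (t2$surface$base_center %||% c(0, 0)) + offset
  t2$surface$true_dpe[1:2] <- t2$surface$true_dpe[1:2] + offset
  t2$true_dpe <- t2$surface$true_dpe
  lm <- t2$landmarks
  lm$fovea <- lm$fovea + offset
  lm$disc_center <- lm$disc_center + offset
  lm$disc_margin[, "x"] <- lm$disc_margin[, "x"] + offset[1]
  lm$disc_margin[, "y"] <- lm$disc_margin[, "y"] + offset[2]
  t2$landmarks <- lm
  t2
}

#' @export
print.eye_truth <- function(x, ...) {
  cat(sprintf("eye_truth %s (%s, %s eye): DPE (%.2f, %.2f) mm depth %.0f um, %s\n",
              x$id, x$group, x$laterality, x$true_dpe[1], x$true_dpe[2],
              x$true_dpe[3], as.character(x$true_category)))
  invisible(x)
}
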