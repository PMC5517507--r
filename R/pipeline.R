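#' Measure one eye end to end
#'
#' Canonicalizes the volume (left eyes are mirrored), computes the depth
#' map, locates the DPE, derives the six posterior-pole metrics, the disc
#' configuration and the four-region DPE category.
#'
#' @param volume an `enface_volume` with landmarks
#' @param seg_params overrides of [seg_defaults()]
#' @return list: `dpe`, `metrics`, `disc`, `category`, `depth_map_quality`
#' @export
measure_eye <- function(volume, seg_params = list()) {
  volume <- canonicalize_volume(volume)
  if (is.null(volume$landmarks)) stop_pp("volume carries no landmarks")
  dmap <- depth_map(volume, seg_params)
  dpe <- locate_dpe(volume, seg_params, dmap = dmap)
  list(dpe = dpe,
       metrics = posterior_pole_metrics(dpe, volume$landmarks, dmap),
       disc = disc_config(volume, dmap),
       category = classify_dpe(dpe$center, volume$landmarks),
       depth_map_quality = attr(dmap, "quality"))
}

truth_row <- function(truth) {
  data.frame(
    true_dpe_x_mm = truth$true_dpe[1], true_dpe_y_mm = truth$true_dpe[2],
    true_dpe_depth_um = truth$true_dpe[3],
    true_torsion_deg = truth$true_torsion_deg,
    true_ovality = truth$true_ovality,
    true_h_tilt_deg = truth$true_h_tilt_deg,
    true_v_tilt_deg = truth$true_v_tilt_deg,
    true_category = as.character(truth$true_category),
    stringsAsFactors = FALSE)
}

measurement_row <- function(truth, meas) {
  data.frame(
    eye_id = truth$id, group = truth$group, laterality = truth$laterality,
    age_years = truth$covariates$age_years,
    se_diopter = truth$covariates$se_diopter,
    axial_length_mm = truth$covariates$axial_length_mm,
    dpe_section = meas$dpe$section_index,
    dpe_x_mm = meas$dpe$center[1], dpe_y_mm = meas$dpe$center[2],
    dpe_area_mm2 = meas$dpe$region_area_mm2,
    dpe_quality = paste(meas$dpe$quality, collapse = ";"),
    disc_dpe_distance_um = meas$metrics$disc_dpe_distance_um,
    fovea_dpe_distance_um = meas$metrics$fovea_dpe_distance_um,
    disc_dpe_depth_um = meas$metrics$disc_dpe_depth_um,
    fovea_dpe_depth_um = meas$metrics$fovea_dpe_depth_um,
    disc_dpe_angle_deg = meas$metrics$disc_dpe_angle_deg,
    disc_fovea_angle_deg = meas$metrics$disc_fovea_angle_deg,
    long_axis_um = meas$disc$long_axis_um,
    short_axis_um = meas$disc$short_axis_um,
    ovality = meas$disc$ovality,
    torsion_deg = meas$disc$torsion_deg,
    torsion_defined = meas$disc$torsion_defined,
    h_tilt_deg = meas$disc$h_tilt_deg,
    v_tilt_deg = meas$disc$v_tilt_deg,
    dpe_category = as.character(meas$category$label),
    stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' @param n_eyes cohort size
#' @param seed master seed; every stochastic stage derives its seed from it
#' @param out_dir output directory for the CSV tables and the run log
#' @param render_params overrides of [render_defaults()]
#' @param seg_params overrides of [seg_defaults()]
#' @param cohort_spec see [default_cohort_spec()]
#' @param reproducibility list for [reproducibility_run()]: `n_emmetropic`,
#'   `n_myopic`, `jitter` (see [rescan()])
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n_eyes = 165, seed = 1, out_dir = tempfile("poleprofile"),
                            render_params = list(), seg_params = list(),
                            cohort_spec = default_cohort_spec(),
                            reproducibility = list(n_emmetropic = 10,
                                                   n_myopic = 15,
                                                   jitter = list(lateral_sd_mm = 0.05))) {
  structure(list(n_eyes = n_eyes, seed = seed, out_dir = out_dir,
                 render_params = render_params, seg_params = seg_params,
                 cohort_spec = cohort_spec, reproducibility = reproducibility),
            class = "pipeline_config")
}

regression_candidates <- function(table) {
  within(table, {
    disc_dpe_distance_mm <- disc_dpe_distance_um / 1000
    disc_dpe_depth_mm <- disc_dpe_depth_um / 1000
    fovea_dpe_depth_mm <- fovea_dpe_depth_um / 1000
  })
}

run_regressions <- function(table) {
  cands <- c("disc_dpe_distance_mm", "disc_dpe_depth_mm",
             "fovea_dpe_depth_mm", "disc_dpe_angle_deg")
  tt <- regression_candidates(table)
  out <- list()
  for (dep in c("torsion_deg", "ovality")) {
    for (grp in c("emmetropic", "myopic", "all")) {
      sub <- if (grp == "all") tt else tt[tt$group == grp, , drop = FALSE]
      if (nrow(sub) <= length(cands) + 2L) next
      rep <- regression_tables(sub, dep, cands)
      uni <- rep$univariate
      uni$model <- "univariate"
      uni$ci_low <- NA_real_
      uni$ci_high <- NA_real_
      multi <- rep$multivariate
      if (!is.null(multi)) multi$model <- "multivariate"
      block <- rbind(uni[, c("model", "variable", "beta", "ci_low", "ci_high", "p")],
                     if (!is.null(multi)) {
                       multi[, c("model", "variable", "beta", "ci_low", "ci_high", "p")]
                     })
      block$dependent <- dep
      block$group <- grp
      out[[paste(dep, grp, sep = "_")]] <- block
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulates (or measures) a cohort, detects the DPE in every eye, computes
#' all metrics and classifications, and writes the cohort CSV plus the
#' group-comparison, subgroup, correlation and regression tables and a run
#' log. Deterministic given the config seed; any stage error aborts with
#' the eye id and stage name and no partial outputs are left behind
#' (tables are written only after every eye succeeded).
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the cohort table, the emitted tables and
#'   the output paths
#' @export
run_pipeline <- function(config = pipeline_config()) {
  eyes <- simulate_cohort(config$cohort_spec, config$n_eyes, seed = config$seed,
                          render = TRUE, render_params = config$render_params)
  rows <- lapply(seq_along(eyes), function(i) {
    eye <- eyes[[i]]
    meas <- tryCatch(measure_eye(eye$volume, config$seg_params),
                     error = function(e) {
                       stop_pp(sprintf("[measure] eye %s: %s",
                                       eye$truth$id, conditionMessage(e)))
                     })
    cbind(measurement_row(eye$truth, meas), truth_row(eye$truth))
  })
  cohort <- do.call(rbind, rows)

  metric_vars <- c("age_years", "se_diopter", "axial_length_mm",
                   "disc_dpe_distance_um", "fovea_dpe_distance_um",
                   "disc_dpe_depth_um", "fovea_dpe_depth_um",
                   "disc_fovea_angle_deg", "disc_dpe_angle_deg",
                   "torsion_deg", "ovality", "h_tilt_deg", "v_tilt_deg")
  tables <- list()
  tables$groups <- cohort_summary(cohort, "group", metric_vars)$formatted
  if (length(unique(cohort$group)) == 2L &&
      all(table(cohort$group) >= 2L)) {
    tables$group_tests <- compare_groups(cohort, "group",
                                         c(metric_vars, "laterality", "dpe_category"))
  }
  myo <- cohort[cohort$group == "myopic", , drop = FALSE]
  sub_vars <- intersect(metric_vars, names(myo))
  if (nrow(myo) > 0L) {
    tables$subgroups <- cohort_summary(myo, "dpe_category", sub_vars)$formatted
    cat_n <- table(factor(myo$dpe_category, levels = dpe_category_levels()))
    if (all(cat_n >= 2L)) {
      tables$subgroup_tests <- compare_groups(myo, "dpe_category", sub_vars)
    }
  }
  corr_vars <- c("age_years", "se_diopter", "axial_length_mm",
                 "disc_dpe_distance_um", "fovea_dpe_distance_um",
                 "disc_dpe_depth_um", "fovea_dpe_depth_um",
                 "disc_dpe_angle_deg", "torsion_deg", "ovality",
                 "h_tilt_deg", "v_tilt_deg")
  tables$correlations <- correlation_matrix(cohort, corr_vars)
  tables$regressions <- run_regressions(cohort)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(config$out_dir, "cohort.csv"))
  complete <- FALSE
  on.exit(if (!complete) unlink(paths), add = TRUE)   # no partial outputs
  write_table(cohort, paths[["cohort"]])
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(config$out_dir, paste0("table_", nm, ".csv"))
    paths[nm] <- p
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
  }
  complete <- TRUE
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    sprintf("poleprofile %s", as.character(packageVersion("poleprofile"))),
    sprintf("seed: %d", config$seed),
    sprintf("n_eyes: %d", config$n_eyes),
    sprintf("render overrides: %s",
            paste(names(config$render_params), config$render_params,
                  sep = "=", collapse = " ") %||% ""),
    sprintf("eyes measured: %s", paste(cohort$eye_id, collapse = " "))),
    log_path)
  paths["log"] <- log_path
  invisible(list(cohort = cohort, tables = tables, paths = paths))
}

#' Simulated intervisit reproducibility (ICC table)
#'
#' Simulates the reproducibility design — independent series on emmetropic
#' and myopic eyes (10 + 15 by default), each scanned twice with fresh
#' speckle and a small fixation offset — runs the full measurement on both
#' visits and reports the two-way mixed-model ICC (single and average
#' measure) for the five reported metrics: DPE interface section, disc-DPE
#' distance, disc-DPE depth, fovea-DPE depth and disc-DPE angle.
#'
#' @param config a [pipeline_config()]; `config$reproducibility` gives the
#'   design sizes and jitter
#' @return data.frame: metric, icc_single, its CI, icc_average, its CI
#' @export
reproducibility_run <- function(config = pipeline_config()) {
  rp <- config$reproducibility
  n_em <- rp$n_emmetropic %||% 10
  n_my <- rp$n_myopic %||% 15
  m <- n_em + n_my
  if (m < 3) stop_pp("reproducibility needs at least 3 eyes")
  spec <- config$cohort_spec
  spec$groups$emmetropic$prop <- n_em / m
  spec$groups$myopic$prop <- n_my / m
  eyes <- simulate_cohort(spec, m, seed = config$seed, render = TRUE,
                          render_params = config$render_params)
  metrics <- c(dpe_interface_section = "dpe_section",
               disc_dpe_distance_um = "disc_dpe_distance_um",
               disc_dpe_depth_um = "disc_dpe_depth_um",
               fovea_dpe_depth_um = "fovea_dpe_depth_um",
               disc_dpe_angle_deg = "disc_dpe_angle_deg")
  ratings <- matrix(NA_real_, m, 2L * length(metrics))
  for (i in seq_len(m)) {
    eye <- eyes[[i]]
    v2 <- rescan(eye$truth, rp$jitter %||% list(lateral_sd_mm = 0.05),
                 seed = config$seed + 20000L + i,
                 render_params = config$render_params)
    m1 <- measurement_row(eye$truth, measure_eye(eye$volume, config$seg_params))
    m2 <- measurement_row(v2$truth, measure_eye(v2$volume, config$seg_params))
    for (k in seq_along(metrics)) {
      ratings[i, 2 * k - 1] <- m1[[metrics[k]]]
      ratings[i, 2 * k] <- m2[[metrics[k]]]
    }
  }
  out <- do.call(rbind, lapply(seq_along(metrics), function(k) {
    icc <- icc_two_way_mixed(ratings[, c(2 * k - 1, 2 * k)])
    data.frame(metric = names(metrics)[k],
               icc_single = icc$icc_single,
               single_lo = icc$ci_single[1], single_hi = icc$ci_single[2],
               icc_average = icc$icc_average,
               average_lo = icc$ci_average[1], average_hi = icc$ci_average[2],
               n = icc$n_subjects, k = icc$k_raters,
               stringsAsFactors = FALSE)
  }))
  out
}
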