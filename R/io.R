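sidecar_path <- function(path) {
  sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
}

landmarks_to_list <- function(lm) {
  list(fovea = lm$fovea, disc_center = lm$disc_center,
       disc_radius = lm$disc_radius,
       disc_margin = unname(as.matrix(lm$disc_margin)),
       disc_plane_tilt_axis = lm$disc_plane_tilt_axis,
       disc_plane_tilt_deg = lm$disc_plane_tilt_deg,
       tilt_direction_deg = lm$tilt_direction_deg,
       laterality = lm$laterality)
}

landmarks_from_list <- function(l) {
  m <- do.call(rbind, lapply(l$disc_margin, unlist))
  colnames(m) <- c("x", "y", "z")
  structure(
    list(fovea = unlist(l$fovea), disc_center = unlist(l$disc_center),
         disc_radius = l$disc_radius, disc_margin = m,
         disc_plane_tilt_axis = unlist(l$disc_plane_tilt_axis),
         disc_plane_tilt_deg = l$disc_plane_tilt_deg,
         tilt_direction_deg = l$tilt_direction_deg,
         laterality = l$laterality),
    class = "landmarks")
}

#' Write an en-face volume as a multi-page TIFF plus JSON sidecar
#'
#' One 16-bit grayscale TIFF page per coronal section (anterior to
#' posterior) and a JSON sidecar carrying the geometry, landmarks and —
#' when present — the ground truth. [read_volume()] inverts the pair
#' bit-exactly.
#'
#' @param volume an `enface_volume`
#' @param path output path ending in `.tif`/`.tiff`; the sidecar replaces
#'   the extension with `.json`
#' @return invisibly, the two paths written
#' @export
write_volume <- function(volume, path) {
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop_pp("`path` must end in .tif or .tiff")
  }
  v <- volume$intensities
  pages <- lapply(seq_len(dim(v)[3]), function(s) v[, , s])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(
    format_version = 1L,
    lateral_pitch_mm = volume$lateral_pitch,
    section_pitch_um = volume$section_pitch_um,
    n_sections = volume$n_sections,
    origin = volume$origin,
    laterality = volume$laterality)
  if (!is.null(volume$landmarks)) {
    side$landmarks <- landmarks_to_list(volume$landmarks)
  }
  if (!is.null(volume$truth)) {
    s <- volume$truth$surface
    side$truth <- list(
      base_radius = if (is.finite(s$base_radius)) s$base_radius else "Inf",
      bump_center = s$bump_center, bump_amplitude = s$bump_amplitude,
      bump_sigma = s$bump_sigma, axial_length = s$axial_length,
      field = s$field, base_center = s$base_center %||% c(0, 0),
      true_dpe = unname(s$true_dpe), z_offset_um = volume$truth$z_offset_um)
  }
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar_path(path)))
}

#' Read an en-face volume written by [write_volume()]
#'
#' @param path the TIFF path; the JSON sidecar must sit next to it
#' @return an `enface_volume`
#' @export
read_volume <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_pp(sprintf("missing sidecar: %s", sp))
  side <- jsonlite::read_json(sp, simplifyVector = FALSE)
  for (f in c("lateral_pitch_mm", "section_pitch_um", "n_sections", "origin",
              "laterality")) {
    if (is.null(side[[f]])) stop_pp(sprintf("sidecar field missing: %s", f))
  }
  if (side$lateral_pitch_mm <= 0) stop_pp("sidecar field invalid: lateral_pitch_mm <= 0")
  if (side$section_pitch_um <= 0) stop_pp("sidecar field invalid: section_pitch_um <= 0")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != side$n_sections) {
    stop_pp(sprintf("page-count mismatch: sidecar n_sections = %d but TIFF has %d pages",
                    side$n_sections, length(pages)))
  }
  vol <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) {
    pg <- pages[[s]]
    attributes(pg) <- list(dim = dim(pg))
    vol[, , s] <- pg
  }
  truth <- NULL
  if (!is.null(side$truth)) {
    tr <- side$truth
    br <- if (identical(tr$base_radius, "Inf")) Inf else tr$base_radius
    surface <- build_surface(br, unlist(tr$bump_center), tr$bump_amplitude,
                             tr$bump_sigma, axial_length = tr$axial_length,
                             field = unlist(tr$field),
                             base_center = unlist(tr$base_center))
    truth <- list(surface = surface, z_offset_um = tr$z_offset_um)
  }
  structure(
    list(intensities = vol, lateral_pitch = side$lateral_pitch_mm,
         section_pitch_um = side$section_pitch_um,
         n_sections = as.integer(side$n_sections),
         origin = unlist(side$origin), laterality = side$laterality,
         landmarks = if (!is.null(side$landmarks)) {
           landmarks_from_list(side$landmarks)
         },
         truth = truth),
    class = "enface_volume")
}

#' Column schema of the per-eye cohort table
#'
#' Fixed, versioned schema: every measured metric with its unit, the group
#' labels, and the optional ground-truth columns. Units travel with the
#' CSV as a second header row because the metrics mix um, mm and degrees.
#'
#' @return data.frame with `name`, `unit`, `type`
#' @export
cohort_schema <- function() {
  s <- rbind(
    c("eye_id", "", "character"),
    c("group", "", "character"),
    c("laterality", "", "character"),
    c("age_years", "years", "numeric"),
    c("se_diopter", "D", "numeric"),
    c("axial_length_mm", "mm", "numeric"),
    c("dpe_section", "section", "numeric"),
    c("dpe_x_mm", "mm", "numeric"),
    c("dpe_y_mm", "mm", "numeric"),
    c("dpe_area_mm2", "mm2", "numeric"),
    c("dpe_quality", "", "character"),
    c("disc_dpe_distance_um", "um", "numeric"),
    c("fovea_dpe_distance_um", "um", "numeric"),
    c("disc_dpe_depth_um", "um", "numeric"),
    c("fovea_dpe_depth_um", "um", "numeric"),
    c("disc_dpe_angle_deg", "deg", "numeric"),
    c("disc_fovea_angle_deg", "deg", "numeric"),
    c("long_axis_um", "um", "numeric"),
    c("short_axis_um", "um", "numeric"),
    c("ovality", "ratio", "numeric"),
    c("torsion_deg", "deg", "numeric"),
    c("torsion_defined", "", "logical"),
    c("h_tilt_deg", "deg", "numeric"),
    c("v_tilt_deg", "deg", "numeric"),
    c("dpe_category", "", "character"),
    c("true_dpe_x_mm", "mm", "numeric"),
    c("true_dpe_y_mm", "mm", "numeric"),
    c("true_dpe_depth_um", "um", "numeric"),
    c("true_torsion_deg", "deg", "numeric"),
    c("true_ovality", "ratio", "numeric"),
    c("true_h_tilt_deg", "deg", "numeric"),
    c("true_v_tilt_deg", "deg", "numeric"),
    c("true_category", "", "character"))
  data.frame(name = s[, 1], unit = s[, 2], type = s[, 3],
             stringsAsFactors = FALSE)
}

check_table_columns <- function(table) {
  schema <- cohort_schema()
  unknown <- setdiff(names(table), schema$name)
  if (length(unknown) > 0L) {
    stop_pp(sprintf("unknown cohort-table column: %s", unknown[1]))
  }
  schema[match(names(table), schema$name), , drop = FALSE]
}

#' Write a cohort table as CSV with a unit header row
#'
#' Row 1: column names; row 2: units; data from row 3. Numeric values are
#' written with 15 significant digits so the round trip is exact to 1e-9.
#' Columns must belong to the versioned [cohort_schema()].
#'
#' @param table data.frame with schema columns
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_table <- function(table, path) {
  schema <- check_table_columns(table)
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- sprintf("%.15g", x)
      out[is.na(x)] <- ""
      out
    } else {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    }
  }
  lines <- c(paste(names(table), collapse = ","),
             paste(schema$unit, collapse = ","))
  if (nrow(table) > 0L) {
    cells <- vapply(table, fmt, character(nrow(table)))
    if (nrow(table) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort table written by [write_table()]
#'
#' @param path the CSV path
#' @return data.frame typed per [cohort_schema()], with a `units`
#'   attribute
#' @export
read_table <- function(path) {
  header <- strsplit(readLines(path, n = 2L), ",", fixed = TRUE)
  nms <- header[[1]]
  schema <- cohort_schema()
  unknown <- setdiff(nms, schema$name)
  if (length(unknown) > 0L) {
    stop_pp(sprintf("unknown cohort-table column: %s", unknown[1]))
  }
  raw <- utils::read.csv(path, skip = 2L, header = FALSE, col.names = nms,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) {
    raw <- as.data.frame(setNames(rep(list(character(0)), length(nms)), nms),
                         check.names = FALSE)
  }
  types <- schema$type[match(nms, schema$name)]
  for (j in seq_along(nms)) {
    raw[[j]][raw[[j]] == ""] <- NA
    raw[[j]] <- switch(types[j],
                       numeric = as.numeric(raw[[j]]),
                       logical = as.logical(raw[[j]]),
                       raw[[j]])
  }
  attr(raw, "units") <- schema$unit[match(nms, schema$name)]
  raw
}

#' Mean ± SD cohort summary in the group-table presentation format
#'
#' @param table cohort data.frame
#' @param grouping grouping column name
#' @param variables numeric columns to summarise
#' @return list: `numeric` (variable x group means and SDs, long format)
#'   and `formatted` ("mean ± SD" strings, variable x group)
#' @export
cohort_summary <- function(table, grouping, variables) {
  g <- factor(table[[grouping]])
  num <- do.call(rbind, lapply(variables, function(v) {
    data.frame(variable = v, group = levels(g),
               mean = as.numeric(tapply(table[[v]], g, mean, na.rm = TRUE)),
               sd = as.numeric(tapply(table[[v]], g, sd, na.rm = TRUE)),
               n = as.integer(table(g)), stringsAsFactors = FALSE)
  }))
  fm <- do.call(rbind, lapply(variables, function(v) {
    row <- data.frame(variable = v, stringsAsFactors = FALSE)
    for (lev in levels(g)) row[[lev]] <- mean_sd(table[[v]][g == lev])
    row
  }))
  list(numeric = num, formatted = fm)
}
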