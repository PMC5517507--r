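#' Default segmentation parameters
#'
#' The clinical cue for the deepest point is a bright Bruch's-membrane
#' island surrounded by darker choroid, so the detector thresholds on
#' relative brightness (Otsu) rather than absolute intensity, removes
#' speckle with a small median filter, closes small gaps morphologically
#' and discards regions below a minimum area.
#'
#' @return named list: `threshold` (NULL = Otsu), `min_area_mm2`,
#'   `closing_radius_px`, `median_size` (number of 3 x 3 binary-median
#'   passes applied to the thresholded mask; 0 disables), `min_contrast`
#'   (bright/dark mean ratio guard used when thresholding a single section
#'   in isolation), `smooth_depth_map` (3 x 3 median of the depth map
#'   before the argmax)
#' @export
seg_defaults <- function() {
  list(threshold = NULL, min_area_mm2 = 0.05, closing_radius_px = 2L,
       median_size = 1L, min_contrast = 1.5, smooth_depth_map = TRUE)
}

## two-stage Otsu aimed at the brightest tissue class: a first split
## separates the dark choroid, a second split of the upper class isolates
## the hyper-reflective BM band from the retina when the two are clearly
## distinct (mean ratio >= 1.3); Inf flags "no signal"
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) < 1e-6) return(Inf)   # uniform: no interface signal
  t1 <- EBImage::otsu(matrix(v, ncol = 1L), range = c(0, 1))
  if (t1 <= rng[1] || t1 >= rng[2]) return(Inf)
  upper <- v[v > t1]
  if (length(upper) > 50L && diff(range(upper)) > 1e-6) {
    t2 <- EBImage::otsu(matrix(upper, ncol = 1L), range = c(0, 1))
    hi <- upper[upper > t2]
    lo <- upper[upper <= t2]
    if (length(hi) > 0L && length(lo) > 0L && mean(hi) >= 1.3 * mean(lo)) {
      return(t2)
    }
  }
  t1
}

#' Global threshold of a volume for BM-band segmentation
#'
#' Computed on a voxel subsample (the histogram is what matters): a
#' two-stage Otsu that isolates the brightest class — the hyper-reflective
#' Bruch's membrane band — from retina and choroid.
#'
#' @param volume an `enface_volume`
#' @param max_voxels subsample size cap
#' @return scalar threshold in \[0, 1\]; `Inf` when the volume carries no
#'   contrast at all
#' @export
volume_threshold <- function(volume, max_voxels = 2e6) {
  v <- volume$intensities
  n <- length(v)
  if (n > max_voxels) {
    stride <- ceiling(n / max_voxels)
    v <- v[seq(1L, n, by = stride)]
  }
  otsu_threshold(as.vector(v))
}

#' Segment the BM-band interface in one coronal section
#'
#' @param section_image 2D numeric matrix in \[0, 1\]
#' @param seg_params overrides of [seg_defaults()]; supply `threshold` to
#'   use a volume-global threshold (as [depth_map()] does)
#' @param lateral_pitch mm/pixel, used to convert `min_area_mm2` to pixels
#' @return logical mask matrix; empty (all `FALSE`) for sections without
#'   interface signal
#' @export
segment_interface <- function(section_image, seg_params = list(),
                              lateral_pitch = 12 / 512) {
  p <- modifyList(seg_defaults(), seg_params)
  sec <- section_image
  empty <- matrix(FALSE, nrow(sec), ncol(sec))
  if (is.null(p$threshold)) {
    thr <- otsu_threshold(as.vector(sec))
    if (!is.finite(thr)) return(empty)           # uniform section
    bright <- sec > thr
    if (!any(bright) || all(bright)) return(empty)
    if (mean(sec[bright]) < p$min_contrast * mean(sec[!bright])) return(empty)
  } else {
    thr <- p$threshold
    bright <- sec > thr
    if (!any(bright)) return(empty)
  }
  mask <- bright
  if (p$median_size > 0L && !all(mask)) {
    ## binary median (majority vote): one pass per unit of median_size
    for (i in seq_len(p$median_size)) mask <- majority3x3(mask)
    if (!any(mask)) return(empty)
  }
  if (p$closing_radius_px > 0L && !all(mask)) {
    brush <- EBImage::makeBrush(2L * p$closing_radius_px + 1L, shape = "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  min_px <- ceiling(p$min_area_mm2 / lateral_pitch^2)
  if (min_px > 1L) {
    lbl <- EBImage::bwlabel(mask)
    areas <- tabulate(lbl[lbl > 0])
    keep <- which(areas >= min_px)
    if (length(keep) == 0L) return(empty)
    mask <- matrix(lbl %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Per-pixel map of the deepest section containing interface signal
#'
#' Scans the coronal sections anterior to posterior and records, for every
#' lateral pixel, the largest (most posterior, 0-based) section index whose
#' interface mask contains it — the automated counterpart of the examiner
#' moving the sections back and forth. Pixels never segmented (e.g. inside
#' the BM opening at the disc) are `NA`.
#'
#' @param volume an `enface_volume`
#' @param seg_params overrides of [seg_defaults()]
#' @return integer matrix of 0-based section indices with attributes
#'   `section_pitch_um`, `lateral_pitch`, `origin` and `quality`
#'   (`"low_contrast"` when more than half the pixels are missing)
#' @export
depth_map <- function(volume, seg_params = list()) {
  p <- modifyList(seg_defaults(), seg_params)
  if (is.null(p$threshold)) p$threshold <- volume_threshold(volume)
  dm <- matrix(NA_integer_, nrow(volume$intensities), ncol(volume$intensities))
  for (s in seq_len(dim(volume$intensities)[3])) {
    sec <- volume$intensities[, , s]
    if (max(sec) <= p$threshold) next     # nothing above threshold
    mask <- segment_interface(sec, p, volume$lateral_pitch)
    if (any(mask)) dm[mask] <- s - 1L
  }
  quality <- if (mean(is.na(dm)) > 0.5) "low_contrast" else "ok"
  structure(dm, section_pitch_um = volume$section_pitch_um,
            lateral_pitch = volume$lateral_pitch, origin = volume$origin,
            quality = quality)
}

## 3x3 median smoothing of an integer depth map (NA-aware; medians of 9
## integers stay on the integer grid)
smooth_depth_map <- function(dm, n_sections) {
  filled <- matrix(as.numeric(dm), nrow(dm), ncol(dm))
  filled[is.na(filled)] <- -1
  out <- median3x3(filled)
  out[out < 0] <- NA
  matrix(as.integer(out), nrow(dm), ncol(dm))
}

#' Locate the deepest point of the eyeball in a volume
#'
#' The DPE section is the maximum of the (optionally median-smoothed)
#' depth map — smoothing suppresses single-pixel speckle wins; ties resolve
#' to the more posterior section by construction. The DPE centre is the
#' intensity-weighted centroid of the interface region in that deepest
#' section; with several disjoint regions the largest is taken and the
#' `multiple_regions` flag set. A depth map with relief below 2 sections
#' raises the `low_relief` flag (degenerate flat surface: the centre then
#' reports the field centroid of the region).
#'
#' @param volume an `enface_volume`
#' @param seg_params overrides of [seg_defaults()]
#' @param dmap a precomputed [depth_map()] (optional, avoids recomputation)
#' @return object of class `dpe_result`: `section_index` (0-based),
#'   `center` (x, y mm), `depth_um` (= section_index * section pitch),
#'   `region_area_mm2`, `quality` (character vector of flags, `"ok"` if none)
#' @export
locate_dpe <- function(volume, seg_params = list(), dmap = NULL) {
  p <- modifyList(seg_defaults(), seg_params)
  if (is.null(p$threshold)) p$threshold <- volume_threshold(volume)
  if (is.null(dmap)) dmap <- depth_map(volume, p)
  if (all(is.na(dmap))) stop_pp("no interface signal found anywhere in the volume")
  flags <- character(0)
  if (identical(attr(dmap, "quality"), "low_contrast")) flags <- c(flags, "low_contrast")

  dm <- if (isTRUE(p$smooth_depth_map)) {
    smooth_depth_map(dmap, volume$n_sections)
  } else {
    dmap
  }
  if (all(is.na(dm))) dm <- dmap
  s_star <- max(dm, na.rm = TRUE)
  relief <- s_star - min(dm, na.rm = TRUE)
  if (relief < 2L) flags <- c(flags, "low_relief")

  mask <- segment_interface(volume$intensities[, , s_star + 1L], p,
                            volume$lateral_pitch)
  if (!any(mask)) {
    ## smoothing can nudge the argmax past the last segmented section
    mask <- !is.na(dmap) & dmap >= s_star
  }
  lbl <- EBImage::bwlabel(mask)
  areas <- tabulate(lbl[lbl > 0])
  if (length(areas) > 1L) flags <- c(flags, "multiple_regions")
  region <- lbl == which.max(areas)
  w <- volume$intensities[, , s_star + 1L] * region
  idx <- which(region, arr.ind = TRUE)
  wts <- w[region]
  ax <- pixel_axes(volume)
  center <- c(sum(ax$x[idx[, 2]] * wts), sum(ax$y[idx[, 1]] * wts)) / sum(wts)

  structure(
    list(section_index = as.integer(s_star), center = center,
         depth_um = s_star * volume$section_pitch_um,
         region_area_mm2 = sum(region) * volume$lateral_pitch^2,
         quality = if (length(flags)) unique(flags) else "ok"),
    class = "dpe_result")
}

#' @export
print.dpe_result <- function(x, ...) {
  cat(sprintf(
    "dpe_result: section %d (depth %.1f um), center (%.3f, %.3f) mm, area %.3f mm2 [%s]\n",
    x$section_index, x$depth_um, x$center[1], x$center[2], x$region_area_mm2,
    paste(x$quality, collapse = ",")))
  invisible(x)
}
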