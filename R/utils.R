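#' Wrap an angle to (-180, 180] degrees
#' @param a angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap180 <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Wrap a line orientation to (-90, 90] degrees
#'
#' Orientations of undirected lines are defined modulo 180 degrees.
#' @param a angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap90 <- function(a) {
  w <- a %% 180
  w[w > 90] <- w[w > 90] - 180
  w
}

#' Signed angle with the inferior-positive convention
#'
#' Angle in degrees at `from` between the +x (temporal) horizontal meridian
#' and the ray towards `to`, positive when `to` lies inferior (-y) to
#' `from`. This is the convention under which the disc-fovea angle of a
#' normal eye (fovea 2-6 degrees below the disc) is positive.
#'
#' @param from,to length-2 numeric (x, y) in mm, canonical right-eye frame
#' @return angle in degrees in (-180, 180]
#' @export
angle_inferior_positive <- function(from, to) {
  d <- unname(to - from)
  wrap180(atan2(-d[2], d[1]) * 180 / pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pp <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pp(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) stop_pp(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_pp(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

## vectorised 3x3 median filter (edge-replicated padding) via the
## 19-comparator median-of-9 sorting network; orders of magnitude faster
## than histogram-based median filters at 16-bit depth
median3x3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr < 2L || nc < 2L) return(m)
  up <- c(1L, seq_len(nr - 1L))
  dn <- c(seq_len(nr)[-1L], nr)
  lf <- c(1L, seq_len(nc - 1L))
  rt <- c(seq_len(nc)[-1L], nc)
  p <- list(m[up, lf], m[up, ], m[up, rt],
            m[, lf],   m,       m[, rt],
            m[dn, lf], m[dn, ], m[dn, rt])
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]])
    p[[j]] <<- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  matrix(p[[5]], nr, nc)
}

## 3x3 majority vote on a logical matrix (the binary special case of the
## median filter), edge-replicated; used for speckle suppression of masks
majority3x3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr < 2L || nc < 2L) return(m)
  mi <- matrix(as.integer(m), nr, nc)
  up <- c(1L, seq_len(nr - 1L))
  dn <- c(seq_len(nr)[-1L], nr)
  lf <- c(1L, seq_len(nc - 1L))
  rt <- c(seq_len(nc)[-1L], nc)
  s <- mi[up, lf] + mi[up, ] + mi[up, rt] +
    mi[, lf] + mi + mi[, rt] +
    mi[dn, lf] + mi[dn, ] + mi[dn, rt]
  s >= 5L
}

## pixel-centre coordinates of a volume raster
pixel_axes <- function(volume) {
  nx <- ncol(volume$intensities)
  ny <- nrow(volume$intensities)
  p <- volume$lateral_pitch
  list(
    x = volume$origin[1] + (seq_len(nx) - 1L) * p,
    y = volume$origin[2] - (seq_len(ny) - 1L) * p
  )
}

## nearest pixel (row, col) of an (x, y) mm point; NA when outside raster
mm_to_pixel <- function(volume, xy) {
  p <- volume$lateral_pitch
  col <- round((xy[1] - volume$origin[1]) / p) + 1L
  row <- round((volume$origin[2] - xy[2]) / p) + 1L
  if (col < 1L || col > ncol(volume$intensities) ||
      row < 1L || row > nrow(volume$intensities)) {
    return(c(NA_integer_, NA_integer_))
  }
  c(as.integer(row), as.integer(col))
}

pixel_to_mm <- function(volume, row, col) {
  c(volume$origin[1] + (col - 1) * volume$lateral_pitch,
    volume$origin[2] - (row - 1) * volume$lateral_pitch)
}
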