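#' Partition the upper hemisphere into equal solid angles
#'
#' The sky is tiled with `bands` zenith bands of equal solid angle
#' (cos-zenith boundaries uniformly spaced between 1 and 0), each split
#' into `n / bands` azimuth sectors. Each cell subtends `2 pi / n`
#' steradians and carries weight `1 / n`; its mean direction is the
#' solid-angle centroid of the cell, normalised to unit length.
#'
#' @param n number of cells (default 32).
#' @param bands number of zenith bands (default 4).
#' @return A list with `dir` (`n x 3` matrix of unit mean directions, all
#'   with positive vertical component), `weight` (`1 / n`) and
#'   `solid_angle` (`2 pi / n`).
#' @export
sky_directions <- function(n = 32, bands = 4) {
  if (n <= 0) stop("n must be positive")
  if (n %% bands != 0) stop("n must be a multiple of bands")
  naz <- n %/% bands
  cb <- seq(1, 0, length.out = bands + 1)
  dir <- matrix(0, n, 3)
  row <- 1L
  for (i in seq_len(bands)) {
    c1 <- cb[i]
    c2 <- cb[i + 1]
    iz <- (c1^2 - c2^2) / 2                    # integral of cos(zenith)
    is <- (c1 * sqrt(1 - c1^2) + asin(c1) -    # integral of sin(zenith)
             c2 * sqrt(1 - c2^2) - asin(c2)) / 2
    for (j in seq_len(naz)) {
      p1 <- 2 * pi * (j - 1) / naz
      p2 <- 2 * pi * j / naz
      v <- c(is * (sin(p2) - sin(p1)), is * (cos(p1) - cos(p2)),
             iz * (p2 - p1))
      dir[row, ] <- v / sqrt(sum(v^2))
      row <- row + 1L
    }
  }
  list(dir = dir, weight = 1 / n, solid_angle = 2 * pi / n)
}

plane_basis <- function(d) {
  if (abs(d[3]) < 0.9999) {
    e1 <- c(d[2], -d[1], 0)
    e1 <- e1 / sqrt(sum(e1^2))
  } else {
    e1 <- c(1, 0, 0)
  }
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  cbind(e1, e2, d)
}

#' Light intercepted by each foliage
#'
#' For every sky direction the foliage centers are rotated so the mean
#' direction maps to +z, binned into an `L x L` ground grid (fixed origin,
#' no jitter), and ranked by descending rotated height within each column
#' (ties broken by foliage index). The k-th foliage of a column (k = 0, 1,
#' ...) receives `weight * alpha_fol^k`; intercepted light is the sum over
#' all directions, so an unshaded foliage receives exactly 1. Segments
#' cast no shadow.
#'
#' @param centers `n x 3` matrix of foliage center positions.
#' @param params a [wt_params()] object (`alpha_fol`, `L`,
#'   `n_sky_angles`).
#' @param sky optional precomputed [sky_directions()] partition.
#' @return Numeric vector of light fractions `l` in `[0, 1]`, one per
#'   foliage.
#' @examples
#' intercept_light(matrix(c(0, 0, 1), 1, 3)) # == 1
#' @export
intercept_light <- function(centers, params = wt_params(), sky = NULL) {
  n <- nrow(centers)
  if (is.null(n) || n == 0) return(numeric(0))
  if (is.null(sky)) sky <- sky_directions(params$n_sky_angles)
  alpha <- params$alpha_fol
  l <- numeric(n)
  for (k in seq_len(nrow(sky$dir))) {
    rot <- centers %*% plane_basis(sky$dir[k, ])
    xc <- floor(rot[, 1] / params$L)
    yc <- floor(rot[, 2] / params$L)
    key <- (xc - min(xc)) * (max(yc) - min(yc) + 1) + (yc - min(yc))
    o <- order(key, -rot[, 3], seq_len(n))
    depth <- sequence(rle(key[o])$lengths) - 1
    l[o] <- l[o] + sky$weight * alpha^depth
  }
  l
}
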