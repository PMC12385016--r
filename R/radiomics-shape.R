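## 2D shape descriptors of the binary mask via marching squares.

## Per-cell marching-squares lookup on the 0.5 iso-level, pixel centers at
## integer coordinates. Case index = tl + 2*tr + 4*br + 8*bl. Saddle cells
## (two diagonal corners) are resolved as two disconnected triangles.
MS_AREA <- c(0, 1/8, 1/8, 1/2, 1/8, 1/4, 1/2, 7/8,
             1/8, 1/2, 1/4, 7/8, 1/2, 7/8, 7/8, 1)
MS_PERIM <- {
  s <- sqrt(0.5)
  c(0, s, s, 1, s, 2 * s, 1, s, s, 1, 2 * s, s, 1, s, s, 0)
}

#' 2D shape features of a mask
#'
#' Mesh-based surface area and perimeter from a marching-squares contour of
#' the mask (iso-level 0.5 between pixel centers; a single pixel contributes
#' a diamond of area 0.5 and perimeter `2*sqrt(2)`). Axis lengths derive
#' from the principal moments of the in-mask pixel coordinates (population
#' covariance, axis length `4*sqrt(lambda)`), the maximum diameter from the
#' convex hull of pixel centers.
#'
#' @param mask binary matrix; must be non-empty.
#' @param pixel_spacing physical pixel size.
#' @return Named numeric vector of 10 features (prefix `shape_`).
#' @export
shape2d <- function(mask, pixel_spacing = 1) {
  msk <- mask != 0
  if (!any(msk)) abort_config("shape2d needs a non-empty mask")
  nr <- nrow(msk); nc <- ncol(msk)
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- msk
  tl <- M[1:(nr + 1L), 1:(nc + 1L)]
  tr <- M[1:(nr + 1L), 2:(nc + 2L)]
  bl <- M[2:(nr + 2L), 1:(nc + 1L)]
  br <- M[2:(nr + 2L), 2:(nc + 2L)]
  case <- tl + 2L * tr + 4L * br + 8L * bl
  counts <- tabulate(case + 1L, nbins = 16L)
  area <- sum(counts * MS_AREA) * pixel_spacing^2
  perim <- sum(counts * MS_PERIM) * pixel_spacing

  idx <- which(msk, arr.ind = TRUE)
  np <- nrow(idx)
  coords <- idx * pixel_spacing
  if (np > 1L) {
    cov <- stats::cov(coords) * (np - 1) / np     # population covariance
    ev <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1

  max_diam <- 0
  if (np > 1L) {
    pts <- coords
    if (np > 400L) {
      hull <- tryCatch(grDevices::chull(coords[, 2], coords[, 1]),
                       error = function(e) seq_len(np))
      pts <- coords[hull, , drop = FALSE]
    }
    max_diam <- max(stats::dist(pts))
  }

  c(shape_mesh_surface = area,
    shape_pixel_surface = np * pixel_spacing^2,
    shape_perimeter = perim,
    shape_perimeter_surface_ratio = if (area > 0) perim / area else 0,
    shape_sphericity = if (perim > 0) 2 * sqrt(pi * area) / perim else 0,
    shape_compactness = if (perim > 0) 4 * pi * area / perim^2 else 0,
    shape_maximum_diameter = max_diam,
    shape_major_axis_length = major,
    shape_minor_axis_length = minor,
    shape_elongation = elong)
}
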