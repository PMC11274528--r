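#' Rotation matrix from intrinsic Z-Y-X Euler angles
#' @keywords internal
euler_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Band-limited angular irregularity field
#'
#' Returns a function f(U) on unit directions (rows of U), a sum of a few
#' low-frequency cosine waves with random directions, frequencies, and
#' phases, normalized so |f| <= amplitude. Smoothness comes from the low
#' frequency band (2--5 cycles across the sphere), so the perturbed surface
#' stays lobulated rather than noisy -- the shape regime in which the
#' ellipsoid approximation is known to drift.
#' @keywords internal
irregularity_field <- function(amplitude, seed, n_waves = 8L) {
  if (amplitude == 0) return(function(U) rep(0, nrow(U)))
  coefs <- with_local_seed(seed, {
    dirs <- matrix(rnorm(3L * n_waves), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    list(dirs = dirs,
         freq = runif(n_waves, 2, 5),
         phase = runif(n_waves, 0, 2 * pi),
         w = runif(n_waves, 0.3, 1))
  })
  norm <- sum(coefs$w)
  function(U) {
    proj <- U %*% t(coefs$dirs)  # n x n_waves
    f <- sweep(cos(sweep(proj, 2, coefs$freq, `*`) +
                     matrix(coefs$phase, nrow(U), n_waves, byrow = TRUE)),
               2, coefs$w, `*`)
    amplitude * rowSums(f) / norm
  }
}

#' @keywords internal
voxel_grid_bbox <- function(center, radius_mm, spacing, shape) {
  lo <- pmax(1L, floor(1 + (center - radius_mm) / spacing))
  hi <- pmin(shape, ceiling(1 + (center + radius_mm) / spacing))
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Voxelize an ellipsoid (optionally rotated / perturbed) into a label array
#'
#' Marks voxels whose centers fall inside the surface. Voxel centers sit at
#' world coordinate `(i - 1) * spacing` along each axis.
#' @keywords internal
fill_ellipsoid <- function(labels, value, center, semi_axes, spacing,
                           rotation = NULL, field = NULL) {
  shape <- dim(labels)
  rad <- max(semi_axes) * (if (is.null(field)) 1 else 1.6)
  bb <- voxel_grid_bbox(center, rad, spacing, shape)
  if (any(bb$lo > bb$hi)) return(labels)
  ii <- bb$lo[1]:bb$hi[1]; jj <- bb$lo[2]:bb$hi[2]; kk <- bb$lo[3]:bb$hi[3]
  xs <- (ii - 1) * spacing[1] - center[1]
  ys <- (jj - 1) * spacing[2] - center[2]
  zs <- (kk - 1) * spacing[3] - center[3]
  n1 <- length(ii); n2 <- length(jj); n3 <- length(kk)
  P <- cbind(rep(xs, times = n2 * n3),
             rep(rep(ys, each = n1), times = n3),
             rep(zs, each = n1 * n2))
  if (!is.null(rotation)) P <- P %*% rotation  # world -> lesion frame (R^T p)
  E <- sweep(P, 2, semi_axes, `/`)
  r <- sqrt(rowSums(E^2))
  if (is.null(field)) {
    inside <- r <= 1
  } else {
    nrm <- sqrt(rowSums(P^2))
    U <- P / pmax(nrm, 1e-12)
    inside <- r <= 1 + field(U)
  }
  idx <- cbind(rep(ii, times = n2 * n3),
               rep(rep(jj, each = n1), times = n3),
               rep(kk, each = n1 * n2))[inside, , drop = FALSE]
  if (nrow(idx)) {
    lin <- (idx[, 3] - 1L) * (shape[1] * shape[2]) +
      (idx[, 2] - 1L) * shape[1] + idx[, 1]
    labels[lin] <- value
  }
  labels
}

#' Render a lesion spec into a voxel label mask
#'
#' Voxelizes the main residue (perturbed ellipsoid), unions the satellite
#' residues, then carves the resection cavity. Voxel labels follow the
#' package convention: 0 background, 1 tumor, 2 cavity. The cavity is
#' labelled after the union so measurement rules can distinguish "crossing
#' the cavity" from "crossing normal brain".
#'
#' @param spec a [lesion_spec()]
#' @param spacing voxel spacing in mm, length 3
#' @param shape image grid size in voxels, length 3
#' @return a [lesion_mask()] with labels in `{0, 1, 2}`
#' @examples
#' sp <- lesion_spec(center = c(32, 32, 32), semi_axes = c(10, 10, 10))
#' m <- generate_lesion_mask(sp, spacing = c(1, 1, 1), shape = c(64, 64, 64))
#' sum(m$labels == 1) / 1000  # approx (4/3) pi 10^3 / 1000 mL
#' @export
generate_lesion_mask <- function(spec, spacing = c(1, 1, 1),
                                 shape = c(128, 128, 128)) {
  stopifnot(inherits(spec, "lesion_spec"),
            length(spacing) == 3L, all(spacing > 0),
            length(shape) == 3L, all(shape >= 2))
  shape <- as.integer(shape)
  extent <- (shape - 1L) * spacing
  check_fit <- function(center, radius, what) {
    # radius: per-axis support half-width (length 1 or 3)
    radius <- rep_len(radius, 3L)
    for (ax in 1:3) {
      if (center[ax] - radius[ax] < 0 || center[ax] + radius[ax] > extent[ax]) {
        stop(sprintf(
          "%s exceeds image bounds along the %s axis (needs [%.1f, %.1f] mm, image spans [0, %.1f] mm)",
          what, c("x", "y", "z")[ax], center[ax] - radius[ax],
          center[ax] + radius[ax], extent[ax]), call. = FALSE)
      }
    }
  }
  R_fit <- euler_rotation(spec$orientation)
  # support of the rotated ellipsoid along world axis i:
  # sqrt(sum_j (a_j R[i,j])^2)
  support <- sqrt((R_fit^2) %*% (spec$semi_axes^2))[, 1]
  check_fit(spec$center, support * (1 + spec$irregularity_amplitude),
            "main lesion")
  for (i in seq_along(spec$satellites)) {
    st <- spec$satellites[[i]]
    check_fit(st$center, st$semi_axes, sprintf("satellite %d", i))
  }

  labels <- array(0L, dim = shape)
  R <- euler_rotation(spec$orientation)
  field <- if (spec$irregularity_amplitude > 0) {
    irregularity_field(spec$irregularity_amplitude, spec$irregularity_seed)
  } else NULL
  labels <- fill_ellipsoid(labels, 1L, spec$center, spec$semi_axes, spacing,
                           rotation = R, field = field)
  for (st in spec$satellites) {
    labels <- fill_ellipsoid(labels, 1L, st$center, st$semi_axes, spacing)
  }
  if (!is.null(spec$cavity)) {
    labels <- fill_ellipsoid(labels, 2L, spec$cavity$center,
                             rep(spec$cavity$radius, 3), spacing)
  }
  lesion_mask(labels, spacing)
}
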