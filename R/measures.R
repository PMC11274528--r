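## Linear measurement of a lesion mask.
##
## Caliper conventions, applied consistently so that identities such as
## W = D1 = D2 = D3 hold on a voxelized sphere:
##   * chord length = euclidean distance between voxel centers plus one
##     in-plane voxel projected onto the chord direction (compensates the
##     half-voxel truncation at both ends);
##   * axis extents  = (max index - min index + 1) * spacing.

#' @keywords internal
slice_boundary_points <- function(slmat) {
  # tumor pixels with at least one 4-neighbour outside the tumor
  nr <- nrow(slmat); nc <- ncol(slmat)
  up <- rbind(FALSE, slmat[-nr, , drop = FALSE])
  dn <- rbind(slmat[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, slmat[, -nc, drop = FALSE])
  rt <- cbind(slmat[, -1, drop = FALSE], FALSE)
  which(slmat & !(up & dn & lf & rt), arr.ind = TRUE)
}

#' Fraction of a chord lying outside tumor tissue
#'
#' Samples each chord at `2 * ceiling(slice diagonal in voxels) + 1` evenly
#' spaced points between the two endpoint voxel centers (at least
#' half-voxel resolution for every chord in the slice, and a fixed, batch
#' independent definition) and returns the fraction of samples on non-tumor
#' labels (cavity *or* background -- both are penalized by the LGG
#' measurement rules).
#' @param labmat integer slice matrix (0/1/2)
#' @param p1,p2 k x 2 index matrices of chord endpoints
#' @return numeric vector of length k in [0, 1]
#' @keywords internal
chord_crossing <- function(labmat, p1, p2) {
  k <- nrow(p1)
  dx <- p2[, 1] - p1[, 1]
  dy <- p2[, 2] - p1[, 2]
  n_s <- 2L * ceiling(sqrt(nrow(labmat)^2 + ncol(labmat)^2)) + 1L
  tt <- seq(0, 1, length.out = n_s)
  xi <- round(p1[, 1] + outer(dx, tt))
  yj <- round(p1[, 2] + outer(dy, tt))
  xi[xi < 1L] <- 1L; xi[xi > nrow(labmat)] <- nrow(labmat)
  yj[yj < 1L] <- 1L; yj[yj > ncol(labmat)] <- ncol(labmat)
  hit <- matrix(labmat[cbind(as.vector(xi), as.vector(yj))] != 1L, k, n_s)
  rowMeans(hit)
}

#' @keywords internal
corrected_length <- function(dxw, dyw, sx, sy) {
  len <- sqrt(dxw^2 + dyw^2)
  ux <- ifelse(len > 0, dxw / len, 1)
  uy <- ifelse(len > 0, dyw / len, 0)
  len + sqrt((sx * ux)^2 + (sy * uy)^2)
}

#' Longest tolerance-compliant chord within one axial slice
#' @keywords internal
slice_longest_chord <- function(labmat, sx, sy, crossing_tolerance,
                                max_boundary, batch = 128L) {
  bp <- slice_boundary_points(labmat == 1L)
  flags <- character(0)
  if (nrow(bp) < 2L) {
    return(list(best = NULL, fallback = NULL, degenerate = nrow(bp) == 1L,
                bp = bp, flags = flags))
  }
  if (nrow(bp) > max_boundary) {
    stride <- ceiling(nrow(bp) / max_boundary)
    bp <- bp[seq(1L, nrow(bp), by = stride), , drop = FALSE]
    flags <- "boundary_subsampled"
  }
  k <- nrow(bp)
  pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  dxw <- (bp[pr[, 2], 1] - bp[pr[, 1], 1]) * sx
  dyw <- (bp[pr[, 2], 2] - bp[pr[, 1], 2]) * sy
  len <- corrected_length(dxw, dyw, sx, sy)
  ord <- order(len, decreasing = TRUE)
  best <- NULL
  fb <- list(crossing = Inf, length = -Inf)
  for (start in seq(1L, length(ord), by = batch)) {
    sel <- ord[start:min(start + batch - 1L, length(ord))]
    cr <- chord_crossing(labmat, bp[pr[sel, 1], , drop = FALSE],
                         bp[pr[sel, 2], , drop = FALSE])
    ok <- which(cr <= crossing_tolerance)
    if (length(ok)) {
      i <- ok[1L]
      best <- list(length = len[sel[i]], crossing = cr[i],
                   endpoints = rbind(bp[pr[sel[i], 1], ], bp[pr[sel[i], 2], ]))
      break
    }
    i <- which.min(cr)
    if (cr[i] < fb$crossing ||
        (cr[i] == fb$crossing && len[sel[i]] > fb$length)) {
      fb <- list(length = len[sel[i]], crossing = cr[i],
                 endpoints = rbind(bp[pr[sel[i], 1], ], bp[pr[sel[i], 2], ]))
    }
  }
  list(best = best, fallback = if (is.null(best)) fb else NULL,
       degenerate = FALSE, bp = bp, flags = flags)
}

#' @keywords internal
line_angle_to <- function(dxw, dyw, theta_ref) {
  # acute angle (radians, in [0, pi/2]) between each chord and a reference line
  d <- abs(atan2(dyw, dxw) - theta_ref) %% pi
  pmin(d, pi - d)
}

#' Tumor width and perpendicular width of a lesion mask
#'
#' `W` is the longest in-plane (axial) chord between two tumor boundary
#' voxels whose cavity/background crossing fraction does not exceed
#' `crossing_tolerance`; `PW` is the longest such chord in the *same* axial
#' slice within `perp_tol_deg` of perpendicular to `W`. Both follow the
#' post-surgical LGG rules: chords must remain within tumor tissue as much
#' as possible, and crossing of the resection cavity is maximally avoided.
#' If no chord on any slice meets the tolerance, the chord with minimal
#' crossing fraction is used and flagged `"w_fallback"`.
#'
#' Call [largest_residue()] first: width is defined on the largest residue
#' only.
#'
#' @param mask a [lesion_mask()] (largest residue)
#' @param crossing_tolerance maximal allowed fraction of the chord length
#'   outside tumor tissue (default 0.10)
#' @param perp_tol_deg angular tolerance (degrees) around exact
#'   perpendicularity for the PW chord (default 5)
#' @param exact if `TRUE`, never subsample boundary points (exhaustive
#'   search; used by the validation suite)
#' @param max_boundary boundary-point budget per slice before uniform
#'   stride subsampling kicks in (ignored when `exact = TRUE`)
#' @return a list with elements `W`, `PW` (mm), `w_slice_index`,
#'   `w_endpoints`, `pw_endpoints` (voxel indices), `cavity_crossing_fraction`,
#'   `pw_crossing_fraction`, and `flags` (character vector; possible values
#'   `"degenerate"`, `"w_fallback"`, `"pw_fallback"`, `"pw_degenerate"`,
#'   `"boundary_subsampled"`, `"pw_clamped"`)
#' @export
extract_w_pw <- function(mask, crossing_tolerance = 0.10, perp_tol_deg = 5,
                         exact = FALSE, max_boundary = 2000L) {
  stopifnot(inherits(mask, "lesion_mask"))
  labs <- mask$labels
  sx <- mask$spacing[1]; sy <- mask$spacing[2]
  if (exact) max_boundary <- .Machine$integer.max
  nz <- dim(labs)[3]
  slice_has <- vapply(seq_len(nz), function(z) any(labs[, , z] == 1L), logical(1))
  if (!any(slice_has)) {
    stop("no measurable lesion: mask contains no tumor voxels", call. = FALSE)
  }
  zs <- which(slice_has)
  voxdiag <- sqrt(sx^2 + sy^2)
  # cheap per-slice upper bound: in-plane bounding-box diagonal + 1 voxel
  bound <- vapply(zs, function(z) {
    ai <- which(labs[, , z] == 1L, arr.ind = TRUE)
    dxw <- (max(ai[, 1]) - min(ai[, 1])) * sx
    dyw <- (max(ai[, 2]) - min(ai[, 2])) * sy
    sqrt(dxw^2 + dyw^2) + voxdiag
  }, numeric(1))
  zs <- zs[order(bound, decreasing = TRUE)]
  bound <- sort(bound, decreasing = TRUE)

  best <- NULL; best_z <- NA_integer_
  fb <- NULL; fb_z <- NA_integer_
  degen_only <- TRUE
  flags <- character(0)
  for (i in seq_along(zs)) {
    if (!is.null(best) && bound[i] <= best$length) break
    res <- slice_longest_chord(labs[, , zs[i]], sx, sy, crossing_tolerance,
                               max_boundary)
    flags <- union(flags, res$flags)
    if (res$degenerate || is.null(res$best) && is.null(res$fallback)) next
    degen_only <- FALSE
    if (!is.null(res$best)) {
      if (is.null(best) || res$best$length > best$length) {
        best <- res$best; best_z <- zs[i]
      }
    } else if (is.null(best)) {
      if (is.null(fb) || res$fallback$crossing < fb$crossing ||
          (res$fallback$crossing == fb$crossing &&
           res$fallback$length > fb$length)) {
        fb <- res$fallback; fb_z <- zs[i]
      }
    }
  }

  if (degen_only) {
    # lesion is a single voxel (or a stack of single-voxel slices)
    return(list(W = voxdiag, PW = voxdiag, w_slice_index = zs[1],
                w_endpoints = NULL, pw_endpoints = NULL,
                cavity_crossing_fraction = 0, pw_crossing_fraction = 0,
                flags = union(flags, "degenerate")))
  }
  if (is.null(best)) {
    best <- fb; best_z <- fb_z
    flags <- union(flags, "w_fallback")
  }

  # PW: longest near-perpendicular compliant chord in W's slice
  labz <- labs[, , best_z]
  e <- best$endpoints
  theta_w <- atan2((e[2, 2] - e[1, 2]) * sy, (e[2, 1] - e[1, 1]) * sx)
  bp <- slice_boundary_points(labz == 1L)
  if (nrow(bp) > max_boundary) {
    bp <- bp[seq(1L, nrow(bp), by = ceiling(nrow(bp) / max_boundary)), ,
             drop = FALSE]
  }
  k <- nrow(bp)
  pw <- NULL; pw_cross <- 0
  if (k >= 2L) {
    pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    dxw <- (bp[pr[, 2], 1] - bp[pr[, 1], 1]) * sx
    dyw <- (bp[pr[, 2], 2] - bp[pr[, 1], 2]) * sy
    ang <- line_angle_to(dxw, dyw, theta_w)
    keep <- which(ang >= (90 - perp_tol_deg) * pi / 180)
    if (length(keep)) {
      len <- corrected_length(dxw[keep], dyw[keep], sx, sy)
      ord <- keep[order(len, decreasing = TRUE)]
      lens <- sort(len, decreasing = TRUE)
      fbp <- list(crossing = Inf, length = -Inf)
      for (start in seq(1L, length(ord), by = 128L)) {
        sel <- start:min(start + 127L, length(ord))
        cr <- chord_crossing(labz, bp[pr[ord[sel], 1], , drop = FALSE],
                             bp[pr[ord[sel], 2], , drop = FALSE])
        ok <- which(cr <= crossing_tolerance)
        if (length(ok)) {
          pw <- list(length = lens[sel[ok[1L]]], crossing = cr[ok[1L]],
                     endpoints = rbind(bp[pr[ord[sel[ok[1L]]], 1], ],
                                       bp[pr[ord[sel[ok[1L]]], 2], ]))
          break
        }
        i <- which.min(cr)
        if (cr[i] < fbp$crossing) {
          fbp <- list(length = lens[sel[i]], crossing = cr[i],
                      endpoints = rbind(bp[pr[ord[sel[i]], 1], ],
                                        bp[pr[ord[sel[i]], 2], ]))
        }
      }
      if (is.null(pw)) {
        pw <- fbp
        flags <- union(flags, "pw_fallback")
      }
    }
  }
  if (is.null(pw)) {
    pw <- list(length = voxdiag, crossing = 0, endpoints = NULL)
    flags <- union(flags, "pw_degenerate")
  }
  if (pw$length > best$length) {  # can occur only via fallback paths
    pw$length <- best$length
    flags <- union(flags, "pw_clamped")
  }
  list(W = best$length, PW = pw$length,
       w_slice_index = best_z,
       w_endpoints = best$endpoints, pw_endpoints = pw$endpoints,
       cavity_crossing_fraction = best$crossing,
       pw_crossing_fraction = pw$crossing,
       flags = flags)
}

#' Axis-aligned maximal extents D1, D2, D3
#'
#' D1 is the maximal transversal extent (x), D2 the maximal antero-posterior
#' extent (y) and D3 the maximal height (z) of the tumor, measured as
#' whole-residue projections onto the anatomical axes:
#' `(max - min voxel index + 1) * spacing` in mm. Call [largest_residue()]
#' first when multiple residues are present.
#'
#' @param mask a [lesion_mask()]
#' @return named numeric vector `c(D1 = , D2 = , D3 = )` in mm
#' @export
extract_d123 <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  ai <- which(mask$labels == 1L, arr.ind = TRUE)
  if (!nrow(ai)) {
    stop("no measurable lesion: mask contains no tumor voxels", call. = FALSE)
  }
  ext <- (apply(ai, 2, max) - apply(ai, 2, min) + 1) * mask$spacing
  c(D1 = ext[[1]], D2 = ext[[2]], D3 = ext[[3]])
}

#' Segmented tumor volume
#'
#' The reference volume: the concatenated area of the tumor outline on each
#' axial slice, extruded across the slice pitch (slice thickness plus any
#' declared inter-slice gap). Unlike the linear measures, *every* tumor
#' residue counts.
#'
#' @param mask a [lesion_mask()]
#' @param slice_gap declared gap between consecutive axial slices in mm
#'   (default 0 for contiguous acquisitions)
#' @return volume in mL
#' @export
segmented_volume <- function(mask, slice_gap = 0) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!is_scalar_number(slice_gap) || slice_gap < 0) {
    stop("slice_gap must be a non-negative number of mm", call. = FALSE)
  }
  counts <- apply(mask$labels == 1L, 3, sum)
  pitch <- mask$spacing[3] + slice_gap
  sum(counts) * mask$spacing[1] * mask$spacing[2] * pitch / 1000
}

#' Linear size estimates and measurability flags for one scan
#'
#' Combines the five diameters and the segmented volume into the per-scan
#' size record: `size_1d = W` (mm), `size_2d = W * PW` (mm^2),
#' `size_3d = (D1 * D2 * D3) / 2` (ellipsoid half-product, converted to mL),
#' plus the measurability flags (a tumor is non-measurable below 10 mm for
#' 1D, 100 mm^2 for 2D, 0.5 mL for 3D).
#'
#' @param d named list or vector with `W`, `PW`, `D1`, `D2`, `D3` in mm
#' @param volume_seg segmented volume in mL
#' @param thresholds a [threshold_config()]
#' @return one-row `data.frame`
#' @export
size_estimates <- function(d, volume_seg, thresholds = threshold_config()) {
  W <- d[["W"]]; PW <- d[["PW"]]
  D1 <- d[["D1"]]; D2 <- d[["D2"]]; D3 <- d[["D3"]]
  stopifnot(all(vapply(list(W, PW, D1, D2, D3), is_scalar_number, logical(1))),
            W >= 0, PW >= 0, D1 >= 0, D2 >= 0, D3 >= 0)
  size_1d <- W
  size_2d <- W * PW
  size_3d <- D1 * D2 * D3 / 2 / 1000  # mm^3 -> mL
  data.frame(
    size_1d = size_1d, size_2d = size_2d, size_3d = size_3d,
    volume_seg = volume_seg,
    measurable_1d = size_1d >= thresholds$min_1d,
    measurable_2d = size_2d >= thresholds$min_2d,
    measurable_3d = size_3d >= thresholds$min_3d
  )
}

#' Full measurement of one lesion mask
#'
#' Runs the whole per-scan protocol: largest-residue selection, W/PW chord
#' search, D1/D2/D3 extents, segmented volume (all residues), size
#' estimates, and both MTD variants.
#'
#' @inheritParams extract_w_pw
#' @param thresholds a [threshold_config()]
#' @param slice_gap declared inter-slice gap in mm (see [segmented_volume()])
#' @return one-row `data.frame` with diameters (mm), sizes, volume (mL),
#'   `mtd_3d`, `mtd_v` (mm), component count, crossing fraction and flags
#' @export
measure_mask <- function(mask, thresholds = threshold_config(),
                         crossing_tolerance = 0.10, slice_gap = 0,
                         exact = FALSE) {
  main <- largest_residue(mask)
  wp <- extract_w_pw(main, crossing_tolerance = crossing_tolerance,
                     exact = exact)
  d3 <- extract_d123(main)
  vol <- segmented_volume(mask, slice_gap = slice_gap)
  sizes <- size_estimates(c(W = wp$W, PW = wp$PW, d3), vol, thresholds)
  cbind(
    data.frame(W = wp$W, PW = wp$PW,
               D1 = d3[["D1"]], D2 = d3[["D2"]], D3 = d3[["D3"]]),
    sizes,
    data.frame(
      mtd_3d = mtd_from_diameters(d3[["D1"]], d3[["D2"]], d3[["D3"]]),
      mtd_v = mtd_from_volume(vol),
      n_components = attr(main, "n_components"),
      retained_fraction = attr(main, "retained_fraction"),
      cavity_crossing_fraction = wp$cavity_crossing_fraction,
      flags = paste(wp$flags, collapse = ";")
    )
  )
}
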