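# Independent brute-force oracles and fixture builders.
# These deliberately re-derive quantities with naive loops / closed forms,
# sharing only the documented *definitions* with the package code, never its
# code paths.

# --- slice chord oracle -------------------------------------------------

# boundary pixels: tumor with a 4-neighbour outside tumor (naive loop)
oracle_boundary <- function(slmat) {
  nr <- nrow(slmat); nc <- ncol(slmat)
  out <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!slmat[i, j]) next
      nb_in <- (i > 1 && slmat[i - 1, j]) && (i < nr && slmat[i + 1, j]) &&
        (j > 1 && slmat[i, j - 1]) && (j < nc && slmat[i, j + 1])
      if (!nb_in) out <- rbind(out, c(i, j))
    }
  }
  out
}

# crossing fraction definition: 2*ceil(slice diagonal in voxels)+1 samples
# along the segment between voxel centers; fraction of samples off-tumor
oracle_crossing <- function(labmat, p, q) {
  n_s <- 2L * ceiling(sqrt(nrow(labmat)^2 + ncol(labmat)^2)) + 1L
  tt <- seq(0, 1, length.out = n_s)
  xi <- round(p[1] + tt * (q[1] - p[1]))
  yj <- round(p[2] + tt * (q[2] - p[2]))
  xi <- pmin(pmax(xi, 1L), nrow(labmat))
  yj <- pmin(pmax(yj, 1L), ncol(labmat))
  mean(labmat[cbind(xi, yj)] != 1L)
}

oracle_chord_len <- function(p, q, sx, sy) {
  dxw <- (q[1] - p[1]) * sx
  dyw <- (q[2] - p[2]) * sy
  len <- sqrt(dxw^2 + dyw^2)
  if (len == 0) return(0)
  len + sqrt((sx * dxw / len)^2 + (sy * dyw / len)^2)
}

# longest compliant chord in one slice by exhaustive pair enumeration
oracle_slice_w <- function(labmat, sx, sy, tol = 0.10) {
  bp <- oracle_boundary(labmat == 1L)
  if (is.null(bp) || nrow(bp) < 2L) return(NULL)
  best <- NULL
  for (a in seq_len(nrow(bp) - 1L)) {
    for (b in (a + 1L):nrow(bp)) {
      len <- oracle_chord_len(bp[a, ], bp[b, ], sx, sy)
      if (!is.null(best) && len <= best$len) next
      if (oracle_crossing(labmat, bp[a, ], bp[b, ]) <= tol) {
        best <- list(len = len, p = bp[a, ], q = bp[b, ])
      }
    }
  }
  best
}

# W over the whole mask: max over slices of the exhaustive slice search
oracle_w <- function(mask, tol = 0.10) {
  best <- NULL
  for (z in seq_len(dim(mask$labels)[3])) {
    sl <- mask$labels[, , z]
    if (!any(sl == 1L)) next
    r <- oracle_slice_w(sl, mask$spacing[1], mask$spacing[2], tol)
    if (!is.null(r) && (is.null(best) || r$len > best$len)) {
      best <- r; best$z <- z
    }
  }
  best
}

# longest compliant chord within +/- perp_tol_deg of perpendicular to theta_w
oracle_pw <- function(labmat, sx, sy, theta_w, tol = 0.10, perp_tol_deg = 5) {
  bp <- oracle_boundary(labmat == 1L)
  if (is.null(bp) || nrow(bp) < 2L) return(NULL)
  best <- NULL
  for (a in seq_len(nrow(bp) - 1L)) {
    for (b in (a + 1L):nrow(bp)) {
      dxw <- (bp[b, 1] - bp[a, 1]) * sx
      dyw <- (bp[b, 2] - bp[a, 2]) * sy
      d <- abs(atan2(dyw, dxw) - theta_w) %% pi
      d <- min(d, pi - d)
      if (d < (90 - perp_tol_deg) * pi / 180) next
      len <- oracle_chord_len(bp[a, ], bp[b, ], sx, sy)
      if (!is.null(best) && len <= best$len) next
      if (oracle_crossing(labmat, bp[a, ], bp[b, ]) <= tol) {
        best <- list(len = len, p = bp[a, ], q = bp[b, ])
      }
    }
  }
  best
}

# --- mask builders ------------------------------------------------------

# direct voxelization of a sphere into a label array (independent of
# generate_lesion_mask)
build_sphere_array <- function(shape, center_vox, radius_vox, value = 1L,
                               base = NULL) {
  labs <- if (is.null(base)) array(0L, dim = shape) else base
  for (z in seq_len(shape[3])) {
    dz2 <- (z - center_vox[3])^2
    if (dz2 > radius_vox^2) next
    r2 <- radius_vox^2 - dz2
    for (x in seq_len(shape[1])) {
      dx2 <- (x - center_vox[1])^2
      if (dx2 > r2) next
      yr <- sqrt(r2 - dx2)
      ys <- seq_len(shape[2])
      sel <- ys[abs(ys - center_vox[2]) <= yr]
      labs[x, sel, z] <- value
    }
  }
  labs
}

# a random multi-lobed slice stack for chord-oracle fuzzing: a few ellipse
# lobes, optionally a cavity disc, embedded in a small 3D array
random_blob_mask <- function(n_side = 48L, n_slices = 3L, cavity = FALSE) {
  labs <- array(0L, dim = c(n_side, n_side, n_slices))
  cx <- n_side / 2 + runif(1, -4, 4)
  cy <- n_side / 2 + runif(1, -4, 4)
  xg <- matrix(seq_len(n_side), n_side, n_side)
  yg <- t(xg)
  for (z in seq_len(n_slices)) {
    sl <- matrix(FALSE, n_side, n_side)
    for (k in seq_len(sample(2:4, 1))) {
      a <- runif(1, 5, n_side / 3); b <- runif(1, 4, n_side / 4)
      th <- runif(1, 0, pi)
      ox <- cx + runif(1, -6, 6); oy <- cy + runif(1, -6, 6)
      xr <- (xg - ox) * cos(th) + (yg - oy) * sin(th)
      yr <- -(xg - ox) * sin(th) + (yg - oy) * cos(th)
      sl <- sl | (xr / a)^2 + (yr / b)^2 <= 1
    }
    if (cavity) {
      cr <- runif(1, 3, 7)
      cav <- (xg - cx)^2 + (yg - cy)^2 <= cr^2
      slz <- ifelse(cav, 2L, ifelse(sl, 1L, 0L))
    } else {
      slz <- ifelse(sl, 1L, 0L)
    }
    labs[, , z] <- slz
  }
  lesion_mask(labs, c(1, 1, 1))
}

# half-annulus ("C-shape") slice embedded in a 3-slice mask
c_shape_mask <- function(n_side = 64L, r_out = 26, r_in = 16) {
  labs <- array(0L, dim = c(n_side, n_side, 3L))
  cx <- n_side / 2; cy <- n_side / 2
  xg <- matrix(seq_len(n_side), n_side, n_side)
  yg <- t(xg)
  r2 <- (xg - cx)^2 + (yg - cy)^2
  ring <- r2 <= r_out^2 & r2 >= r_in^2
  half <- yg >= cy  # keep one half -> open C
  labs[, , 2][ring & half] <- 1L
  lesion_mask(labs, c(1, 1, 1))
}

# --- independent statistics oracles -------------------------------------

# Lin's CCC straight from the published formula, population moments,
# written as one arithmetic expression
oracle_ccc <- function(x, y) {
  n <- length(x)
  2 * (sum(x * y) / n - mean(x) * mean(y)) /
    ((sum(x^2) / n - mean(x)^2) + (sum(y^2) / n - mean(y)^2) +
       (mean(x) - mean(y))^2)
}

# AUC as the normalized Mann-Whitney U statistic (ties get half credit)
oracle_auc <- function(changes, truth) {
  pos <- changes[truth]
  neg <- changes[!truth]
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  u / (length(pos) * length(neg))
}
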