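#' Analytic description of a post-surgical LGG lesion
#'
#' A `lesion_spec` describes one lesion in continuous (world, mm) coordinates:
#' a main residue modelled as a rotated ellipsoid whose radius may be
#' modulated by a smooth angular irregularity field, an optional resection
#' cavity (sphere), and 0 or more satellite residues (small ellipsoids).
#' The spec is the analytic ground truth from which voxelized masks are
#' rendered; all downstream measurements can be checked against it.
#'
#' The "true" size quantities of a spec refer to the unperturbed main
#' ellipsoid and live on the linear-measure scale used throughout the
#' follow-up protocol: `true_mtd = (2a * 2b * 2c)^(1/3)` (so a sphere of
#' diameter d has true MTD exactly d, and growth at a given VDE moves the
#' MTD linearly) and `true_volume = true_mtd^3 / 2`, the volume under the
#' ellipsoid-halving convention. The geometric ellipsoid volume
#' `(4/3) pi a b c` is smaller by the factor `3/pi`; comparisons with the
#' voxelized segmented volume use the geometric form directly. The
#' irregularity field is mean-zero, and satellites/cavity are deviations the
#' measurement pipeline has to cope with, not part of the nominal truth.
#'
#' @param center numeric length-3, lesion center in mm (world coordinates).
#' @param semi_axes numeric length-3 `(a, b, c)` in mm, all positive.
#' @param orientation numeric length-3 Euler angles (radians), intrinsic
#'   Z-Y-X rotation applied to the ellipsoid.
#' @param irregularity_amplitude fraction of local radius in `[0, 0.5]` by
#'   which the smooth angular field modulates the surface.
#' @param irregularity_seed integer seed for the irregularity field; kept in
#'   the spec so a growing lesion keeps the same shape over time.
#' @param cavity `NULL` or `list(center = <mm 3-vector>, radius = <mm>)`.
#' @param satellites list of `list(center = <mm 3-vector>,
#'   semi_axes = <mm 3-vector>)`.
#' @param true_vde true velocity of diameter expansion in mm/year (typical
#'   LGG range 3--4 mm/year; 8 mm/year is the anaplastic-transformation
#'   alarm level).
#' @return object of class `lesion_spec`
#' @seealso [grow_spec()], [generate_lesion_mask()]
#' @export
lesion_spec <- function(center, semi_axes,
                        orientation = c(0, 0, 0),
                        irregularity_amplitude = 0,
                        irregularity_seed = 1L,
                        cavity = NULL,
                        satellites = list(),
                        true_vde = 0) {
  stopifnot(length(center) == 3L, is.numeric(center),
            length(semi_axes) == 3L, is.numeric(semi_axes),
            length(orientation) == 3L, is.numeric(orientation))
  if (any(semi_axes <= 0)) stop("semi_axes must all be > 0", call. = FALSE)
  if (!is_scalar_number(irregularity_amplitude) ||
      irregularity_amplitude < 0 || irregularity_amplitude > 0.5) {
    stop("irregularity_amplitude must be in [0, 0.5]", call. = FALSE)
  }
  if (!is.null(cavity)) {
    stopifnot(is.list(cavity), length(cavity$center) == 3L,
              is_scalar_number(cavity$radius), cavity$radius > 0)
    # the cavity must overlap or abut the main lesion's bounding box
    bb_lo <- center - max(semi_axes)
    bb_hi <- center + max(semi_axes)
    if (any(cavity$center + cavity$radius < bb_lo) ||
        any(cavity$center - cavity$radius > bb_hi)) {
      stop("cavity does not overlap or abut the main lesion bounding box",
           call. = FALSE)
    }
  }
  for (s in satellites) {
    stopifnot(length(s$center) == 3L, length(s$semi_axes) == 3L)
    if (any(s$semi_axes <= 0)) {
      stop("satellite semi_axes must all be > 0", call. = FALSE)
    }
  }
  structure(
    list(center = as.numeric(center),
         semi_axes = as.numeric(semi_axes),
         orientation = as.numeric(orientation),
         irregularity_amplitude = irregularity_amplitude,
         irregularity_seed = as.integer(irregularity_seed),
         cavity = cavity,
         satellites = satellites,
         true_vde = true_vde),
    class = "lesion_spec"
  )
}

#' True size quantities of a lesion spec
#'
#' Nominal volume (mL, halving convention: `(2a * 2b * 2c) / 2`), principal
#' diameters (mm) and mean tumor diameter (mm) of the unperturbed main
#' ellipsoid. `true_mtd(spec)` equals `mtd_from_volume(true_volume(spec))`
#' exactly, by construction.
#'
#' @param spec a [lesion_spec()]
#' @return numeric scalar (or length-3 vector for `true_diameters`)
#' @export
true_volume <- function(spec) {
  a <- spec$semi_axes
  4 * a[1] * a[2] * a[3] / 1000  # (2a)(2b)(2c)/2, mm^3 -> mL
}

#' @rdname true_volume
#' @export
true_diameters <- function(spec) 2 * spec$semi_axes

#' @rdname true_volume
#' @export
true_mtd <- function(spec) {
  (2 * true_volume(spec) * 1000)^(1 / 3)
}

#' Grow a lesion spec forward in time
#'
#' Advances a lesion by `dt` years at its own `true_vde`: the true MTD of the
#' main residue increases by exactly `true_vde * dt` mm. In `isotropic` mode
#' all three semi-axes are scaled by the same factor; in `anisotropic` mode
#' the whole MTD increment is allocated to a single axis (LGGs preferentially
#' grow along white matter fiber bundles), leaving the other two unchanged.
#' Satellite residues are scaled by the same linear factor as the isotropic
#' main-lesion growth, so multi-residue lesions grow "in concert" -- the
#' situation in which diameter-based measures under-read the whole-lesion
#' growth. The cavity and the irregularity field are unchanged.
#'
#' @param spec a [lesion_spec()]
#' @param dt time step in years, `>= 0`
#' @param mode `"isotropic"` or `"anisotropic"`
#' @param axis which semi-axis receives the growth in anisotropic mode (1-3)
#' @return a new `lesion_spec`
#' @export
grow_spec <- function(spec, dt, mode = c("isotropic", "anisotropic"),
                      axis = 1L) {
  mode <- match.arg(mode)
  if (!is_scalar_number(dt) || dt < 0) {
    stop("dt must be a non-negative number of years", call. = FALSE)
  }
  if (dt == 0) return(spec)
  mtd0 <- true_mtd(spec)
  mtd1 <- mtd0 + spec$true_vde * dt
  if (mtd1 <= 0) {
    stop("growth step would shrink the lesion to non-positive MTD",
         call. = FALSE)
  }
  s <- mtd1 / mtd0  # linear scale factor; volume scales as s^3
  out <- spec
  if (mode == "isotropic") {
    out$semi_axes <- spec$semi_axes * s
  } else {
    # all volume change on one axis: product abc must scale by s^3
    out$semi_axes[axis] <- spec$semi_axes[axis] * s^3
  }
  if (length(spec$satellites)) {
    out$satellites <- lapply(spec$satellites, function(st) {
      st$semi_axes <- st$semi_axes * s
      st
    })
  }
  out
}
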