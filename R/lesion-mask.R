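#' Labelled lesion mask
#'
#' The geometric substrate of all measurements: a 3D integer label array
#' (0 background, 1 tumor, 2 resection cavity) plus the voxel spacing in mm.
#' Axis convention: x transversal (left-right), y antero-posterior,
#' z inferior-superior -- i.e. the canonical RAS-aligned voxel grid; the
#' third array index runs over axial slices.
#'
#' @param labels 3D integer array with values in `{0, 1, 2}`
#' @param spacing voxel spacing in mm, length 3, all positive
#' @return object of class `lesion_mask`
#' @export
lesion_mask <- function(labels, spacing) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array", call. = FALSE)
  if (!all(labels %in% c(0L, 1L, 2L))) {
    stop("labels must only contain 0 (background), 1 (tumor), 2 (cavity)",
         call. = FALSE)
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels @ %s mm | tumor %d, cavity %d voxels\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' Read a lesion mask from a NIfTI file
#'
#' Reads a label volume (0 background / 1 tumor / 2 cavity), reorients it to
#' the canonical RAS axes using the NIfTI affine (so D1/D2/D3 are always
#' transversal / antero-posterior / height regardless of how the file was
#' stored), and extracts the voxel spacing from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return a [lesion_mask()]
#' @export
read_lesion_mask <- function(path) {
  img <- RNifti::readNifti(path)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(orient) && nzchar(orient) && orient != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  spacing <- abs(RNifti::pixdim(img))[1:3]
  labels <- array(as.integer(round(as.array(img))), dim = dim(img)[1:3])
  lesion_mask(labels, spacing)
}

#' Write a lesion mask to a NIfTI file
#' @param mask a [lesion_mask()]
#' @param path destination path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_lesion_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Label 26-connected tumor components
#'
#' Breadth-first flood fill over the 26-neighbourhood, restricted to the
#' tumor bounding box and padded by one voxel so neighbour offsets never
#' wrap around array edges. 26-connectivity keeps thin infiltrative bridges
#' between diffuse FLAIR-defined residues connected.
#'
#' @param mask a [lesion_mask()]
#' @return integer array of the same shape: 0 outside tumor, component id
#'   (1, 2, ...) on tumor voxels; component ids are ordered by first voxel
#'   encountered in array order
#' @export
label_components <- function(mask) {
  labs <- mask$labels
  out <- array(0L, dim = dim(labs))
  tum <- which(labs == 1L)
  if (!length(tum)) return(out)
  ai <- arrayInd(tum, dim(labs))
  lo <- apply(ai, 2, min); hi <- apply(ai, 2, max)
  d <- hi - lo + 3L  # one-voxel pad on each side
  sub <- array(FALSE, dim = d)
  sub[cbind(ai[, 1] - lo[1] + 2L, ai[, 2] - lo[2] + 2L, ai[, 3] - lo[3] + 2L)] <- TRUE
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lin_offs <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  comp <- array(0L, dim = d)
  todo <- which(sub)
  cid <- 0L
  while (length(todo)) {
    cid <- cid + 1L
    frontier <- todo[1L]
    comp[frontier] <- cid
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, lin_offs, `+`)))
      nb <- nb[sub[nb] & comp[nb] == 0L]
      comp[nb] <- cid
      frontier <- nb
    }
    todo <- todo[comp[todo] == 0L]
  }
  ci <- arrayInd(which(sub), d)
  out[cbind(ci[, 1] + lo[1] - 2L, ci[, 2] + lo[2] - 2L, ci[, 3] + lo[3] - 2L)] <-
    comp[sub]
  out
}

#' Restrict a mask to its largest tumor residue
#'
#' Post-surgical LGGs often consist of several disconnected residues; linear
#' measurements are taken on the largest portion only, excluding small
#' satellite lesions. Returns the mask with tumor voxels outside the largest
#' 26-connected component set to background; cavity voxels are preserved
#' unchanged. Exact volume ties are broken toward the component with the
#' smallest lexicographic centroid, with a warning (ties do not occur on
#' real anatomy).
#'
#' @param mask a [lesion_mask()]
#' @return a [lesion_mask()] with attributes `n_components` (integer) and
#'   `retained_fraction` (retained / total tumor volume)
#' @export
largest_residue <- function(mask) {
  comp <- label_components(mask)
  n <- max(comp)
  if (n == 0L) stop("no measurable lesion: mask contains no tumor voxels",
                    call. = FALSE)
  sizes <- tabulate(comp[comp > 0L], nbins = n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    cent <- t(vapply(best, function(k) {
      colMeans(arrayInd(which(comp == k), dim(comp)))
    }, numeric(3)))
    ord <- do.call(order, as.data.frame(cent))
    best <- best[ord[1L]]
    warning("tie between equal-volume residues; keeping the one with the ",
            "smallest lexicographic centroid", call. = FALSE)
  }
  labels <- mask$labels
  labels[labels == 1L & comp != best] <- 0L
  out <- lesion_mask(labels, mask$spacing)
  attr(out, "n_components") <- n
  attr(out, "retained_fraction") <- sizes[best] / sum(sizes)
  out
}
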