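#' Image grid: dimensions, voxel size and voxel-to-mm affine
#'
#' An `image_grid` describes the sampling lattice of a volume: integer
#' dimensions, voxel edge lengths in mm, and a 4x4 affine mapping homogeneous
#' voxel indices to stereotaxic mm coordinates. The affine follows the NIfTI
#' convention (it maps 0-based indices); all R-level functions in this package
#' take and return 1-based indices, as [RNifti::worldToVoxel()] does.
#'
#' By default the grid is centred, so stereotaxic (0, 0, 0) falls at the
#' geometric centre of the volume — convenient for placing seeds given in
#' Talairach-style mm coordinates.
#'
#' @param dims integer vector of length 3, all >= 1.
#' @param voxel_size positive numeric vector of length 3 (mm); recycled.
#' @param origin mm coordinate of the first voxel (index `c(1,1,1)`). Default
#'   centres the grid on mm (0, 0, 0).
#' @param affine optional full 4x4 affine (overrides `voxel_size`/`origin`);
#'   its upper-left 3x3 block must be invertible.
#' @return An object of class `image_grid` with fields `dims`, `voxel_size`
#'   and `affine`.
#' @examples
#' g <- image_grid(c(20, 18, 14))
#' voxel_to_mm(g, c(1, 1, 1))
#' @export
image_grid <- function(dims, voxel_size = c(3, 3, 3), origin = NULL,
                       affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  if (!is.null(affine)) {
    affine <- as.matrix(affine)
    stopifnot(identical(dim(affine), c(4L, 4L)))
    if (!all(is.finite(affine)))
      stop("affine contains non-finite entries")
    if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
      stop("affine upper-left 3x3 block is singular")
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  } else {
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    stopifnot(all(voxel_size > 0))
    if (is.null(origin)) origin <- -(dims - 1) / 2 * voxel_size
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin
  }
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-6))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("objects are not on the same image grid")
  invisible(TRUE)
}

#' Map voxel indices to stereotaxic mm coordinates
#'
#' @param grid an [image_grid()].
#' @param idx 1-based voxel indices: a length-3 vector or an n x 3 matrix.
#' @return mm coordinates, same shape as `idx`.
#' @export
voxel_to_mm <- function(grid, idx) {
  m <- if (is.matrix(idx)) idx else matrix(idx, ncol = 3)
  mm <- t(grid$affine[1:3, 1:3] %*% t(m - 1)) +
    matrix(grid$affine[1:3, 4], nrow(m), 3, byrow = TRUE)
  if (is.matrix(idx)) mm else drop(mm)
}

# Round half away from zero, elementwise (deterministic tie-break for
# mm -> voxel mapping; base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map a stereotaxic mm coordinate to the nearest voxel index
#'
#' Applies the inverse affine and rounds each axis to the nearest index,
#' breaking exact ties by rounding half away from zero.
#'
#' @param grid an [image_grid()].
#' @param mm numeric length-3 mm coordinate.
#' @return Integer length-3, 1-based voxel index.
#' @export
mm_to_voxel <- function(grid, mm) {
  stopifnot(length(mm) == 3L, all(is.finite(mm)))
  cont <- solve(grid$affine, c(mm, 1))[1:3]        # 0-based continuous index
  idx <- as.integer(round_half_away(cont)) + 1L
  if (any(idx < 1L) || any(idx > grid$dims))
    stop(sprintf("mm coordinate (%g, %g, %g) maps outside the grid",
                 mm[1], mm[2], mm[3]))
  idx
}

# mm coordinates of every voxel centre, n_voxels x 3, in linear (column-major)
# voxel order.
all_voxel_mm <- function(grid) {
  idx <- arrayInd(seq_len(n_voxels(grid)), grid$dims)
  voxel_to_mm(grid, idx)
}
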