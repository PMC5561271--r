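#' 4D BOLD container
#'
#' Stores one subject-session's preprocessed BOLD run as a voxels x time
#' matrix (column-major voxel order) together with its [image_grid()] and
#' repetition time. 3D volumes are represented as a single timepoint.
#'
#' @param data a (nx, ny, nz, t) array, a (nx, ny, nz) array, or an
#'   `n_voxels x t` matrix.
#' @param grid the [image_grid()] the data live on.
#' @param tr_seconds repetition time in seconds (study value: 2.0).
#' @return An object of class `bold4d` with fields `grid`, `data`
#'   (matrix, voxels x time), `n_timepoints`, `tr_seconds`.
#' @export
bold4d <- function(data, grid, tr_seconds = 2.0) {
  if (is.array(data) && !is.matrix(data)) {
    d <- dim(data)
    if (length(d) == 3L) d <- c(d, 1L)
    stopifnot(identical(as.integer(d[1:3]), grid$dims))
    data <- matrix(data, nrow = prod(d[1:3]), ncol = d[4])
  }
  stopifnot(is.matrix(data), nrow(data) == n_voxels(grid))
  if (!all(is.finite(data))) stop("BOLD data contain non-finite values")
  stopifnot(tr_seconds > 0)
  structure(list(grid = grid, data = data,
                 n_timepoints = ncol(data), tr_seconds = tr_seconds),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  cat(sprintf("bold4d: %d voxels x %d timepoints, TR = %g s\n",
              nrow(x$data), x$n_timepoints, x$tr_seconds))
  print(x$grid)
  invisible(x)
}

#' Voxelwise statistic map
#'
#' @param values numeric vector, one value per voxel (linear order); `NA`
#'   allowed outside the analysis mask.
#' @param grid the [image_grid()].
#' @param stat_type one of `"t"`, `"F"`, `"r"`, `"z"`.
#' @param df degrees-of-freedom descriptor: a single value for t, a pair
#'   `(df1, df2)` for F, the sample size n for r.
#' @param mask optional logical vector marking the voxels the map is defined
#'   on; defaults to the non-`NA` voxels.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, grid, stat_type = c("t", "F", "r", "z"),
                     df = NULL, mask = NULL) {
  stat_type <- match.arg(stat_type)
  values <- as.numeric(values)
  stopifnot(length(values) == n_voxels(grid))
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(length(mask) == length(values))
  if (!all(is.finite(values[mask])))
    stop("statistic map is non-finite inside its mask")
  structure(list(grid = grid, values = values, stat_type = stat_type,
                 df = df, mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map (%s): %d mask voxels, df = %s\n", x$stat_type,
              sum(x$mask), paste(signif(x$df, 4), collapse = ", ")))
  invisible(x)
}

#' Binary brain mask
#'
#' @param included logical vector (one entry per voxel, linear order) or a
#'   logical/0-1 3D array.
#' @param grid the [image_grid()].
#' @return An object of class `brain_mask` with fields `grid` and `included`.
#' @export
brain_mask <- function(included, grid) {
  if (is.array(included) && !is.null(dim(included)))
    included <- as.vector(included)
  included <- as.logical(included)
  stopifnot(length(included) == n_voxels(grid))
  if (!any(included)) stop("mask is empty")
  structure(list(grid = grid, included = included), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: %d / %d voxels included\n",
              sum(x$included), length(x$included)))
  invisible(x)
}

grid_from_nifti <- function(img, path) {
  d <- dim(img)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  if (!all(is.finite(aff)))
    stop(sprintf("'%s' declares a non-finite affine", path))
  image_grid(d[1:3], affine = aff)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D or 4D NIfTI-1 file (optionally gzipped) into a [bold4d()]
#' object; 3D files yield a single-timepoint object. Data are returned on the
#' header-declared scaling; the grid is populated from the sform/qform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr_seconds repetition time to record; if `NA`, taken from the
#'   header's time pixdim when available (else 2.0).
#' @return A [bold4d()] object.
#' @export
read_volume <- function(path, tr_seconds = NA) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("'%s' is not a readable NIfTI-1 file: %s",
                                 path, conditionMessage(e))))
  d <- dim(img)
  if (!length(d) %in% c(3L, 4L))
    stop(sprintf("'%s' is %dD; expected a 3D or 4D volume", path, length(d)))
  grid <- grid_from_nifti(img, path)
  if (is.na(tr_seconds)) {
    pd <- attr(img, "pixdim")
    tr_seconds <- if (length(d) == 4L && length(pd) >= 4 && pd[4] > 0)
      pd[4] else 2.0
  }
  nt <- if (length(d) == 4L) d[4] else 1L
  bold4d(matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = nt),
         grid, tr_seconds = tr_seconds)
}

#' Write a volume, statistic map or mask as NIfTI-1
#'
#' Volumes are written as float32 with the grid's affine stored in the sform
#' (aligned-anatomy code). Statistic maps and masks are written as 3D files.
#'
#' @param x a [bold4d()], [stat_map()], fc map or [brain_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "bold4d")) {
    grid <- x$grid
    arr <- array(x$data, dim = c(grid$dims, x$n_timepoints))
    if (x$n_timepoints == 1L) arr <- array(arr, dim = grid$dims)
  } else if (inherits(x, "stat_map") || inherits(x, "fc_map")) {
    grid <- x$grid
    v <- if (inherits(x, "fc_map")) x$z else x$values
    v[is.na(v)] <- 0
    arr <- array(v, dim = grid$dims)
  } else if (inherits(x, "brain_mask")) {
    grid <- x$grid
    arr <- array(as.numeric(x$included), dim = grid$dims)
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  img <- RNifti::asNifti(arr)
  # pixdim must be consistent before the xforms are attached, or the
  # writer rescales the affine to unit voxels
  pd <- grid$voxel_size
  if (inherits(x, "bold4d") && x$n_timepoints > 1L)
    pd <- c(pd, x$tr_seconds)
  RNifti::pixdim(img) <- pd
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Intensity-threshold brain mask
#'
#' Includes every voxel whose temporal-mean intensity reaches `fraction`
#' times the grand mean of all temporal means — a standard quick separation
#' of tissue from empty background in echo-planar volumes.
#'
#' @param bold a [bold4d()].
#' @param fraction threshold fraction in (0, 1).
#' @return A [brain_mask()].
#' @export
auto_brain_mask <- function(bold, fraction = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  tm <- rowMeans(bold$data)
  g <- mean(tm)
  if (g == 0 && all(tm == 0)) stop("volume is identically zero; no mask")
  brain_mask(tm >= fraction * g, bold$grid)
}
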