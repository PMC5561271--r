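#' Bilateral seed specification
#'
#' Defaults to the bilateral amygdala seed used throughout the package:
#' 5 mm radius spheres around stereotaxic (+-22, -6, -14).
#'
#' @param centers_mm 2 x 3 matrix of left/right sphere centres in mm.
#' @param radius_mm sphere radius in mm.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(centers_mm = rbind(c(-22, -6, -14), c(22, -6, -14)),
                      radius_mm = 5) {
  centers_mm <- as.matrix(centers_mm)
  stopifnot(identical(dim(centers_mm), c(2L, 3L)), radius_mm > 0)
  structure(list(centers_mm = centers_mm, radius_mm = radius_mm),
            class = "seed_spec")
}

#' Spherical region-of-interest mask
#'
#' Includes every voxel whose centre lies within `radius_mm` (Euclidean, mm)
#' of `center_mm`. On the study's 3 mm isotropic grid a 5 mm sphere centred
#' on a voxel centre covers 19 voxels (centre + 6 face + 12 edge neighbours).
#'
#' @param grid an [image_grid()].
#' @param center_mm sphere centre, mm.
#' @param radius_mm sphere radius, mm.
#' @return A [brain_mask()].
#' @export
build_sphere_mask <- function(grid, center_mm, radius_mm) {
  stopifnot(radius_mm > 0)
  mm_to_voxel(grid, center_mm)  # errors if the centre is off the grid
  d2 <- rowSums(sweep(all_voxel_mm(grid), 2, center_mm)^2)
  inc <- d2 <= radius_mm^2
  if (!any(inc))
    stop(sprintf(paste0("no voxel centre within %g mm of (%g, %g, %g); ",
                        "consider the nearest voxel instead"),
                 radius_mm, center_mm[1], center_mm[2], center_mm[3]))
  brain_mask(inc, grid)
}

#' Averaged bilateral seed time course
#'
#' The left and right sphere means are averaged with equal weight at every
#' timepoint (the two hemispheres' courses are treated as one seed because
#' of their high mutual correlation), i.e. `0.5 * (mean_left + mean_right)`.
#'
#' @param bold a [bold4d()].
#' @param left,right [brain_mask()]s of the two seed spheres, on `bold`'s
#'   grid.
#' @return Numeric vector of length `bold$n_timepoints`.
#' @export
extract_seed_course <- function(bold, left, right) {
  stop_if_grid_mismatch(bold$grid, left$grid)
  stop_if_grid_mismatch(bold$grid, right$grid)
  course <- 0.5 * (colMeans(bold$data[left$included, , drop = FALSE]) +
                   colMeans(bold$data[right$included, , drop = FALSE]))
  if (stats::sd(course) == 0)
    stop("seed time course is constant (zero variance)")
  course
}

#' Fisher z with correlation clipping
#'
#' `atanh(r)` after clipping `|r|` at `1 - 1e-7`, so self-correlated voxels
#' yield a large finite z rather than infinity.
#'
#' @param r correlations in `[-1, 1]`.
#' @return Fisher z values.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))

#' Seed-based Fisher-z connectivity map
#'
#' Correlates every brain-mask voxel's time course with the seed course
#' (Pearson), then applies the Fisher r-to-z transformation. Voxels with a
#' constant time course get z = 0 with a warning. If a confound matrix is
#' supplied, both seed and voxel courses are residualized on it (with
#' intercept) first.
#'
#' @param bold a [bold4d()].
#' @param seed_course numeric vector, length `bold$n_timepoints`, nonzero
#'   variance.
#' @param mask [brain_mask()] of voxels to map (seed voxels are included in
#'   the map if the mask includes them).
#' @param subject_id,session identifiers carried on the result.
#' @param confounds optional timepoints x q numeric matrix of nuisance
#'   regressors.
#' @return An object of class `fc_map`: fields `grid`, `mask`, `z` (full
#'   length vector, `NA` off-mask), `subject_id`, `session`, `n_timepoints`.
#' @export
fc_map <- function(bold, seed_course, mask, subject_id = NA, session = NA,
                   confounds = NULL) {
  stop_if_grid_mismatch(bold$grid, mask$grid)
  if (length(seed_course) != bold$n_timepoints)
    stop("seed course length does not match the number of timepoints")
  Y <- t(bold$data[mask$included, , drop = FALSE])   # time x voxels
  s <- as.numeric(seed_course)
  if (!is.null(confounds)) {
    X <- cbind(1, as.matrix(confounds))
    stopifnot(nrow(X) == length(s))
    q <- qr(X)
    s <- qr.resid(q, s)
    Y <- qr.resid(q, Y)
  }
  if (stats::sd(s) == 0) stop("seed course has zero variance")
  # vectorized Pearson r over all voxels at once
  sc <- s - mean(s)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_y <- colSums(Yc^2)
  flat <- ss_y == 0
  denom <- ss_y
  denom[flat] <- 1                        # dummy; r zeroed below
  r <- as.numeric(crossprod(Yc, sc)) / sqrt(denom * sum(sc^2))
  r[flat] <- 0
  if (any(flat))
    warning(sprintf("%d voxel(s) with zero variance set to z = 0", sum(flat)))
  z <- rep(NA_real_, n_voxels(bold$grid))
  z[mask$included] <- fisher_z(r)
  structure(list(grid = bold$grid, mask = mask$included, z = z,
                 subject_id = subject_id, session = session,
                 n_timepoints = bold$n_timepoints),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("fc_map: subject %s, session %s, %d mask voxels\n",
              x$subject_id, x$session, sum(x$mask)))
  invisible(x)
}
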