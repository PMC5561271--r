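cluster_table_skeleton <- function() {
  data.frame(label = integer(), sign = integer(), size_voxels = integer(),
             size_mm3 = numeric(), peak_value = numeric(),
             peak_x = numeric(), peak_y = numeric(), peak_z = numeric())
}

label_sign_set <- function(incl, dims, connectivity) {
  label_components_cpp(incl, as.integer(dims), as.integer(connectivity))
}

#' Label suprathreshold clusters of a statistic map
#'
#' Connected components of the suprathreshold voxel set under 6-, 18- or
#' 26-neighbourhood connectivity. With `two_tailed = TRUE`, positive
#' (`value >= threshold`) and negative (`value <= -threshold`) exceedances
#' are labelled separately and never merged. Clusters are ordered by
#' descending size, ties broken by peak value then lexicographic peak index.
#'
#' @param map a [stat_map()] (or fc map); `NA` voxels are background.
#' @param threshold positive cluster-forming threshold on the statistic
#'   scale (see [t_critical()] / [f_critical()]).
#' @param connectivity 6, 18 or 26 (default 26, also used by the null
#'   simulation).
#' @param two_tailed label both signs? Use `FALSE` for F maps.
#' @param voxel_p optional voxelwise p corresponding to `threshold`,
#'   recorded so [apply_extent()] can verify consistency with the null.
#' @return A `cluster_table` data.frame with columns label, sign,
#'   size_voxels, size_mm3, peak_value, peak_x/y/z (mm); the member voxel
#'   indices are carried in `attr(, "voxels")`.
#' @export
label_clusters <- function(map, threshold, connectivity = 26,
                           two_tailed = TRUE, voxel_p = NULL) {
  stopifnot(threshold > 0)
  grid <- map$grid
  v <- if (inherits(map, "fc_map")) map$z else map$values
  v[is.na(v)] <- 0
  vox_vol <- prod(grid$voxel_size)
  signs <- if (two_tailed) c(1, -1) else 1
  rows <- list(); members <- list()
  for (sg in signs) {
    incl <- if (sg > 0) v >= threshold else v <= -threshold
    if (!any(incl)) next
    lab <- label_sign_set(incl, grid$dims, connectivity)
    for (id in seq_len(max(lab))) {
      mem <- which(lab == id)
      vals <- v[mem]
      peak_i <- mem[if (sg > 0) which.max(vals) else which.min(vals)]
      peak_mm <- voxel_to_mm(grid, arrayInd(peak_i, grid$dims)[1, ])
      rows[[length(rows) + 1L]] <- data.frame(
        label = NA_integer_, sign = sg, size_voxels = length(mem),
        size_mm3 = length(mem) * vox_vol,
        peak_value = v[peak_i],
        peak_x = peak_mm[1], peak_y = peak_mm[2], peak_z = peak_mm[3])
      members[[length(members) + 1L]] <- mem
    }
  }
  if (!length(rows)) {
    tab <- cluster_table_skeleton()
    attr(tab, "voxels") <- list()
  } else {
    tab <- do.call(rbind, rows)
    peak_idx <- vapply(seq_along(members), function(i)
      members[[i]][which.max(abs(v[members[[i]]]))], numeric(1))
    ord <- order(-tab$size_voxels, -abs(tab$peak_value), peak_idx)
    tab <- tab[ord, , drop = FALSE]
    tab$label <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    attr(tab, "voxels") <- members[ord]
  }
  attr(tab, "threshold") <- threshold
  attr(tab, "connectivity") <- connectivity
  attr(tab, "voxel_p") <- voxel_p
  attr(tab, "tail") <- if (two_tailed) "two" else "upper"
  attr(tab, "grid") <- grid
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

#' Map smoothness from residual maps (gradient-variance estimator)
#'
#' Per axis `a`, `FWHM_a = delta_a * sqrt(-2*log(2) / log(1 - v_a/(2*v)))`
#' where `v_a` is the variance of neighbouring-voxel differences along the
#' axis (both voxels inside the mask) and `v` the map variance in the mask;
#' estimates are averaged over maps and floored at the voxel size (with a
#' warning when the log is undefined, as for spatially uncorrelated maps).
#'
#' @param maps a list of [stat_map()]s (typically second-level residual
#'   maps; see [change_residual_maps()]), or a single map.
#' @param mask a [brain_mask()] spanning at least 2 voxels per axis.
#' @return An object of class `smoothness_estimate`: `fwhm_mm` (per-axis
#'   triple), `method`.
#' @export
estimate_smoothness <- function(maps, mask) {
  if (inherits(maps, "stat_map") || inherits(maps, "fc_map"))
    maps <- list(maps)
  stopifnot(length(maps) >= 1)
  grid <- mask$grid
  dims <- grid$dims
  inc <- array(mask$included, dims)
  per_map <- matrix(NA_real_, length(maps), 3)
  floored <- FALSE
  for (m in seq_along(maps)) {
    mp <- maps[[m]]
    stop_if_grid_mismatch(mp$grid, grid)
    x <- if (inherits(mp, "fc_map")) mp$z else mp$values
    arr <- array(x, dims)
    vals <- arr[inc]
    v <- stats::var(vals)
    if (!is.finite(v) || v == 0) stop("constant map; smoothness undefined")
    for (axis in 1:3) {
      if (dims[axis] < 2) { per_map[m, axis] <- NA_real_; next }
      idx_lo <- slice_indices(dims, axis, 1L, dims[axis] - 1L)
      idx_hi <- slice_indices(dims, axis, 2L, dims[axis])
      ok <- inc[idx_lo] & inc[idx_hi]
      d <- arr[idx_hi][ok] - arr[idx_lo][ok]
      if (length(d) < 2) { per_map[m, axis] <- NA_real_; next }
      ratio <- stats::var(d) / (2 * v)
      delta <- grid$voxel_size[axis]
      if (ratio <= 0 || ratio >= 1) {
        per_map[m, axis] <- delta
        floored <- TRUE
      } else {
        est <- delta * sqrt(-2 * log(2) / log(1 - ratio))
        per_map[m, axis] <- max(delta, est)
      }
    }
  }
  if (floored)
    warning("smoothness at or below voxel size; floored at the voxel size")
  structure(list(fwhm_mm = colMeans(per_map), method = "gradient_variance",
                 n_maps = length(maps)),
            class = "smoothness_estimate")
}

# Linear indices of the sub-array dims with axis restricted to [from, to].
slice_indices <- function(dims, axis, from, to) {
  ranges <- lapply(seq_along(dims), function(a)
    if (a == axis) from:to else seq_len(dims[a]))
  grid_idx <- as.matrix(expand.grid(ranges))
  grid_idx[, 1] + dims[1] * (grid_idx[, 2] - 1) +
    dims[1] * dims[2] * (grid_idx[, 3] - 1)
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness (gradient-variance): FWHM = %.2f x %.2f x %.2f mm (%d map(s))\n",
              x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3], x$n_maps))
  invisible(x)
}

#' Per-subject change-score residual maps
#'
#' Change scores minus their group mean, per voxel — the second-level
#' residuals of the interaction model, used to estimate map smoothness.
#'
#' @param zset a [subject_zset()].
#' @param groups groups to include (default all).
#' @return A list of [stat_map()]s, one per subject.
#' @export
change_residual_maps <- function(zset, groups = NULL) {
  if (is.null(groups)) groups <- unique(zset$subjects$group)
  rows <- which(zset$subjects$group %in% groups)
  D <- session_scores(zset, rows, "change")
  g <- factor(zset$subjects$group[rows], levels = groups)
  gm <- rowsum(D, g) / as.vector(table(g))
  R <- D - gm[as.integer(g), , drop = FALSE]
  lapply(seq_len(nrow(R)), function(i)
    stat_map(embed_values(R[i, ], zset), zset$grid, "z",
             mask = zset$mask))
}

#' Monte-Carlo null distribution of the maximum cluster extent
#'
#' Each iteration draws an independent standard-normal field on the mask's
#' bounding box (padded by twice the FWHM so smoothing has no edge deficit),
#' smooths it with the given Gaussian FWHM, restandardizes within the mask
#' (only when smoothing was applied; an unsmoothed draw is already standard
#' normal), thresholds two-tailed at `voxel_p`, labels positive and negative
#' exceedances separately, and records the maximum cluster size. The
#' critical extent is the smallest `k` whose exceedance probability
#' `P(max >= k)` is at most `alpha`.
#'
#' @param mask a [brain_mask()] (the analysis domain).
#' @param smoothness a `smoothness_estimate`, or an FWHM triple/scalar (mm).
#' @param voxel_p voxelwise threshold (study value 0.01); the total
#'   suprathreshold probability per voxel, however it is split across tails.
#' @param alpha cluster-level family-wise error rate (study value 0.05).
#' @param iterations Monte-Carlo iterations (study value 1000; >= 100).
#' @param connectivity neighbourhood used for clusters (default 26; must
#'   match [label_clusters()]).
#' @param tail `"two"` (default) splits `voxel_p` across both signs and
#'   labels them separately — the null matching a two-tailed t map.
#'   `"upper"` puts the whole `voxel_p` in one sign set — the null matching
#'   a one-tailed F map, whose suprathreshold set is a single set of
#'   density `voxel_p` (calibration requires the null to be thresholded the
#'   same way as the map it corrects).
#' @param rng_seed integer seed; same seed, same distribution.
#' @return An object of class `extent_null`: `critical_extent_k`,
#'   `max_sizes` (per iteration), `dist` (counts per size), plus the
#'   parameters.
#' @export
extent_threshold <- function(mask, smoothness, voxel_p = 0.01, alpha = 0.05,
                             iterations = 1000, connectivity = 26,
                             tail = c("two", "upper"), rng_seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(iterations >= 100, voxel_p > 0, voxel_p < 1,
            alpha > 0, alpha <= 1)
  if (alpha < 1 / iterations)
    stop("alpha below 1/iterations; increase the iteration count")
  fwhm <- if (inherits(smoothness, "smoothness_estimate"))
    smoothness$fwhm_mm else rep_len(smoothness, 3L)
  fwhm[!is.finite(fwhm)] <- 0
  grid <- mask$grid
  inc_arr <- array(mask$included, grid$dims)
  box <- apply(which(inc_arr, arr.ind = TRUE), 2, range)
  box_dims <- as.integer(box[2, ] - box[1, ] + 1)
  # simulate on the bounding box padded by 2 x FWHM so smoothing suffers no
  # edge deficit inside the mask
  pad <- as.integer(ceiling(2 * fwhm / grid$voxel_size))
  sim_dims <- box_dims + 2L * pad
  off <- pad
  sub_mask <- inc_arr[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2],
                      box[1, 3]:box[2, 3], drop = FALSE]
  sub_mask <- array(sub_mask, box_dims)
  mask_lin <- which(as.vector(sub_mask))
  zc <- if (tail == "two") stats::qnorm(1 - voxel_p / 2)
  else stats::qnorm(1 - voxel_p)
  signs <- if (tail == "two") c(1, -1) else 1
  do_smooth <- any(fwhm > 0)
  max_sizes <- with_rng_seed(rng_seed, {
    vapply(seq_len(iterations), function(it) {
      f <- array(stats::rnorm(prod(sim_dims)), sim_dims)
      if (do_smooth) f <- gaussian_smooth_3d(f, fwhm, grid$voxel_size)
      f <- f[off[1] + seq_len(box_dims[1]),
             off[2] + seq_len(box_dims[2]),
             off[3] + seq_len(box_dims[3]), drop = FALSE]
      vals <- f[mask_lin]
      # restandardize only to undo the variance shrinkage of smoothing; an
      # unsmoothed draw is already exactly standard normal
      if (do_smooth) vals <- (vals - mean(vals)) / stats::sd(vals)
      m <- 0L
      for (sg in signs) {
        incl <- logical(prod(box_dims))
        incl[mask_lin[if (sg > 0) vals >= zc else vals <= -zc]] <- TRUE
        if (!any(incl)) next
        lab <- label_sign_set(incl, box_dims, connectivity)
        m <- max(m, max(tabulate(lab)))
      }
      m
    }, integer(1))
  })
  exceed <- function(k) mean(max_sizes >= k)
  k <- 1L
  while (exceed(k) > alpha) k <- k + 1L
  structure(list(critical_extent_k = k,
                 max_sizes = max_sizes,
                 dist = table(max_sizes),
                 iterations = iterations, voxel_p = voxel_p, alpha = alpha,
                 connectivity = connectivity, tail = tail, fwhm_mm = fwhm,
                 rng_seed = rng_seed),
            class = "extent_null")
}

#' @export
print.extent_null <- function(x, ...) {
  cat(sprintf(paste0("extent_null: k = %d voxels (voxel p = %g, alpha = %g,",
                     " %d iterations, FWHM %.1f/%.1f/%.1f mm)\n"),
              x$critical_extent_k, x$voxel_p, x$alpha, x$iterations,
              x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3]))
  invisible(x)
}

#' Apply the cluster-extent criterion to a cluster table
#'
#' Retains clusters with `size_voxels >= critical_extent_k` and annotates
#' every retained cluster with its empirical cluster-level p-value
#' `P(max null extent >= size)`.
#'
#' @param table a `cluster_table` from [label_clusters()].
#' @param null an `extent_null` from [extent_threshold()] built with the
#'   same voxelwise p and connectivity (mismatches raise an error).
#' @return The corrected cluster table with a `cluster_p` column.
#' @export
apply_extent <- function(table, null) {
  tab_p <- attr(table, "voxel_p")
  if (!is.null(tab_p) && !isTRUE(all.equal(tab_p, null$voxel_p)))
    stop("cluster table and null use different voxelwise thresholds")
  if (!is.null(attr(table, "connectivity")) &&
      attr(table, "connectivity") != null$connectivity)
    stop("cluster table and null use different connectivities")
  if (!is.null(attr(table, "tail")) && !is.null(null$tail) &&
      attr(table, "tail") != null$tail)
    stop("cluster table and null use different tails")
  keep <- table$size_voxels >= null$critical_extent_k
  out <- table[keep, , drop = FALSE]
  out$cluster_p <- vapply(out$size_voxels,
                          function(s) mean(null$max_sizes >= s), numeric(1))
  attr(out, "voxels") <- attr(table, "voxels")[keep]
  for (a in c("voxel_p", "connectivity", "threshold", "tail", "grid"))
    attr(out, a) <- attr(table, a)
  class(out) <- class(table)
  out
}
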