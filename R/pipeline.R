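#' Full corrected group-by-time interaction analysis
#'
#' Runs the complete second-level pipeline on a z-map set: site
#' residualization, interaction F map on change scores, smoothness
#' estimation from the change-score residual maps, Monte-Carlo cluster
#' extent null, cluster labeling and extent correction, per-group paired t
#' maps, and the restriction of interaction clusters to those supported by
#' a task effect in at least one group.
#'
#' @param zset a [subject_zset()].
#' @param groups the two (or more) group labels entering the ANOVA.
#' @param voxel_p voxelwise threshold (study value 0.01; F map upper-tailed,
#'   t maps two-tailed).
#' @param alpha cluster-level FWE rate (study value 0.05).
#' @param iterations Monte-Carlo iterations (study value 1000).
#' @param connectivity cluster connectivity (default 26).
#' @param rng_seed seed for the Monte-Carlo null.
#' @param residualize run [residualize_site()] first? (default TRUE).
#' @return A list with `F_map`, `t_maps` (per group), `smoothness`, `null`,
#'   `clusters_all` (thresholded, uncorrected), `clusters_corrected`
#'   (extent-corrected) and `clusters` (corrected + restricted).
#' @export
interaction_analysis <- function(zset, groups = NULL, voxel_p = 0.01,
                                 alpha = 0.05, iterations = 1000,
                                 connectivity = 26, rng_seed = 1L,
                                 residualize = TRUE) {
  if (is.null(groups)) groups <- unique(zset$subjects$group)
  if (residualize) zset <- residualize_site(zset)
  Fmap <- interaction_F_map(zset, groups)
  resid <- change_residual_maps(zset, groups)
  smooth <- estimate_smoothness(resid, zset_mask(zset))
  # the F map is thresholded one-tailed, so its null must put the whole
  # voxel_p in one sign set; a split null would under-estimate the extent
  null <- extent_threshold(zset_mask(zset), smooth, voxel_p = voxel_p,
                           alpha = alpha, iterations = iterations,
                           connectivity = connectivity, tail = "upper",
                           rng_seed = rng_seed)
  fthr <- f_critical(voxel_p, Fmap$df[1], Fmap$df[2])
  clusters_all <- label_clusters(Fmap, fthr, connectivity = connectivity,
                                 two_tailed = FALSE, voxel_p = voxel_p)
  clusters_corrected <- apply_extent(clusters_all, null)
  t_maps <- lapply(groups, function(g) paired_t_map(zset, g))
  names(t_maps) <- groups
  tthr <- t_critical(voxel_p, t_maps[[1]]$df)
  clusters <- restrict_interaction(clusters_corrected, t_maps, tthr)
  list(F_map = Fmap, t_maps = t_maps, smoothness = smooth, null = null,
       clusters_all = clusters_all, clusters_corrected = clusters_corrected,
       clusters = clusters, zset = zset)
}
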