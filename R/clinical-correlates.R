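#' Post-minus-pre connectivity change map
#'
#' `dz = z_post - z_pre` voxelwise: positive values mean stronger seed
#' connectivity after the task.
#'
#' @param pre,post [fc_map()]s of one subject on a common grid.
#' @return An `fc_map` of change scores.
#' @export
change_map <- function(pre, post) {
  stop_if_grid_mismatch(pre$grid, post$grid)
  if (!identical(pre$mask, post$mask)) stop("pre/post masks differ")
  out <- post
  out$z <- post$z - pre$z
  out$session <- "change"
  out
}

#' Change scores of a z-map set as a subjects x voxels matrix
#'
#' @param zset a [subject_zset()].
#' @param group optional group label to restrict to.
#' @return Matrix of `z_post - z_pre`, one row per subject, columns on the
#'   mask.
#' @export
change_scores <- function(zset, group = NULL) {
  rows <- if (is.null(group)) rep(TRUE, nrow(zset$subjects))
  else zset$subjects$group == group
  zset$z_post[rows, , drop = FALSE] - zset$z_pre[rows, , drop = FALSE]
}

#' Masked voxelwise correlation of connectivity change with a score
#'
#' Pearson correlation between each masked voxel's change score and a
#' clinical score across subjects, with pairwise deletion of missing scores
#' (the effective n is recorded in the map's df = n - 2 and reported via a
#' message when subjects are dropped). Downstream thresholding can convert
#' r to t via [r_to_t()].
#'
#' @param dz subjects x voxels matrix of change scores on the zset mask
#'   (see [change_scores()]).
#' @param scores numeric vector of clinical scores, one per subject (`NA`
#'   allowed).
#' @param mask a [brain_mask()] restricting the analysis (e.g. the network
#'   showing a post-task response); must lie inside the zset mask.
#' @param zset the [subject_zset()] the rows of `dz` came from (supplies
#'   grid and column indexing).
#' @return A [stat_map()] of type `"r"` with `df = n - 2`.
#' @export
masked_correlation_map <- function(dz, scores, mask, zset) {
  stopifnot(nrow(dz) == length(scores))
  ok <- !is.na(scores)
  if (sum(ok) < 4) stop("need at least 4 subjects with scores")
  if (sum(ok) < length(scores))
    message(sprintf("dropping %d subject(s) with missing scores (n = %d)",
                    sum(!ok), sum(ok)))
  s <- scores[ok]
  if (stats::sd(s) == 0) stop("score is constant")
  cols <- match(which(mask$included), which(zset$mask))
  if (anyNA(cols)) stop("correlation mask extends outside the analysis mask")
  r <- as.numeric(stats::cor(dz[ok, cols, drop = FALSE], s))
  r[is.na(r)] <- 0     # zero-variance voxels
  full <- rep(NA_real_, n_voxels(zset$grid))
  full[mask$included] <- r
  stat_map(full, zset$grid, "r", df = sum(ok) - 2, mask = mask$included)
}

#' Convert a correlation map to the t scale
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, so r maps can be thresholded and
#' cluster-corrected exactly like t maps.
#'
#' @param rmap a [stat_map()] of type `"r"` with `df = n - 2`, or a numeric
#'   vector of correlations (then give `n`).
#' @param n sample size (ignored for a map, which carries it in df).
#' @return A t-type [stat_map()] or numeric vector.
#' @export
r_to_t <- function(rmap, n = NULL) {
  if (inherits(rmap, "stat_map")) {
    df <- rmap$df
    r <- rmap$values
    t <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-12))
    stat_map(t, rmap$grid, "t", df = df, mask = rmap$mask)
  } else {
    stopifnot(!is.null(n))
    rmap * sqrt(n - 2) / sqrt(pmax(1 - rmap^2, 1e-12))
  }
}

#' Bonferroni family-wise error gate
#'
#' Rejects `p <= alpha / m`; the family size defaults to the number of
#' p-values supplied (for cluster-by-scale correlate families,
#' m = clusters x scales).
#'
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @param m family size (default `length(p_values)`).
#' @return A list with `reject` (logical), `threshold` (`alpha/m`), `m`.
#' @export
bonferroni_gate <- function(p_values, alpha = 0.05, m = length(p_values)) {
  stopifnot(m >= 1, alpha > 0)
  thr <- alpha / m
  list(reject = p_values <= thr, threshold = thr, m = m)
}
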