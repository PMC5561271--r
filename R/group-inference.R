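#' Per-subject pre/post Fisher-z map collection
#'
#' The second-level data structure: every subject contributes one pre-task
#' and one post-task Fisher-z connectivity map on a common grid and mask.
#'
#' @param z_pre,z_post numeric matrices, subjects x mask-voxels, of Fisher-z
#'   values (columns follow the mask's included voxels in linear order).
#' @param subjects data.frame with columns `subject_id`, `group`, `site`,
#'   `medicated` (one row per subject).
#' @param grid the common [image_grid()].
#' @param mask the common [brain_mask()].
#' @return An object of class `subject_zset`.
#' @export
subject_zset <- function(z_pre, z_post, subjects, grid, mask) {
  stopifnot(is.matrix(z_pre), is.matrix(z_post),
            identical(dim(z_pre), dim(z_post)),
            nrow(z_pre) == nrow(subjects),
            ncol(z_pre) == sum(mask$included),
            all(c("subject_id", "group", "site") %in% names(subjects)))
  if (!"medicated" %in% names(subjects)) subjects$medicated <- FALSE
  if (any(table(subjects$group) < 2))
    stop("every group needs at least 2 subjects")
  structure(list(grid = grid, mask = mask$included,
                 z_pre = z_pre, z_post = z_post,
                 subjects = as.data.frame(subjects)),
            class = "subject_zset")
}

#' @export
print.subject_zset <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("subject_zset: %d subjects (%s), %d mask voxels\n",
              nrow(x$subjects),
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
              ncol(x$z_pre)))
  invisible(x)
}

#' Compute the full pre/post z-map set for a synthetic cohort
#'
#' Convenience pipeline step: builds the bilateral seed on the cohort's grid,
#' extracts each subject-session's seed course, computes its Fisher-z map,
#' and assembles the [subject_zset()].
#'
#' @param cohort an [simulate_cohort()] result (volumes in memory or on
#'   disk).
#' @param mask optional [brain_mask()]; default is the generator's brain box.
#' @param seed optional [seed_spec()]; default uses the cohort's configured
#'   seed centres and radius.
#' @return A [subject_zset()].
#' @export
zset_from_cohort <- function(cohort, mask = NULL, seed = NULL) {
  config <- cohort$config
  grid <- config_grid(config)
  if (is.null(seed))
    seed <- seed_spec(config$seed_centers_mm, config$seed_radius_mm)
  if (is.null(mask)) {
    inc <- logical(n_voxels(grid))
    inc[cohort$truth$brain_voxels] <- TRUE
    mask <- brain_mask(inc, grid)
  }
  left <- build_sphere_mask(grid, seed$centers_mm[1, ], seed$radius_mm)
  right <- build_sphere_mask(grid, seed$centers_mm[2, ], seed$radius_mm)
  m <- cohort$manifest
  subjects <- unique(m[, c("subject_id", "group", "site", "medicated")])
  n <- nrow(subjects)
  V <- sum(mask$included)
  z_pre <- matrix(NA_real_, n, V)
  z_post <- matrix(NA_real_, n, V)
  get_bold <- function(row) {
    if (!is.null(cohort$bolds))
      cohort$bolds[[sprintf("%s_%s", m$subject_id[row], m$session[row])]]
    else read_volume(m$path[row])
  }
  for (row in seq_len(nrow(m))) {
    bold <- get_bold(row)
    course <- extract_seed_course(bold, left, right)
    fmap <- fc_map(bold, course, mask, subject_id = m$subject_id[row],
                   session = m$session[row])
    i <- match(m$subject_id[row], subjects$subject_id)
    if (m$session[row] == "pre") z_pre[i, ] <- fmap$z[mask$included]
    else z_post[i, ] <- fmap$z[mask$included]
  }
  subject_zset(z_pre, z_post, subjects, grid, mask)
}

zset_mask <- function(zset) brain_mask(zset$mask, zset$grid)

embed_values <- function(values_on_mask, zset) {
  full <- rep(NA_real_, n_voxels(zset$grid))
  full[zset$mask] <- values_on_mask
  full
}

#' Remove the acquisition-site effect from the z maps
#'
#' Per voxel, ordinary least squares of z on site indicator dummies (with
#' intercept), fitted jointly across all subject-sessions; the residuals are
#' returned with the grand mean re-added so maps keep their interpretable
#' scale. After residualization, the per-site mean equals the grand mean at
#' every voxel.
#'
#' @param zset a [subject_zset()].
#' @return A [subject_zset()] of residualized maps.
#' @export
residualize_site <- function(zset) {
  site <- as.character(zset$subjects$site)
  counts <- table(site)
  if (any(counts * 2 == 1)) {} # sessions double every site count
  if (any(counts == 0)) stop("empty site level")
  Z <- rbind(zset$z_pre, zset$z_post)          # 2n x V, site repeats twice
  s2 <- factor(c(site, site))
  if (min(table(s2)) == 1L)
    warning("a site has a single subject-session; its residuals are 0 there")
  means <- rowsum(Z, s2) / as.vector(table(s2))
  grand <- colMeans(Z)
  R <- Z - means[as.integer(s2), , drop = FALSE] +
    rep(1, nrow(Z)) %o% grand
  dimnames(R) <- NULL
  n <- nrow(zset$z_pre)
  out <- zset
  out$z_pre <- R[seq_len(n), , drop = FALSE]
  out$z_post <- R[n + seq_len(n), , drop = FALSE]
  out
}

#' Within-group paired t map (post versus pre)
#'
#' Per voxel, `t = mean(d) / (sd(d)/sqrt(n))` with `d = z_post - z_pre`,
#' df = n - 1. Voxels with zero change variance get t = 0 with a warning.
#'
#' @param zset a [subject_zset()].
#' @param group group label to test.
#' @return A [stat_map()] of type `"t"`.
#' @export
paired_t_map <- function(zset, group) {
  rows <- zset$subjects$group == group
  n <- sum(rows)
  if (n < 2) stop("paired t needs at least 2 subjects")
  D <- zset$z_post[rows, , drop = FALSE] - zset$z_pre[rows, , drop = FALSE]
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  flat <- s == 0
  t <- numeric(length(m))
  t[!flat] <- m[!flat] / (s[!flat] / sqrt(n))
  if (any(flat & m != 0))
    warning(sprintf("%d voxel(s) with zero change variance set to t = 0",
                    sum(flat & m != 0)))
  stat_map(embed_values(t, zset), zset$grid, "t", df = n - 1,
           mask = zset$mask)
}

session_scores <- function(zset, rows,
                           data = c("change", "pre", "post")) {
  data <- match.arg(data)
  switch(data,
         change = zset$z_post[rows, , drop = FALSE] -
           zset$z_pre[rows, , drop = FALSE],
         pre = zset$z_pre[rows, , drop = FALSE],
         post = zset$z_post[rows, , drop = FALSE])
}

#' Between-group pooled-variance t map
#'
#' Two-sample t with pooled variance (df = nA + nB - 2), computed on the
#' session selected by `data`: pre-task maps (baseline contrast), post-task
#' maps, or post-minus-pre change scores. Sign convention: group A minus
#' group B.
#'
#' @param zset a [subject_zset()].
#' @param groups two group labels `(A, B)`.
#' @param data `"pre"`, `"post"` or `"change"`.
#' @return A [stat_map()] of type `"t"`.
#' @export
independent_t_map <- function(zset, groups,
                              data = c("pre", "post", "change")) {
  data <- match.arg(data)
  A <- session_scores(zset, zset$subjects$group == groups[1], data)
  B <- session_scores(zset, zset$subjects$group == groups[2], data)
  na <- nrow(A); nb <- nrow(B)
  if (na < 2 || nb < 2) stop("both groups need at least 2 subjects")
  ma <- colMeans(A); mb <- colMeans(B)
  ssa <- colSums(sweep(A, 2, ma)^2)
  ssb <- colSums(sweep(B, 2, mb)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(se == 0, 0, (ma - mb) / se)
  stat_map(embed_values(t, zset), zset$grid, "t", df = na + nb - 2,
           mask = zset$mask)
}

#' Group-by-time interaction F map of the mixed ANOVA
#'
#' For a two-level within-subject factor (pre/post) the mixed-ANOVA
#' interaction is exactly the one-way between-group ANOVA on the change
#' scores `d_i = z_post - z_pre`, which is how the map is computed:
#' `F = (SSB/(k-1)) / (SSW/(N-k))` per voxel, df = (k - 1, N - k).
#'
#' @param zset a [subject_zset()].
#' @param groups group labels to include (default: all).
#' @return A [stat_map()] of type `"F"`.
#' @export
interaction_F_map <- function(zset, groups = NULL) {
  if (is.null(groups)) groups <- unique(zset$subjects$group)
  rows <- zset$subjects$group %in% groups
  g <- factor(zset$subjects$group[rows], levels = groups)
  if (any(table(g) < 2)) stop("every group needs at least 2 subjects")
  D <- session_scores(zset, rows, "change")
  N <- nrow(D); k <- nlevels(g)
  counts <- as.vector(table(g))
  gm <- rowsum(D, g) / counts                   # k x V group means
  grand <- colMeans(D)
  ssb <- colSums(counts * sweep(gm, 2, grand)^2)
  ssw <- colSums(sweep(D, 2, grand)^2) - ssb
  msw <- ssw / (N - k)
  F <- ifelse(msw == 0, 0, (ssb / (k - 1)) / msw)
  stat_map(embed_values(F, zset), zset$grid, "F", df = c(k - 1, N - k),
           mask = zset$mask)
}

#' Two-tailed voxel-threshold helpers
#'
#' `t_critical` gives `|t|` such that a two-tailed test at `voxel_p` rejects;
#' `f_critical` the upper-tail F threshold.
#'
#' @param voxel_p voxelwise p threshold (study value 0.01).
#' @param df,df1,df2 degrees of freedom.
#' @return The critical statistic value.
#' @export
t_critical <- function(voxel_p, df) stats::qt(1 - voxel_p / 2, df)

#' @rdname t_critical
#' @export
f_critical <- function(voxel_p, df1, df2) stats::qf(1 - voxel_p, df1, df2)

#' Minimum-statistic conjunction of two t maps
#'
#' A voxel enters the conjunction iff both maps exceed the threshold in the
#' same direction (conjunction-null logic): `tA >= thr & tB >= thr`, or
#' `tA <= -thr & tB <= -thr`.
#'
#' @param tA,tB [stat_map()]s on a common grid/mask.
#' @param threshold positive per-map voxel threshold on the t scale.
#' @return A [brain_mask()] of conjointly suprathreshold voxels (may be
#'   empty; then an error is raised by the mask constructor only if you
#'   request it — an all-`FALSE` logical is returned as attribute-free
#'   logical via `conjunction_voxels`).
#' @export
conjunction_mask <- function(tA, tB, threshold) {
  stop_if_grid_mismatch(tA$grid, tB$grid)
  stopifnot(threshold > 0)
  a <- tA$values; b <- tB$values
  inc <- (!is.na(a) & !is.na(b)) &
    ((a >= threshold & b >= threshold) | (a <= -threshold & b <= -threshold))
  inc[is.na(inc)] <- FALSE
  structure(list(grid = tA$grid, included = inc), class = "brain_mask")
}

#' Restrict interaction clusters to task-effect support
#'
#' Keeps only interaction clusters that overlap (by at least one voxel) the
#' suprathreshold set of at least one group's paired t map — i.e. only
#' interaction effects grounded in a task effect in at least one group.
#' Dropped clusters are reported in the `kept` column and a message.
#'
#' @param clusters a cluster table from [label_clusters()] /
#'   [apply_extent()] on the interaction F map.
#' @param t_maps list of per-group paired-t [stat_map()]s.
#' @param threshold positive two-tailed t threshold applied to each t map
#'   (same voxel p as the F map).
#' @return The cluster table restricted to supported clusters, with an
#'   `overlap_groups` column naming the supporting group maps.
#' @export
restrict_interaction <- function(clusters, t_maps, threshold) {
  supra <- lapply(t_maps, function(tm) {
    v <- tm$values
    which(!is.na(v) & abs(v) >= threshold)
  })
  vox <- attr(clusters, "voxels")
  keep <- logical(nrow(clusters))
  overlap <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    hits <- vapply(supra, function(sv) any(vox[[i]] %in% sv), logical(1))
    keep[i] <- any(hits)
    overlap[i] <- paste(names(t_maps)[hits], collapse = "+")
  }
  if (any(!keep))
    message(sprintf(
      "dropping %d cluster(s) without a task effect in any group: %s",
      sum(!keep), paste(clusters$label[!keep], collapse = ", ")))
  out <- clusters[keep, , drop = FALSE]
  out$overlap_groups <- overlap[keep]
  attr(out, "voxels") <- vox[keep]
  for (a in c("voxel_p", "connectivity", "threshold", "tail", "grid"))
    attr(out, a) <- attr(clusters, a)
  class(out) <- class(clusters)
  out
}

#' Cluster-mean z extraction and simple effects
#'
#' Averages each subject-session's z over the cluster voxels and reports the
#' simple effects: per-group paired t (post vs pre) and between-group
#' pooled t at each session.
#'
#' @param cluster a [brain_mask()], or an integer vector of linear voxel
#'   indices.
#' @param zset a [subject_zset()].
#' @return A list with `scalars` (subject_id, group, session, mean_z) and
#'   `simple_effects` (effect, group, t, df, p).
#' @export
cluster_mean_z <- function(cluster, zset) {
  vox <- if (inherits(cluster, "brain_mask")) which(cluster$included)
  else as.integer(cluster)
  if (!length(vox)) stop("empty cluster")
  cols <- match(vox, which(zset$mask))
  if (anyNA(cols)) stop("cluster extends outside the analysis mask")
  pre <- rowMeans(zset$z_pre[, cols, drop = FALSE])
  post <- rowMeans(zset$z_post[, cols, drop = FALSE])
  subj <- zset$subjects
  scalars <- data.frame(
    subject_id = rep(subj$subject_id, 2),
    group = rep(subj$group, 2),
    session = rep(c("pre", "post"), each = nrow(subj)),
    mean_z = c(pre, post), stringsAsFactors = FALSE)
  groups <- unique(subj$group)
  eff <- list()
  for (g in groups) {
    r <- subj$group == g
    tt <- stats::t.test(post[r], pre[r], paired = TRUE)
    eff[[length(eff) + 1L]] <- data.frame(
      effect = "post_vs_pre", group = g,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  }
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) for (sess in c("pre", "post")) {
      x <- if (sess == "pre") pre else post
      tt <- stats::t.test(x[subj$group == pr[1]], x[subj$group == pr[2]],
                          var.equal = TRUE)
      eff[[length(eff) + 1L]] <- data.frame(
        effect = sprintf("%s_between", sess),
        group = paste(pr, collapse = "_vs_"),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  }
  list(scalars = scalars, simple_effects = do.call(rbind, eff))
}

#' Medication post-hoc mixed ANOVA within one group
#'
#' Tests the time-by-medication interaction on cluster-mean z within a
#' single group (default: the first), using the same change-score identity
#' as [interaction_F_map()]: a one-way ANOVA on post-minus-pre cluster means
#' between medicated and non-medicated subjects.
#'
#' @param zset a [subject_zset()].
#' @param cluster cluster voxels ([brain_mask()] or indices).
#' @param group group label to test within.
#' @return A list with `F`, `df`, `p`, and the per-level change means.
#' @export
medication_posthoc <- function(zset, cluster, group = NULL) {
  if (is.null(group)) group <- zset$subjects$group[1]
  rows <- zset$subjects$group == group
  med <- factor(zset$subjects$medicated[rows], levels = c(FALSE, TRUE))
  if (any(table(med) < 2))
    stop("both medication levels need at least 2 subjects")
  vox <- if (inherits(cluster, "brain_mask")) which(cluster$included)
  else as.integer(cluster)
  cols <- match(vox, which(zset$mask))
  if (anyNA(cols)) stop("cluster extends outside the analysis mask")
  d <- rowMeans(zset$z_post[rows, cols, drop = FALSE]) -
    rowMeans(zset$z_pre[rows, cols, drop = FALSE])
  fit <- stats::aov(d ~ med)
  an <- summary(fit)[[1]]
  list(F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
       p = an[1, "Pr(>F)"],
       change_means = tapply(d, med, mean))
}
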