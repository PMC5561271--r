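test_that("site residualization annihilates site means and keeps scale", {
  # exact two-site fixture: values {1,1} at site 1, {3,3} at site 2
  z <- matrix(c(1, 1, 3, 3), 4, 2)
  zs <- make_zset(z, z, group = c("A", "A", "B", "B"),
                  site = c(1, 1, 2, 2), dims = c(2, 1, 1))
  out <- residualize_site(zs)
  expect_equal(unname(out$z_pre), matrix(2, 4, 2))  # residual 0 + intercept 2
  expect_equal(out$z_pre, out$z_post)
  # a single site leaves the data unchanged
  zs1 <- make_zset(z, z + 1, group = c("A", "A", "B", "B"),
                   site = rep(1, 4), dims = c(2, 1, 1))
  out1 <- residualize_site(zs1)
  expect_equal(out1$z_pre, zs1$z_pre)
  expect_equal(out1$z_post, zs1$z_post)
})

test_that("residualization leaves per-site means exactly equal", {
  set.seed(31)
  n <- 12; V <- 40
  site <- rep(1:3, each = 4)
  offs <- c(-0.3, 0.1, 0.4)
  z_pre <- matrix(rnorm(n * V), n, V) + offs[site]
  z_post <- matrix(rnorm(n * V), n, V) + offs[site]
  zs <- make_zset(z_pre, z_post, group = rep(c("A", "B"), 6), site = site,
                  dims = c(10, 4, 1))
  out <- residualize_site(zs)
  stacked <- rbind(out$z_pre, out$z_post)
  site2 <- c(site, site)
  means <- rowsum(stacked, site2) / as.vector(table(site2))
  expect_lt(max(abs(sweep(means, 2, colMeans(means)))), 1e-10)
  # invariance: adding a per-site constant to the inputs changes nothing
  z_pre2 <- z_pre + 5 * site
  z_post2 <- z_post + 5 * site
  zs2 <- make_zset(z_pre2, z_post2, group = rep(c("A", "B"), 6), site = site,
                   dims = c(10, 4, 1))
  out2 <- residualize_site(zs2)
  f1 <- interaction_F_map(out)
  f2 <- interaction_F_map(out2)
  expect_equal(f1$values, f2$values, tolerance = 1e-8)
})

test_that("paired t map matches hand arithmetic and summary equivalence", {
  # d = {1, 2, 3}: mean 2, sd 1 -> t = 2*sqrt(3), df = 2
  z_pre <- matrix(0, 3, 2)
  z_post <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2)
  zs <- make_zset(z_pre, z_post, group = rep("A", 3), dims = c(2, 1, 1))
  tm <- paired_t_map(zs, "A")
  expect_equal(tm$values, rep(2 * sqrt(3), 2))
  expect_identical(tm$df, 2)
  # agreement with the closed-form one-sample t on (mean(d), sd(d), n)
  expect_equal(tm$values[1], one_sample_t(2, 1, 3)$t)
  # identical pre/post -> t = 0 everywhere
  zs0 <- make_zset(z_post, z_post, group = rep("A", 3), dims = c(2, 1, 1))
  tm0 <- paired_t_map(zs0, "A")
  expect_equal(tm0$values, c(0, 0))
})

test_that("independent t map matches hand arithmetic", {
  # A = {0, 1}, B = {2, 3}: pooled var 0.5, se = 0.7071, t = -2.828, df = 2
  z <- matrix(c(0, 1, 2, 3), 4, 1)
  zs <- make_zset(matrix(0, 4, 1), z, group = c("A", "A", "B", "B"),
                  dims = c(1, 1, 1))
  tm <- independent_t_map(zs, c("A", "B"), data = "post")
  # pooled var 0.5, se = sqrt(0.5 * (1/2 + 1/2)) = 0.7071 -> t = -2/0.7071
  expect_equal(tm$values[1], -2 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(tm$values[1], -2.828427, tolerance = 1e-6)
  expect_identical(tm$df, 2)
  # identical distributions -> t = 0
  zsame <- make_zset(matrix(0, 4, 1), matrix(c(1, 2, 1, 2), 4, 1),
                     group = c("A", "A", "B", "B"), dims = c(1, 1, 1))
  expect_equal(independent_t_map(zsame, c("A", "B"), "post")$values[1], 0)
  # df bookkeeping at the study's group sizes: 48 + 39 - 2 = 85
  zbig <- make_zset(matrix(rnorm(87), 87, 1), matrix(rnorm(87), 87, 1),
                    group = rep(c("BPD", "NPC"), c(48, 39)),
                    dims = c(1, 1, 1))
  expect_identical(independent_t_map(zbig, c("BPD", "NPC"), "pre")$df, 85)
})

test_that("interaction F equals t^2 on change scores and the full
           mixed-model oracle", {
  set.seed(32)
  n <- 6; V <- 20
  group <- rep(c("A", "B"), each = 3)
  z_pre <- matrix(rnorm(n * V), n, V)
  z_post <- matrix(rnorm(n * V), n, V)
  zs <- make_zset(z_pre, z_post, group = group, dims = c(5, 4, 1))
  Fm <- interaction_F_map(zs)
  tm <- independent_t_map(zs, c("A", "B"), data = "change")
  expect_lt(max(abs(Fm$values - tm$values^2) / pmax(Fm$values, 1e-12)),
            1e-10)
  expect_identical(Fm$df, c(1, 4))
  # brute-force two-way mixed ANOVA oracle, voxel by voxel
  for (v in seq_len(V)) {
    expect_equal(Fm$values[v],
                 mixed_anova_F_oracle(z_pre[, v], z_post[, v], group),
                 tolerance = 1e-10)
  }
  # identical change scores in both groups -> F = 0
  d <- matrix(c(1, 2, 3, 1, 2, 3), 6, 1)
  zs0 <- make_zset(matrix(0, 6, 1), d, group = group, dims = c(1, 1, 1))
  expect_equal(interaction_F_map(zs0)$values[1], 0)
  # df bookkeeping at study sizes: (1, 85)
  zbig <- make_zset(matrix(rnorm(87 * 2), 87, 2), matrix(rnorm(87 * 2), 87, 2),
                    group = rep(c("BPD", "NPC"), c(48, 39)), dims = c(2, 1, 1))
  expect_identical(interaction_F_map(zbig)$df, c(1, 85))
})

test_that("three-group interaction F also matches the mixed-model oracle", {
  set.seed(33)
  n <- 9; V <- 8
  group <- rep(c("A", "B", "C"), each = 3)
  z_pre <- matrix(rnorm(n * V), n, V)
  z_post <- matrix(rnorm(n * V), n, V)
  zs <- make_zset(z_pre, z_post, group = group, dims = c(4, 2, 1))
  Fm <- interaction_F_map(zs)
  expect_identical(Fm$df, c(2, 6))
  for (v in seq_len(V)) {
    expect_equal(Fm$values[v],
                 mixed_anova_F_oracle(z_pre[, v], z_post[, v], group),
                 tolerance = 1e-10)
  }
})

test_that("conjunction requires joint suprathreshold agreement in sign", {
  g <- image_grid(c(4, 1, 1))
  mk <- function(v) stat_map(v, g, "t", df = 10)
  tA <- mk(c(4, 4, -4, 1))
  tB <- mk(c(4, -4, -4, 4))
  conj <- conjunction_mask(tA, tB, 2.66)
  expect_identical(conj$included, c(TRUE, FALSE, TRUE, FALSE))
  # idempotence: conjunction of a map with itself is its own threshold mask
  conj_self <- conjunction_mask(tA, tA, 2.66)
  expect_identical(conj_self$included, abs(tA$values) >= 2.66)
  g2 <- image_grid(c(5, 1, 1))
  expect_error(conjunction_mask(tA, stat_map(rep(0, 5), g2, "t", df = 10),
                                2.66), "grid")
})

test_that("restriction drops interaction clusters without task support", {
  # 8 planted interaction clusters on a line grid; 2 lack any per-group
  # task effect -> 6 survive
  g <- image_grid(c(40, 1, 1))
  vals <- rep(0, 40)
  starts <- seq(1, 40, by = 5)          # 8 clusters of 3 voxels
  for (s in starts) vals[s:(s + 2)] <- 10
  Fmap <- stat_map(vals, g, "F", df = c(1, 18))
  tab <- label_clusters(Fmap, 5, connectivity = 6, two_tailed = FALSE)
  expect_identical(nrow(tab), 8L)
  tA <- rep(0, 40); tB <- rep(0, 40)
  tA[starts[1:4]] <- 5                  # clusters 1-4 supported by group A
  tB[starts[5:6] + 1] <- -5             # clusters 5-6 supported by group B
  t_maps <- list(A = stat_map(tA, g, "t", df = 9),
                 B = stat_map(tB, g, "t", df = 9))
  kept <- suppressMessages(restrict_interaction(tab, t_maps, 2.66))
  expect_identical(nrow(kept), 6L)
  expect_true(all(kept$overlap_groups %in% c("A", "B")))
  # fully supported cluster kept; disjoint dropped
  expect_identical(nrow(suppressMessages(
    restrict_interaction(tab, list(A = stat_map(rep(0, 40), g, "t", df = 9)),
                         2.66))), 0L)
})

test_that("cluster mean z extraction and simple effects are faithful", {
  set.seed(34)
  n <- 10
  group <- rep(c("A", "B"), each = 5)
  z_pre <- matrix(rnorm(n * 6), n, 6)
  z_post <- z_pre + 0.1 * matrix(rnorm(n * 6), n, 6)
  z_post[group == "A", 1:3] <- z_post[group == "A", 1:3] + 2  # A increases
  zs <- make_zset(z_pre, z_post, group = group, dims = c(6, 1, 1))
  res <- cluster_mean_z(1:3, zs)
  # homogeneous cluster of one voxel equals that voxel's z
  res1 <- cluster_mean_z(2, zs)
  expect_equal(res1$scalars$mean_z[res1$scalars$session == "pre"],
               z_pre[, 2])
  se <- res$simple_effects
  pA <- se[se$effect == "post_vs_pre" & se$group == "A", ]
  pB <- se[se$effect == "post_vs_pre" & se$group == "B", ]
  expect_lt(pA$p, 0.05)
  expect_gt(pB$p, 0.05)
  expect_error(cluster_mean_z(integer(0), zs), "empty")
})

test_that("medication post-hoc reuses the change-score ANOVA identity", {
  set.seed(35)
  n <- 12
  med <- rep(c(TRUE, FALSE), each = 6)
  z_pre <- matrix(rnorm(n * 4), n, 4)
  z_post <- matrix(rnorm(n * 4), n, 4)
  zs <- make_zset(z_pre, z_post, group = rep("BPD", n), medicated = med,
                  dims = c(4, 1, 1))
  res <- medication_posthoc(zs, 1:4)
  # F = t^2 identity on the cluster scalars
  d <- rowMeans(z_post[, 1:4]) - rowMeans(z_pre[, 1:4])
  tt <- stats::t.test(d[med], d[!med], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_identical(res$df, c(1, 10))
  # degenerate factor errors
  zs_all <- make_zset(z_pre, z_post, group = rep("BPD", n),
                      medicated = rep(TRUE, n), dims = c(4, 1, 1))
  expect_error(medication_posthoc(zs_all, 1:4), "medication levels")
})

test_that("medication post-hoc is calibrated on permuted null labels", {
  set.seed(36)
  n <- 20
  z_pre <- matrix(rnorm(n * 3), n, 3)
  z_post <- matrix(rnorm(n * 3), n, 3)
  p <- replicate(400, {
    med <- sample(rep(c(TRUE, FALSE), each = 10))
    zs <- make_zset(z_pre, z_post, group = rep("BPD", n), medicated = med,
                    dims = c(3, 1, 1))
    medication_posthoc(zs, 1:3)$p
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("voxelwise p-values are uniform on null cohorts", {
  cfg <- quick_cfg(n_per_group = 6, n_timepoints = 180, rng_seed = 37)
  co <- simulate_cohort(cfg)
  zs <- residualize_site(zset_from_cohort(co))
  seedv <- c(co$truth$seed_voxels$left, co$truth$seed_voxels$right)
  keep <- which(!(which(zs$mask) %in% seedv))
  Fm <- interaction_F_map(zs)
  pf <- pf(Fm$values[zs$mask][keep], Fm$df[1], Fm$df[2], lower.tail = FALSE)
  expect_gt(stats::ks.test(pf, "punif")$p.value, 0.01)
  tm <- paired_t_map(zs, "A")
  ptv <- 2 * pt(-abs(tm$values[zs$mask][keep]), tm$df)
  expect_gt(stats::ks.test(ptv, "punif")$p.value, 0.01)
})

test_that("conjunction recovers a common planted network in both groups", {
  grid <- image_grid(c(14, 14, 12))
  net <- sphere_voxels(grid, c(0, 12, 9), 7.5, n_voxels = 40)
  cfg <- sim_config(dims = c(14, 14, 12),
                    groups = data.frame(label = c("A", "B"),
                                        n = c(20L, 20L)),
                    seed_centers_mm = rbind(c(-9, 0, 0), c(9, 0, 0)),
                    rng_seed = 71)
  cfg <- add_network(cfg, "net", net, 0.1)
  w <- matrix(c(0.1, 0.5, 0.1, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("pre", "post")))
  cfg <- plant_interaction(cfg, "net", w)
  co <- simulate_cohort(cfg)
  zs <- residualize_site(zset_from_cohort(co))
  tA <- paired_t_map(zs, "A")
  tB <- paired_t_map(zs, "B")
  conj <- conjunction_mask(tA, tB, t_critical(0.01, tA$df))
  expect_gte(mean(net %in% which(conj$included)), 0.8)
})
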