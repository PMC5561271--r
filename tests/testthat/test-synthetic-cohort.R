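test_that("cohort counting contract and determinism hold", {
  cfg <- quick_cfg(n_per_group = 3, n_timepoints = 20, rng_seed = 21)
  co <- simulate_cohort(cfg)
  # one volume per subject x session
  expect_identical(nrow(co$manifest), 2L * 6L)
  expect_identical(length(co$bolds), 12L)
  expect_true(all(vapply(co$bolds, function(b) b$n_timepoints, integer(1))
                  == 20L))
  # both sessions of a subject share a site
  sp <- split(co$manifest$site, co$manifest$subject_id)
  expect_true(all(vapply(sp, function(s) length(unique(s)) == 1,
                         logical(1))))
  # bitwise determinism under a fixed seed
  co2 <- simulate_cohort(cfg)
  expect_identical(co$bolds, co2$bolds)
  expect_identical(co$clinical, co2$clinical)
  expect_identical(co$truth$zeta, co2$truth$zeta)
  # different seed changes the data
  cfg3 <- cfg; cfg3$rng_seed <- 22L
  expect_false(identical(simulate_cohort(cfg3)$bolds[[1]], co$bolds[[1]]))
})

test_that("default study design yields 216 volumes of 180 timepoints", {
  # manifest-level contract of the full-size default design
  cfg <- sim_config(rng_seed = 1)
  expect_identical(sum(cfg$groups$n) * 2L, 216L)
  expect_identical(cfg$n_timepoints, 180L)
  expect_identical(nrow(cfg$seed_centers_mm), 2L)
  # generate two default-condition subjects (down-sampled groups, same
  # geometry) and check the advertised dimensions
  cfg2 <- sim_config(groups = data.frame(label = c("BPD", "NPC"),
                                         n = c(2L, 2L)), rng_seed = 2)
  co <- simulate_cohort(cfg2)
  expect_identical(nrow(co$manifest), 8L)
  expect_identical(co$bolds[[1]]$n_timepoints, 180L)
  expect_identical(co$bolds[[1]]$grid$dims, c(20L, 18L, 14L))
})

test_that("null coupling gives near-zero seed correlations", {
  cfg <- quick_cfg(n_per_group = 2, n_timepoints = 180, rng_seed = 23,
                   site_gain_sd = 0, site_offset_sd = 0)
  co <- simulate_cohort(cfg)
  zs <- zset_from_cohort(co)
  seedv <- c(co$truth$seed_voxels$left, co$truth$seed_voxels$right)
  cols <- which(!(which(zs$mask) %in% seedv))
  z <- zs$z_pre[1, cols]
  # |r| < 3/sqrt(180) for ~99% of voxels; allow sampling slack
  frac <- mean(abs(tanh(z)) < 3 / sqrt(180))
  expect_gt(frac, 0.97)
})

test_that("planted coupling is recovered on the Fisher-z scale", {
  # w = 0.6, ar1 = 0, no smoothing, no subject/site coupling variation:
  # network-mean z within 2 SE of atanh(0.6)
  cfg <- quick_cfg(n_per_group = 3, n_timepoints = 180, rng_seed = 24,
                   coupling_sd = 0, site_z_shift_sd = 0)
  net <- sphere_voxels(config_grid(cfg), c(0, 9, 6), 6)
  cfg <- add_network(cfg, "net", net, 0.6)
  co <- simulate_cohort(cfg)
  zs <- zset_from_cohort(co)
  cols <- match(net, which(zs$mask))
  per_map <- c(rowMeans(zs$z_pre[, cols]), rowMeans(zs$z_post[, cols]))
  se <- sd(per_map) / sqrt(length(per_map))
  expect_lt(abs(mean(per_map) - atanh(0.6)), 2 * se + 0.01)
})

test_that("variance contract: marginal voxel variance is noise_sd^2", {
  cfg <- quick_cfg(n_per_group = 2, n_timepoints = 180, rng_seed = 25,
                   site_gain_sd = 0, site_offset_sd = 0, noise_sd = 2)
  net <- sphere_voxels(config_grid(cfg), c(0, 9, 6), 6)
  cfg <- add_network(cfg, "net", net, 0.7)
  co <- simulate_cohort(cfg)
  v <- apply(co$bolds[[1]]$data[co$truth$brain_voxels, ], 1, var)
  # averaged over voxels, within 10% at T = 180 — including the w = 0.7
  # network, whose sqrt(1 - w^2) mixing preserves variance
  expect_lt(abs(mean(v) - 4) / 4, 0.10)
  netv <- apply(co$bolds[[1]]$data[net, ], 1, var)
  expect_lt(abs(mean(netv) - 4) / 4, 0.10)
})

test_that("site intensity offsets match their configured draws", {
  cfg <- quick_cfg(n_per_group = 6, n_timepoints = 60, rng_seed = 26,
                   site_gain_sd = 0, site_offset_sd = 5)
  co <- simulate_cohort(cfg)
  bmean <- vapply(co$bolds, function(b) mean(b$data[co$truth$brain_voxels, ]),
                  numeric(1))
  site <- co$manifest$site
  for (s in unique(site)) {
    ms <- mean(bmean[site == s])
    se <- sd(bmean[site == s]) / sqrt(sum(site == s))
    expect_lt(abs(ms - (cfg$baseline + co$truth$site_offset[s])), 2 * se + 0.05)
  }
})

test_that("plant_interaction encodes the intended true effect", {
  cfg <- quick_cfg(rng_seed = 27)
  net <- sphere_voxels(config_grid(cfg), c(0, 9, 6), 6)
  cfg <- add_network(cfg, "net", net, 0.1)
  w_eq <- matrix(0.3, 2, 2, dimnames = list(c("A", "B"), c("pre", "post")))
  expect_equal(true_interaction(plant_interaction(cfg, "net", w_eq),
                                "net", c("A", "B")), 0)
  w <- matrix(c(0.1, 0.5, 0.1, 0.1), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("pre", "post")))
  expect_equal(true_interaction(plant_interaction(cfg, "net", w),
                                "net", c("A", "B")),
               atanh(0.5) - atanh(0.1))
  expect_error(plant_interaction(cfg, "nope", w), "unknown network")
  wbad <- matrix(c(0.1, 1.0, 0.1, 0.1), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("pre", "post")))
  expect_error(plant_interaction(cfg, "net", wbad), "w\\^2 < 1")
})

test_that("networks may not overlap the seed spheres unless allowed", {
  cfg <- quick_cfg(rng_seed = 28)
  g <- config_grid(cfg)
  seed_sphere <- sphere_voxels(g, c(-7, 0, 0), 4)
  expect_error(add_network(cfg, "bad", seed_sphere, 0.3), "overlap")
  cfg2 <- quick_cfg(rng_seed = 28, allow_seed_overlap = TRUE)
  expect_silent({cfg2 <- add_network(cfg2, "ok", seed_sphere, 0.3)})
  # and never outside the brain box
  edge <- 1L   # first voxel sits on the background border
  expect_error(add_network(cfg, "edge", edge, 0.3), "outside the brain box")
})

test_that("on-disk cohorts carry manifest, clinical table and ground truth", {
  cfg <- quick_cfg(n_per_group = 2, n_timepoints = 10, rng_seed = 29)
  d <- file.path(tempdir(), "coh_disk")
  co <- simulate_cohort(cfg, dir = d)
  expect_null(co$bolds)
  expect_true(all(file.exists(co$manifest$path)))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(file.exists(file.path(d, "clinical.csv")))
  gt <- file.path(d, "ground_truth.json")
  expect_true(file.exists(gt))
  parsed <- jsonlite::fromJSON(gt)
  expect_equal(parsed$site_offset, co$truth$site_offset, tolerance = 1e-8)
  # itec total is the unweighted sum of the five subscales
  cl <- co$clinical
  expect_equal(cl$itec_total,
               cl$itec_sexual + cl$itec_physical + cl$itec_emotional +
                 cl$itec_emo_neglect + cl$itec_phys_neglect)
  unlink(d, recursive = TRUE)
})

test_that("clinical link reaches its target correlation with true change", {
  cfg <- quick_cfg(n_per_group = 150, n_timepoints = 10, rng_seed = 30)
  net <- sphere_voxels(config_grid(cfg), c(0, 9, 6), 6)
  cfg <- add_network(cfg, "net", net, 0.3)
  cfg$clinical_links <- list(clinical_link("BPDSI", "net", target_r = 0.45))
  co <- simulate_cohort(cfg)
  dz_true <- co$truth$zeta[, "net", "post"] - co$truth$zeta[, "net", "pre"]
  r <- cor(dz_true, co$clinical$BPDSI)
  expect_lt(abs(r - 0.45), 0.12)  # ~2.5 sd of r at n = 300
})

test_that("YAML configurations reproduce programmatic ones", {
  path <- system.file("extdata", "sim_config_example.yaml",
                      package = "seedfc")
  cfg <- sim_config_from_yaml(path)
  expect_identical(cfg$dims, c(14L, 14L, 12L))
  expect_identical(cfg$groups$n, c(20L, 20L))
  expect_identical(names(cfg$networks), "frontal")
  expect_identical(length(cfg$networks$frontal$voxels), 40L)
  expect_equal(cfg$networks$frontal$w["BPD", "post"], 0.5)
  expect_equal(cfg$networks$frontal$w["NPC", "post"], 0.1)
  expect_identical(cfg$clinical_links[[1]]$score, "BPDSI")
  # equivalent to the same config built in code
  grid <- config_grid(cfg)
  cfg2 <- sim_config(dims = c(14, 14, 12), n_timepoints = 180,
                     groups = data.frame(label = c("BPD", "NPC"),
                                         n = c(20L, 20L)),
                     n_sites = 2,
                     seed_centers_mm = rbind(c(-9, 0, 0), c(9, 0, 0)),
                     rng_seed = 1)
  cfg2 <- add_network(cfg2, "frontal",
                      sphere_voxels(grid, c(0, 12, 9), 7.5, n_voxels = 40),
                      matrix(c(0.1, 0.5, 0.1, 0.1), 2, 2, byrow = TRUE))
  expect_identical(cfg$networks$frontal$voxels,
                   cfg2$networks$frontal$voxels)
  expect_equal(unname(cfg$networks$frontal$w),
               unname(cfg2$networks$frontal$w))
})
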