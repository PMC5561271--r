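#' Configuration of a synthetic multi-site rsFC cohort
#'
#' Defines the study conditions the generator emulates: two six-minute
#' resting-state runs (180 volumes, TR 2 s, 3 mm isotropic voxels) acquired
#' before and after a task, three diagnostic groups (BPD n = 48, NPC n = 39,
#' CPD n = 21), three acquisition sites, a bilateral amygdala seed (5 mm
#' spheres at (+-22, -6, -14) mm), and optional seed-coupled networks whose
#' coupling differs by group and session.
#'
#' The generative model per subject-session: a latent seed signal `s(t)`
#' (AR(1), unit marginal sd); seed voxels carry `s` plus independent noise;
#' a voxel in network with coupling `w` carries `w*s + sqrt(1-w^2)*e` with
#' `e` an independent AR(1) series of matching variance (so every voxel's
#' marginal sd is `noise_sd` regardless of `w`); remaining brain voxels carry
#' pure `e`. Couplings vary per subject on the atanh scale (`coupling_sd`),
#' sites add a coupling shift (`site_z_shift_sd`) plus intensity gain/offset,
#' and clinical scores are optionally linked to a network's true change in
#' atanh coupling.
#'
#' @param dims grid dimensions (default `c(20, 18, 14)`, 3 mm voxels, centred
#'   so the seed spheres fit comfortably).
#' @param voxel_size_mm voxel edge lengths, mm.
#' @param n_timepoints volumes per run (study value 180).
#' @param tr_seconds repetition time (study value 2).
#' @param groups data.frame with columns `label` and `n` (defaults BPD = 48,
#'   NPC = 39, CPD = 21; every group needs n >= 2).
#' @param n_sites number of acquisition sites (study value 3).
#' @param seed_centers_mm,seed_radius_mm bilateral seed definition.
#' @param noise_sd marginal sd of each brain voxel's fluctuation.
#' @param ar1_coef lag-1 autocorrelation of latent and noise series.
#' @param spatial_fwhm_mm optional Gaussian smoothing of each volume (0 =
#'   none).
#' @param baseline mean intensity of brain tissue (arbitrary units).
#' @param background_border voxels of near-empty background bordering the
#'   brain box on every face.
#' @param coupling_sd per-subject, per-session sd of the coupling on the
#'   atanh scale.
#' @param seed_noise_sd noise sd of seed voxels relative to the latent signal.
#' @param site_gain_sd,site_offset_sd per-site multiplicative gain sd and
#'   additive intensity offset sd.
#' @param site_z_shift_sd per-site additive shift of network coupling on the
#'   atanh scale (what site residualization removes).
#' @param medicated_prop proportion of the first group flagged as medicated
#'   (study: 31 of 48).
#' @param allow_seed_overlap may networks overlap the seed spheres?
#' @param clinical_links list of [clinical_link()] specifications.
#' @param rng_seed integer seed; identical configs with identical seeds give
#'   bitwise-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dims = c(20, 18, 14),
                       voxel_size_mm = c(3, 3, 3),
                       n_timepoints = 180,
                       tr_seconds = 2,
                       groups = data.frame(label = c("BPD", "NPC", "CPD"),
                                           n = c(48L, 39L, 21L)),
                       n_sites = 3,
                       seed_centers_mm = rbind(c(-22, -6, -14),
                                               c(22, -6, -14)),
                       seed_radius_mm = 5,
                       noise_sd = 1,
                       ar1_coef = 0.3,
                       spatial_fwhm_mm = 0,
                       baseline = 100,
                       background_border = 1,
                       coupling_sd = 0.15,
                       seed_noise_sd = 0.2,
                       site_gain_sd = 0.05,
                       site_offset_sd = 2,
                       site_z_shift_sd = 0.05,
                       medicated_prop = 31 / 48,
                       allow_seed_overlap = FALSE,
                       clinical_links = list(),
                       rng_seed = 1L) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("label", "n") %in% names(groups)),
            all(groups$n >= 2), n_sites >= 1,
            n_timepoints >= 2, noise_sd > 0,
            abs(ar1_coef) < 1, spatial_fwhm_mm >= 0,
            coupling_sd >= 0, seed_noise_sd >= 0,
            medicated_prop >= 0, medicated_prop <= 1)
  cfg <- structure(list(
    dims = as.integer(dims), voxel_size_mm = rep_len(voxel_size_mm, 3L),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    groups = groups, n_sites = as.integer(n_sites),
    seed_centers_mm = as.matrix(seed_centers_mm),
    seed_radius_mm = seed_radius_mm,
    noise_sd = noise_sd, ar1_coef = ar1_coef,
    spatial_fwhm_mm = spatial_fwhm_mm,
    baseline = baseline, background_border = as.integer(background_border),
    coupling_sd = coupling_sd, seed_noise_sd = seed_noise_sd,
    site_gain_sd = site_gain_sd, site_offset_sd = site_offset_sd,
    site_z_shift_sd = site_z_shift_sd,
    medicated_prop = medicated_prop,
    allow_seed_overlap = allow_seed_overlap,
    networks = list(), clinical_links = clinical_links,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
  grid <- config_grid(cfg)
  for (k in 1:2) mm_to_voxel(grid, cfg$seed_centers_mm[k, ])
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d x %d x %d grid, %d timepoints, ",
                     "%d groups (N = %d), %d sites, %d network(s)\n"),
              x$dims[1], x$dims[2], x$dims[3], x$n_timepoints,
              nrow(x$groups), sum(x$groups$n), x$n_sites,
              length(x$networks)))
  invisible(x)
}

#' @describeIn sim_config the [image_grid()] a configuration generates on.
#' @param config a `sim_config`.
#' @export
config_grid <- function(config) {
  image_grid(config$dims, config$voxel_size_mm)
}

# Linear voxel indices of the brain box (grid minus the background border).
config_brain_voxels <- function(config) {
  b <- config$background_border
  idx <- arrayInd(seq_len(prod(config$dims)), config$dims)
  which(idx[, 1] > b & idx[, 1] <= config$dims[1] - b &
        idx[, 2] > b & idx[, 2] <= config$dims[2] - b &
        idx[, 3] > b & idx[, 3] <= config$dims[3] - b)
}

config_seed_voxels <- function(config) {
  grid <- config_grid(config)
  l <- build_sphere_mask(grid, config$seed_centers_mm[1, ],
                         config$seed_radius_mm)
  r <- build_sphere_mask(grid, config$seed_centers_mm[2, ],
                         config$seed_radius_mm)
  list(left = which(l$included), right = which(r$included))
}

#' Add a seed-coupled network to a configuration
#'
#' @param config a [sim_config()].
#' @param name network name.
#' @param voxels integer linear voxel indices (see [sphere_voxels()]), inside
#'   the brain box.
#' @param w baseline coupling: a scalar applied to every group and session,
#'   or an `n_groups x 2` matrix (columns pre, post) of couplings in `[0, 1)`.
#' @return The updated configuration.
#' @export
add_network <- function(config, name, voxels, w = 0) {
  voxels <- sort(unique(as.integer(voxels)))
  brain <- config_brain_voxels(config)
  if (!all(voxels %in% brain))
    stop(sprintf("network '%s' extends outside the brain box", name))
  seeds <- config_seed_voxels(config)
  if (!config$allow_seed_overlap &&
      any(voxels %in% c(seeds$left, seeds$right)))
    stop(sprintf("network '%s' overlaps the seed spheres", name))
  ng <- nrow(config$groups)
  if (length(w) == 1L) w <- matrix(w, ng, 2)
  w <- as.matrix(w)
  stopifnot(identical(dim(w), c(ng, 2L)))
  if (any(w^2 >= 1) || any(w < 0))
    stop("couplings must satisfy 0 <= w and w^2 < 1")
  dimnames(w) <- list(config$groups$label, c("pre", "post"))
  config$networks[[name]] <- list(voxels = voxels, w = w)
  config
}

#' Linear voxel indices of a sphere
#'
#' @param grid an [image_grid()].
#' @param center_mm,radius_mm sphere definition in mm.
#' @param n_voxels optionally keep only the `n_voxels` indices closest to the
#'   centre (deterministic tie-break by linear index), e.g. to plant a
#'   network of an exact size.
#' @return Integer vector of linear voxel indices.
#' @export
sphere_voxels <- function(grid, center_mm, radius_mm, n_voxels = NULL) {
  d2 <- rowSums(sweep(all_voxel_mm(grid), 2, center_mm)^2)
  idx <- which(d2 <= radius_mm^2)
  if (!is.null(n_voxels)) {
    if (length(idx) < n_voxels)
      stop("sphere holds fewer voxels than requested")
    idx <- idx[order(d2[idx], idx)][seq_len(n_voxels)]
  }
  sort(idx)
}

#' Plant a group-by-time coupling interaction in a network
#'
#' Sets the four couplings (two groups x two sessions) of `network`, leaving
#' other groups at their current values. The planted true interaction effect
#' on the Fisher-z scale is
#' `[atanh(w[A,post]) - atanh(w[A,pre])] - [atanh(w[B,post]) - atanh(w[B,pre])]`.
#'
#' @param config a [sim_config()] that already contains `network`.
#' @param network network name.
#' @param w_by_group_session 2 x 2 numeric matrix, rows named by the two
#'   groups, columns pre/post.
#' @return The updated configuration.
#' @export
plant_interaction <- function(config, network, w_by_group_session) {
  if (!network %in% names(config$networks))
    stop(sprintf("unknown network '%s'", network))
  w <- as.matrix(w_by_group_session)
  stopifnot(identical(dim(w), c(2L, 2L)), !is.null(rownames(w)))
  if (any(w^2 >= 1) || any(w < 0))
    stop("couplings must satisfy 0 <= w and w^2 < 1")
  if (!all(rownames(w) %in% config$groups$label))
    stop("row names of w must be group labels")
  config$networks[[network]]$w[rownames(w), ] <- w
  config
}

#' True interaction effect of a planted network
#'
#' @param config a [sim_config()].
#' @param network network name.
#' @param groups two group labels (A, B).
#' @return The population group-by-time interaction on the atanh scale.
#' @export
true_interaction <- function(config, network, groups) {
  w <- config$networks[[network]]$w
  (atanh(w[groups[1], "post"]) - atanh(w[groups[1], "pre"])) -
    (atanh(w[groups[2], "post"]) - atanh(w[groups[2], "pre"]))
}

#' Link a clinical score to a network's true connectivity change
#'
#' The generated score is `intercept + slope * dz_i + noise`, where `dz_i` is
#' subject i's true post-minus-pre change in atanh coupling of the target
#' network. `noise_sd` may be given directly, or derived from a target
#' population correlation `target_r` between score and true change:
#' `noise_sd = slope * sd(dz) * sqrt(1/target_r^2 - 1)`, where
#' `sd(dz) = coupling_sd` under the generator's coupling model (the two
#' session-specific components have sd `coupling_sd/sqrt(2)` each).
#'
#' @param score score name (e.g. `"BPDSI"`).
#' @param network target network name.
#' @param slope linear slope (score units per unit atanh coupling change).
#' @param noise_sd score noise sd; mutually exclusive with `target_r`.
#' @param target_r target population correlation in (0, 1).
#' @param intercept score mean offset.
#' @return A link specification for `sim_config(clinical_links = ...)`.
#' @export
clinical_link <- function(score, network, slope = 20, noise_sd = NULL,
                          target_r = NULL, intercept = 30) {
  if (is.null(noise_sd) == is.null(target_r))
    stop("give exactly one of noise_sd or target_r")
  structure(list(score = score, network = network, slope = slope,
                 noise_sd = noise_sd, target_r = target_r,
                 intercept = intercept), class = "clinical_link")
}

# Clinical scale marginals used when a score is not linked to a network:
# group-wise normal draws truncated at zero, loosely matching the clinical
# profile of a BPD / non-patient / cluster-C cohort.
clinical_scales <- function() {
  list(
    BPDSI = rbind(BPD = c(30, 12), NPC = c(2, 2), CPD = c(12, 8)),
    BSI = rbind(BPD = c(1.68, 0.55), NPC = c(0.13, 0.13), CPD = c(1.11, 0.43)),
    checklist = rbind(BPD = c(118.44, 25.58), NPC = c(50.68, 5.21),
                      CPD = c(74.80, 17.31)),
    itec_sexual = rbind(BPD = c(9.44, 8.85), NPC = c(0.13, 0.42),
                        CPD = c(2.26, 5.43)),
    itec_physical = rbind(BPD = c(17.15, 12.40), NPC = c(1.69, 3.61),
                          CPD = c(7.00, 10.95)),
    itec_emotional = rbind(BPD = c(20.35, 8.93), NPC = c(2.47, 3.32),
                           CPD = c(13.06, 8.49)),
    itec_emo_neglect = rbind(BPD = c(11.28, 6.99), NPC = c(0.82, 2.07),
                             CPD = c(6.14, 6.55)),
    itec_phys_neglect = rbind(BPD = c(10.68, 9.42), NPC = c(0.88, 2.82),
                              CPD = c(4.35, 6.90)),
    dissociation_pre = rbind(BPD = c(19.81, 19.41), NPC = c(5.18, 6.60),
                             CPD = c(6.37, 6.98)),
    dissociation_post = rbind(BPD = c(31.87, 26.85), NPC = c(6.40, 7.81),
                              CPD = c(15.36, 20.60)))
}

#' Generate a synthetic multi-site two-session cohort
#'
#' Draws one [bold4d()] volume per subject and session under the generative
#' model of [sim_config()], together with a manifest, clinical scores, and
#' the ground truth needed for recovery tests. Identical `(config, rng_seed)`
#' give bitwise-identical output.
#'
#' @param config a [sim_config()].
#' @param dir if non-`NULL`, volumes are written there as
#'   `<subject>_<session>.nii.gz` (plus `manifest.csv`, `clinical.csv`,
#'   `ground_truth.json`) and are not kept in memory.
#' @return An object of class `fc_cohort`: a list with `manifest`
#'   (subject_id, group, site, session, medicated, path), `clinical`
#'   (one row per subject), `truth` (population couplings, per-subject true
#'   atanh couplings `zeta`, network voxels, site effects, brain/seed masks,
#'   clinical generating parameters), `bolds` (named list, `NULL` when
#'   written to `dir`) and `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  with_rng_seed(config$rng_seed, simulate_cohort_impl(config, dir))
}

simulate_cohort_impl <- function(config, dir) {
  grid <- config_grid(config)
  nv <- n_voxels(grid)
  nt <- config$n_timepoints
  groups <- config$groups
  n_total <- sum(groups$n)
  labels <- rep(groups$label, groups$n)
  subject_id <- sprintf("S%03d", seq_len(n_total))
  # Round-robin site assignment within group keeps every group represented
  # at every site; both sessions of a subject share the site.
  site <- unlist(lapply(groups$n, function(n)
    rep_len(seq_len(config$n_sites), n)), use.names = FALSE)
  medicated <- logical(n_total)
  first <- labels == groups$label[1]
  n_med <- round(config$medicated_prop * sum(first))
  medicated[sample(which(first), n_med)] <- TRUE

  site_gain <- 1 + stats::rnorm(config$n_sites, sd = config$site_gain_sd)
  site_offset <- stats::rnorm(config$n_sites, sd = config$site_offset_sd)
  site_z_shift <- stats::rnorm(config$n_sites, sd = config$site_z_shift_sd)

  nets <- config$networks
  n_nets <- length(nets)
  # True per-subject couplings on the atanh scale: group mean + site shift +
  # stable subject effect + session-specific deviation.
  zeta <- array(NA_real_, c(n_total, max(1L, n_nets), 2L),
                dimnames = list(subject_id,
                                if (n_nets) names(nets) else "none",
                                c("pre", "post")))
  if (n_nets) {
    for (k in seq_len(n_nets)) {
      base <- atanh(nets[[k]]$w[labels, , drop = FALSE])
      subj <- stats::rnorm(n_total, sd = config$coupling_sd / sqrt(2))
      sess <- matrix(stats::rnorm(2 * n_total,
                                  sd = config$coupling_sd / sqrt(2)),
                     n_total, 2)
      zeta[, k, ] <- base + site_z_shift[site] + subj + sess
    }
  }

  brain <- config_brain_voxels(config)
  seeds <- config_seed_voxels(config)
  seed_vox <- c(seeds$left, seeds$right)
  plain <- setdiff(brain, seed_vox)
  if (n_nets) plain <- setdiff(plain, unlist(lapply(nets, `[[`, "voxels")))
  background <- setdiff(seq_len(nv), brain)

  manifest <- data.frame(
    subject_id = rep(subject_id, each = 2),
    group = rep(labels, each = 2),
    site = rep(site, each = 2),
    session = rep(c("pre", "post"), n_total),
    medicated = rep(medicated, each = 2),
    path = NA_character_, stringsAsFactors = FALSE)

  keep <- is.null(dir)
  if (!keep) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bolds <- if (keep) vector("list", nrow(manifest)) else NULL
  names_out <- character(nrow(manifest))

  seed_scale <- 1 / sqrt(1 + config$seed_noise_sd^2)
  row <- 0L
  for (i in seq_len(n_total)) {
    for (sess in 1:2) {
      row <- row + 1L
      s <- drop(ar1_noise(1L, nt, config$ar1_coef))
      series <- ar1_noise(nv, nt, config$ar1_coef)   # plain voxels keep eps
      eps_bg <- series[background, , drop = FALSE]
      series[seed_vox, ] <- seed_scale *
        (rep(1, length(seed_vox)) %o% s +
         config$seed_noise_sd * series[seed_vox, , drop = FALSE])
      if (n_nets) {
        for (k in seq_len(n_nets)) {
          w <- tanh(zeta[i, k, sess])
          v <- nets[[k]]$voxels
          series[v, ] <- w * (rep(1, length(v)) %o% s) +
            sqrt(1 - w^2) * series[v, , drop = FALSE]
        }
      }
      if (config$noise_sd != 1) series <- config$noise_sd * series
      if (config$spatial_fwhm_mm > 0) {
        arr <- array(series, c(grid$dims, nt))
        for (tp in seq_len(nt))
          arr[, , , tp] <- gaussian_smooth_3d(arr[, , , tp],
                                              config$spatial_fwhm_mm,
                                              grid$voxel_size)
        series <- matrix(arr, nv, nt)
      }
      st <- site[i]
      data <- config$baseline + site_offset[st] + site_gain[st] * series
      if (length(background))
        data[background, ] <- 0.01 * config$noise_sd * eps_bg
      vol <- bold4d(data, grid, tr_seconds = config$tr_seconds)
      nm <- sprintf("%s_%s", manifest$subject_id[row], manifest$session[row])
      names_out[row] <- nm
      if (keep) bolds[[row]] <- vol
      else {
        p <- file.path(dir, paste0(nm, ".nii.gz"))
        write_volume(vol, p)
        manifest$path[row] <- p
      }
    }
  }
  if (keep) names(bolds) <- names_out

  clinical <- generate_clinical(config, labels, zeta, subject_id)

  truth <- structure(list(
    coupling = if (n_nets) lapply(nets, `[[`, "w") else list(),
    zeta = zeta,
    networks = if (n_nets) lapply(nets, `[[`, "voxels") else list(),
    brain_voxels = brain,
    seed_voxels = seeds,
    site_gain = site_gain, site_offset = site_offset,
    site_z_shift = site_z_shift,
    clinical_params = attr(clinical, "params")), class = "sim_truth")

  cohort <- structure(list(manifest = manifest, clinical = clinical,
                           truth = truth, bolds = bolds, config = config),
                      class = "fc_cohort")
  if (!keep) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(clinical, file.path(dir, "clinical.csv"),
                     row.names = FALSE)
    gt <- list(coupling = truth$coupling, networks = truth$networks,
               site_gain = site_gain, site_offset = site_offset,
               site_z_shift = site_z_shift)
    writeLines(format_truth_json(gt), file.path(dir, "ground_truth.json"))
  }
  cohort
}

# Minimal JSON serialization of the on-disk ground-truth summary (numbers,
# vectors, named lists); avoids adding a hard dependency for one file.
format_truth_json <- function(x) {
  fmt <- function(v) {
    if (is.list(v)) {
      inner <- vapply(seq_along(v), function(i)
        sprintf('"%s": %s', names(v)[i], fmt(v[[i]])), character(1))
      paste0("{", paste(inner, collapse = ", "), "}")
    } else if (is.matrix(v)) {
      fmt(split(v, row(v)))
    } else if (length(v) == 1L) {
      sprintf("%.10g", as.numeric(v))
    } else {
      paste0("[", paste(sprintf("%.10g", as.numeric(v)), collapse = ", "),
             "]")
    }
  }
  fmt(x)
}

generate_clinical <- function(config, labels, zeta, subject_id) {
  scales <- clinical_scales()
  n <- length(labels)
  out <- data.frame(subject_id = subject_id, group = labels,
                    stringsAsFactors = FALSE)
  for (nm in names(scales)) {
    # groups without a tabulated clinical profile fall back to the first row
    ridx <- match(labels, rownames(scales[[nm]]))
    ridx[is.na(ridx)] <- 1L
    par <- scales[[nm]][ridx, , drop = FALSE]
    out[[nm]] <- pmax(0, stats::rnorm(n, par[, 1], par[, 2]))
  }
  params <- list()
  for (link in config$clinical_links) {
    if (!link$network %in% names(config$networks))
      stop(sprintf("clinical link targets unknown network '%s'",
                   link$network))
    dz <- zeta[, link$network, "post"] - zeta[, link$network, "pre"]
    noise_sd <- link$noise_sd
    if (is.null(noise_sd)) {
      # the session-specific coupling components have sd coupling_sd/sqrt(2)
      # each, so the true change dz = e_post - e_pre has sd = coupling_sd
      sd_dz <- config$coupling_sd
      noise_sd <- link$slope * sd_dz * sqrt(1 / link$target_r^2 - 1)
    }
    out[[link$score]] <- link$intercept + link$slope * dz +
      stats::rnorm(n, sd = noise_sd)
    params[[link$score]] <- list(network = link$network, slope = link$slope,
                                 noise_sd = noise_sd,
                                 intercept = link$intercept)
  }
  out$itec_total <- out$itec_sexual + out$itec_physical +
    out$itec_emotional + out$itec_emo_neglect + out$itec_phys_neglect
  out$dissociation_change <- out$dissociation_post - out$dissociation_pre
  attr(out, "params") <- params
  out
}

#' Build a simulation configuration from a YAML file
#'
#' The YAML file may contain any scalar/vector argument of [sim_config()]
#' (`groups` as a list of `{label, n}` records), plus two optional
#' sections: `networks`, a mapping of network name to `{center_mm,
#' radius_mm, n_voxels, w}` (`w` a scalar, or a per-group mapping of
#' `[pre, post]` pairs), and `clinical_links`, a list of
#' [clinical_link()] argument sets. An example ships at
#' `system.file("extdata", "sim_config_example.yaml", package = "seedfc")`.
#'
#' @param path YAML file path.
#' @param rng_seed optional seed overriding the file's value.
#' @return A [sim_config()].
#' @export
sim_config_from_yaml <- function(path, rng_seed = NULL) {
  spec <- yaml::read_yaml(path)
  networks <- spec$networks
  links <- spec$clinical_links
  spec$networks <- NULL
  spec$clinical_links <- NULL
  if (!is.null(spec$groups))
    spec$groups <- do.call(rbind, lapply(spec$groups, function(g)
      data.frame(label = g$label, n = as.integer(g$n))))
  if (!is.null(spec$seed_centers_mm))
    spec$seed_centers_mm <- do.call(rbind, spec$seed_centers_mm)
  if (!is.null(rng_seed)) spec$rng_seed <- rng_seed
  cfg <- do.call(sim_config, spec)
  for (nm in names(networks)) {
    net <- networks[[nm]]
    vox <- sphere_voxels(config_grid(cfg), unlist(net$center_mm),
                         net$radius_mm,
                         n_voxels = net$n_voxels)
    w <- net$w
    if (is.list(w))
      w <- do.call(rbind, w)[cfg$groups$label, , drop = FALSE]
    cfg <- add_network(cfg, nm, vox, if (is.null(w)) 0 else w)
  }
  cfg$clinical_links <- lapply(links, function(l) do.call(clinical_link, l))
  cfg
}
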