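# Independent oracles and small fixture builders used across the suite.

# Pure-R flood-fill connected-component labeling (queue-based), written
# independently of the package's compiled labeler.
flood_fill_oracle <- function(incl, dims, connectivity) {
  stopifnot(connectivity %in% c(6, 18, 26))
  arr <- array(incl, dims)
  labels <- array(0L, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[s > 0 & ((connectivity == 26) | (connectivity == 18 & s <= 2) |
                          (connectivity == 6 & s == 1)), , drop = FALSE]
  nxt <- 0L
  coords <- which(arr, arr.ind = TRUE)
  for (row in seq_len(nrow(coords))) {
    start <- coords[row, ]
    if (labels[start[1], start[2], start[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(start)
    labels[start[1], start[2], start[3]] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        w <- v + offs[k, ]
        if (any(w < 1) || any(w > dims)) next
        if (arr[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  as.vector(labels)
}

# Do two labelings define the same partition of the foreground?
same_partition <- function(lab1, lab2) {
  fg <- lab1 > 0
  if (!identical(fg, lab2 > 0)) return(FALSE)
  key <- paste(lab1[fg], lab2[fg])
  length(unique(key)) == length(unique(lab1[fg])) &&
    length(unique(key)) == length(unique(lab2[fg]))
}

# Full two-way mixed-model ANOVA (group between, time within) via stats::aov
# with an Error(subject) stratum; returns the group:time interaction F.
mixed_anova_F_oracle <- function(pre, post, group) {
  n <- length(pre)
  df <- data.frame(
    y = c(pre, post),
    time = factor(rep(c("pre", "post"), each = n)),
    group = factor(rep(group, 2)),
    subject = factor(rep(seq_len(n), 2)))
  fit <- stats::aov(y ~ group * time + Error(subject), data = df)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  within["group:time", "F value"]
}

# Small subject_zset built directly from given matrices (no simulation).
make_zset <- function(z_pre, z_post, group, site = NULL, medicated = NULL,
                      dims = NULL) {
  n <- nrow(z_pre)
  V <- ncol(z_pre)
  if (is.null(dims)) dims <- c(V, 1, 1)
  grid <- image_grid(dims)
  stopifnot(prod(dims) == V)
  if (is.null(site)) site <- rep(1L, n)
  if (is.null(medicated)) medicated <- rep(FALSE, n)
  subject_zset(z_pre, z_post,
               data.frame(subject_id = sprintf("P%02d", seq_len(n)),
                          group = group, site = site, medicated = medicated),
               grid, brain_mask(rep(TRUE, V), grid))
}

# Small two-group cohort configuration on a compact grid; seeds scaled to
# fit the grid. Extra arguments override sim_config defaults.
quick_cfg <- function(n_per_group = 4, dims = c(12, 12, 10),
                      n_timepoints = 60, ar1_coef = 0, rng_seed = 1, ...) {
  sim_config(dims = dims,
             groups = data.frame(label = c("A", "B"),
                                 n = rep(as.integer(n_per_group), 2)),
             seed_centers_mm = rbind(c(-7, 0, 0), c(7, 0, 0)),
             n_timepoints = n_timepoints, ar1_coef = ar1_coef,
             rng_seed = rng_seed, ...)
}
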