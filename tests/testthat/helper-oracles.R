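## Independent brute-force box counter: enumerates every box of the grid
## anchored at the foreground bounding-box corner with three nested loops and
## tests each sub-array for foreground. Deliberately naive; used as the
## oracle against the optimized counter.
brute_force_box_count <- function(grid, r) {
  w <- which(grid, arr.ind = TRUE)
  lo <- apply(w, 2, min)
  hi <- apply(w, 2, max)
  count <- 0L
  for (x0 in seq(lo[1], hi[1], by = r))
    for (y0 in seq(lo[2], hi[2], by = r))
      for (z0 in seq(lo[3], hi[3], by = r)) {
        xs <- x0:min(x0 + r - 1L, hi[1])
        ys <- y0:min(y0 + r - 1L, hi[2])
        zs <- z0:min(z0 + r - 1L, hi[3])
        if (any(grid[xs, ys, zs])) count <- count + 1L
      }
  count
}

random_mask_grid <- function(shape, density = 0.3) {
  g <- array(runif(prod(shape)) < density, shape)
  if (!any(g)) g[1, 1, 1] <- TRUE
  g
}

## minimal single-region cohort config for simulation studies
one_region_config <- function(n, seed, b0 = 2.38, beta_age = 0, beta_age2 = 0,
                              beta_sex = 0, beta_tbv = 0, sigma = 0.015,
                              region = "lh") {
  cohort_config(
    n_subjects = n, seed = seed,
    coefs = data.frame(region = region, b0 = b0, beta_age = beta_age,
                       beta_age2 = beta_age2, beta_sex = beta_sex,
                       beta_tbv = beta_tbv, sigma = sigma),
    outlier_rate = 0
  )
}

## exact power-law curve n(r) = C * r^(-exponent), free of rounding
power_law_curve <- function(exponent, rr = 2:14, C = 1e6) {
  data.frame(r = rr, n_boxes = C * rr^(-exponent))
}

lobar_regions <- c("lf", "rf", "lt", "rt", "lp", "rp", "lo", "ro")
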