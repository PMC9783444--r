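## Calibration of the percolation generator used in subject volumes: for the
## 24^3 compartment construction (subdivision schedule 3,2,2,2; per-level
## retention m^(d-3)) this maps the theoretical percolation dimension d to
## the mean FD the box-counting estimator measures at the lobe window
## (r = 2..14). The gap between the two is a finite-resolution effect of the
## linear-r log-log fit; it was measured once (60 seeded phantoms per grid
## point) and is frozen here. Monotone increasing, so it can be inverted by
## interpolation to choose d for a target measured FD.
PERC_CALIBRATION <- data.frame(
  d_theory = seq(1.8, 3.0, 0.05),
  fd_measured = c(1.3551, 1.4399, 1.4613, 1.5183, 1.6026, 1.6545, 1.6964,
                  1.7808, 1.8427, 1.8617, 1.9420, 1.9937, 2.0721, 2.1184,
                  2.1635, 2.2419, 2.2789, 2.3321, 2.3955, 2.4647, 2.5132,
                  2.5606, 2.6219, 2.6682, 2.7179)
)

## subdivision schedule for one lobar compartment: 3*2*2*2 = 24 voxels/edge
COMPARTMENT_MS <- c(3L, 2L, 2L, 2L)
COMPARTMENT_EDGE <- prod(COMPARTMENT_MS)

#' Map a target measured FD to a percolation dimension
#'
#' Inverts the frozen generator calibration: given the FD one wants the
#' box-counting estimator to read off a compartment phantom (lobe window),
#' returns the theoretical percolation dimension to generate at. Targets
#' outside the calibrated range are clamped to its ends.
#'
#' @param target_fd Numeric vector of target measured FD values.
#' @return Theoretical dimensions `d` (per-level retention is `m^(d-3)`).
#' @export
target_to_dimension <- function(target_fd) {
  stats::approx(PERC_CALIBRATION$fd_measured, PERC_CALIBRATION$d_theory,
                xout = target_fd, rule = 2)$y
}

## fixed anatomical caricature: left/right split on x, four (y, z) quadrant
## compartments per side. Values are the (x, y, z) octant indices (0/1).
COMPARTMENT_LAYOUT <- list(
  lf = c(0L, 0L, 0L), lt = c(0L, 1L, 0L), lp = c(0L, 0L, 1L), lo = c(0L, 1L, 1L),
  rf = c(1L, 0L, 0L), rt = c(1L, 1L, 0L), rp = c(1L, 0L, 1L), ro = c(1L, 1L, 1L)
)

#' Generate a synthetic subject volume with known regional complexity
#'
#' Builds a DK-coded label volume plus left/right "ribbon" masks for one
#' synthetic subject: eight non-overlapping 24^3 lobar compartments (left
#' and right of a mid-sagittal split, lobes in fixed octants) are filled with
#' fractal-percolation phantoms whose retention is chosen, via the frozen
#' generator calibration, so the measured FD tracks the subject's target
#' regional FD. Foreground voxels of each compartment are assigned the
#' lobe's DK label codes cyclically, so exactly the 58 lobe-assigned codes
#' occur. Hemisphere masks are the unions of each side's compartments.
#'
#' @param targets Named numeric vector of target (measured-scale) FDs for the
#'   eight lobar regions `lf, rf, lt, rt, lp, rp, lo, ro`.
#' @param grid_size Volume edge in voxels (>= 48).
#' @param seed Integer seed; each compartment draws from a deterministic
#'   sub-seed so any subject is regenerable in isolation.
#' @param mirror If `TRUE`, right-side compartments are x-mirrored copies of
#'   the left side (targets for right regions are ignored), giving an exactly
#'   symmetric subject for asymmetry validation.
#' @return List with `labels` ([label_volume()]), `ribbon_left`,
#'   `ribbon_right` ([binary_mask()]s), `targets`, and `theoretical_dims`.
#' @export
generate_subject_volume <- function(targets, grid_size = 48, seed = 1L,
                                    mirror = FALSE) {
  lobar <- c("lf", "rf", "lt", "rt", "lp", "rp", "lo", "ro")
  if (!all(lobar %in% names(targets)))
    cfd_stop(sprintf("targets must name all of: %s", paste(lobar, collapse = ", ")),
             "argument_error")
  if (grid_size < 2 * COMPARTMENT_EDGE)
    cfd_stop(sprintf("grid_size must be >= %d to host the compartments",
                     2 * COMPARTMENT_EDGE), "geometry_error")
  half <- grid_size %/% 2L
  off_in <- (half - COMPARTMENT_EDGE) %/% 2L  # centre compartments in octants
  dims <- setNames(target_to_dimension(as.numeric(targets[lobar])), lobar)

  grid <- array(0L, rep(grid_size, 3L))
  gen_one <- function(code, sub_seed) {
    set.seed(sub_seed)
    for (i in 1:25) {
      g <- percolation_grid(COMPARTMENT_MS, COMPARTMENT_MS^(dims[[code]] - 3))
      if (sum(g) >= 8L) return(g)
    }
    cfd_stop(sprintf("compartment %s: percolation extinct", code),
             "percolation_extinct")
  }
  place <- function(code, g) {
    oct <- COMPARTMENT_LAYOUT[[code]]
    ox <- oct[1] * half + off_in; oy <- oct[2] * half + off_in
    oz <- oct[3] * half + off_in
    lb <- labels_for_region(
      c(f = "frontal", t = "temporal", p = "parietal", o = "occipital")[[substr(code, 2, 2)]],
      if (substr(code, 1, 1) == "l") "left" else "right")
    w <- which(g, arr.ind = TRUE)
    codes <- lb[((seq_len(nrow(w)) - 1L) %% length(lb)) + 1L]
    grid[cbind(w[, 1] + ox, w[, 2] + oy, w[, 3] + oz)] <<- codes
  }
  base_seed <- (as.integer(seed) %% 1000000L) * 131L # keep sub-seeds in int range
  left <- c("lf", "lt", "lp", "lo")
  for (i in seq_along(left))
    place(left[i], gen_one(left[i], base_seed + i))
  right <- sub("^l", "r", left)
  if (mirror) {
    ## reflect the finished left half onto the right and relabel (+1000)
    lx <- seq_len(half)
    leftg <- grid[lx, , , drop = FALSE]
    mir <- leftg[rev(seq_len(half)), , , drop = FALSE]
    mir[mir > 0L] <- mir[mir > 0L] + 1000L
    grid[half + lx, , ] <- mir
  } else {
    for (i in seq_along(right))
      place(right[i], gen_one(right[i], base_seed + 64L + i))
  }

  labels <- label_volume(grid)
  ribbon <- function(side) {
    rng <- if (side == "left") seq_len(half) else (half + 1L):grid_size
    g <- array(FALSE, dim(grid))
    g[rng, , ] <- grid[rng, , ] > 0L
    binary_mask(g)
  }
  list(labels = labels, ribbon_left = ribbon("left"),
       ribbon_right = ribbon("right"),
       targets = targets[lobar], theoretical_dims = dims)
}
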