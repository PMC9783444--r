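#' Create a 3D binary mask
#'
#' Wraps a 3D logical (or numeric, binarized as nonzero) array together with
#' voxel geometry metadata. All FD operations in the package consume this
#' class. Voxel size is metadata only: box edges are measured in voxels, as
#' appropriate for 1 mm isotropic conformed volumes; a warning is issued for
#' anisotropic voxels.
#'
#' @param grid 3D array; logical, or numeric/integer binarized as nonzero.
#' @param voxel_size_mm Numeric length-3 voxel edge lengths in mm.
#' @return An object of class `binary_mask` with elements `grid` (logical
#'   array), `shape`, `voxel_size_mm`.
#' @export
#' @examples
#' m <- binary_mask(array(TRUE, c(4, 4, 4)))
#' count_filled_boxes(m, 2)
binary_mask <- function(grid, voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(grid)) != 3L)
    cfd_stop(sprintf("mask grid must be 3D, got %d dims", length(dim(grid))),
             "geometry_error")
  if (!is.logical(grid)) {
    g <- grid != 0
    dim(g) <- dim(grid)
    grid <- g
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    cfd_stop("voxel_size_mm must be three positive numbers", "argument_error")
  if (max(voxel_size_mm) - min(voxel_size_mm) > 1e-6)
    cfd_warn("anisotropic voxels: box edges are counted in voxel units",
             "anisotropic_voxels")
  structure(
    list(grid = grid, shape = dim(grid), voxel_size_mm = voxel_size_mm),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(x$shape, collapse = "x"), sum(x$grid)))
  invisible(x)
}

## 0-based foreground voxel coordinates relative to the tight bounding box.
## Anchoring the counting grid here makes N(r) translation invariant.
mask_bbox_coords <- function(mask) {
  w <- which(mask$grid, arr.ind = TRUE)
  if (nrow(w) == 0L)
    cfd_stop("mask has no foreground voxels (degenerate region)", "empty_mask")
  sweep(w, 2L, apply(w, 2L, min))
}

#' Count filled boxes at one box edge length
#'
#' Overlays a fixed grid of non-overlapping r x r x r boxes, anchored at the
#' minimal corner of the foreground bounding box, and counts boxes containing
#' at least one foreground voxel. Partial boxes at the far boundary count:
#' every foreground voxel belongs to some box.
#'
#' @param mask A [binary_mask()] with at least one foreground voxel.
#' @param r Integer box edge length in voxels (at least 1).
#' @return Integer count N(r) of occupied boxes.
#' @export
#' @examples
#' m <- binary_mask(array(TRUE, c(5, 5, 5)))
#' count_filled_boxes(m, 2) # 27: ceil(5/2)^3, partial boxes participate
count_filled_boxes <- function(mask, r) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  if (length(r) != 1L || !is.finite(r) || r < 1 || r != round(r))
    cfd_stop("r must be a single integer >= 1", "argument_error")
  w <- mask_bbox_coords(mask)
  b <- w %/% r
  ## encode (bx, by, bz) as one number; box indices are small so doubles are exact
  nx <- max(b[, 1]) + 1
  ny <- max(b[, 2]) + 1
  key <- b[, 1] + nx * (b[, 2] + ny * b[, 3])
  length(unique(key))
}

#' Box-counting curve over a linear range of box sizes
#'
#' Evaluates N(r) for every integer r from `r_min` to `r_max` (step one
#' voxel). The linear r grid is deliberately non-equally spaced on a log
#' scale; [estimate_fd()] fits it as-is.
#'
#' @param mask A [binary_mask()].
#' @param r_min,r_max Integer window bounds, `2 <= r_min < r_max`.
#' @return A `box_count_curve`: data frame with columns `r`, `n_boxes`,
#'   `log_r`, `log_n` (natural logs).
#' @export
#' @examples
#' box_count_curve(binary_mask(array(TRUE, c(8, 8, 8))), 2, 4)
box_count_curve <- function(mask, r_min, r_max) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  if (r_min < 2 || r_max <= r_min)
    cfd_stop("need 2 <= r_min < r_max", "argument_error")
  rr <- seq.int(r_min, r_max)
  n <- vapply(rr, function(r) count_filled_boxes(mask, r), numeric(1))
  structure(
    data.frame(r = rr, n_boxes = n, log_r = log(rr), log_n = log(n)),
    class = c("box_count_curve", "data.frame")
  )
}

#' Estimate the fractal dimension from a box-counting curve
#'
#' Ordinary least-squares fit of log N(r) on log r, all points equally
#' weighted; FD is the magnitude of the slope. Points with a linear r grid
#' are non-equally spaced in log and are fitted as such (no resampling).
#'
#' @param curve A `box_count_curve` (or data frame with columns `r`,
#'   `n_boxes`) with at least two rows and all counts >= 1.
#' @return An `fd_estimate`: list with `fd`, `intercept`, `r_squared`,
#'   `r_min`, `r_max`, `n_points`, and `flags` (character vector; may contain
#'   `"fd_out_of_range"` when fd is outside (0, 3] and `"flat_tail"` when the
#'   three or more final counts are identical, a sign that r exceeded the
#'   structure size).
#' @export
#' @examples
#' cv <- data.frame(r = c(2, 4), n_boxes = c(64, 8))
#' estimate_fd(cv)$fd # exactly 3
estimate_fd <- function(curve) {
  if (!all(c("r", "n_boxes") %in% names(curve)))
    cfd_stop("curve needs columns r and n_boxes", "argument_error")
  if (nrow(curve) < 2L)
    cfd_stop("need at least two (r, N(r)) points to fit", "degenerate_curve")
  if (any(curve$n_boxes < 1))
    cfd_stop("log N(r) undefined: some counts are zero", "degenerate_curve")
  lx <- log(curve$r)
  ly <- log(curve$n_boxes)
  fit <- lm(ly ~ lx)
  slope <- unname(coef(fit)[2L])
  r2 <- if (var(ly) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  flags <- character(0)
  fd <- abs(slope)
  if (!(fd > 0 && fd <= 3)) flags <- c(flags, "fd_out_of_range")
  tail_n <- curve$n_boxes[nrow(curve)]
  run <- sum(rev(curve$n_boxes) == tail_n & !cumsum(rev(curve$n_boxes) != tail_n))
  if (run >= 3L) flags <- c(flags, "flat_tail")
  structure(
    list(fd = fd, intercept = unname(coef(fit)[1L]), r_squared = r2,
         r_min = min(curve$r), r_max = max(curve$r),
         n_points = nrow(curve), flags = flags),
    class = "fd_estimate"
  )
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate> fd = %.4f (R^2 = %.4f, r = %d..%d, %d points)%s\n",
              x$fd, x$r_squared, x$r_min, x$r_max, x$n_points,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Fractal dimension with the standard window for a region class
#'
#' Hemisphere cortical ribbons use box edges r = 2..30 voxels; lobar masks
#' use r = 2..14 voxels. The window used is recorded in the returned
#' estimate.
#'
#' @param mask A [binary_mask()].
#' @param region_class `"hemisphere"` or `"lobe"`.
#' @return An `fd_estimate` (see [estimate_fd()]).
#' @export
region_fd <- function(mask, region_class = c("hemisphere", "lobe")) {
  region_class <- match.arg(region_class)
  win <- if (region_class == "hemisphere") c(2L, 30L) else c(2L, 14L)
  estimate_fd(box_count_curve(mask, win[1], win[2]))
}

#' Export a box-counting curve as CSV
#'
#' @param curve A `box_count_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
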