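#' Generate a 3D fractal phantom with known box dimension
#'
#' Builds validation phantoms for the box-counting estimator:
#' * `solid_cube`: filled `size^3` cube, dimension 3;
#' * `slab`: one-voxel-thick `size x size x 1` sheet, dimension 2;
#' * `line`: one-voxel-thick straight segment of `size` voxels, dimension 1;
#' * `menger_sponge`: deterministic sponge of the given `level` on a
#'   `3^level` grid, box dimension log(20)/log(3);
#' * `fractal_percolation`: Mandelbrot percolation -- recursive subdivision
#'   into `m^3` subcells, each retained independently with probability `p`,
#'   down to `level` generations (grid `m^level`); box dimension
#'   `log(m^3 p)/log(m)` conditional on non-extinction. Extinct (empty)
#'   draws are regenerated up to `max_retries` times.
#'
#' @param kind Phantom kind (see above).
#' @param level Recursion depth for `menger_sponge`/`fractal_percolation`.
#' @param m Subdivision factor for `fractal_percolation` (>= 2; the Menger
#'   sponge is the deterministic m = 3 construction).
#' @param retention_p Retention probability in (0, 1] for
#'   `fractal_percolation`; `m^3 * p > 1` is required for a non-degenerate
#'   dimension.
#' @param size Edge length for `solid_cube`/`slab`/`line`.
#' @param seed Integer seed for `fractal_percolation` (other kinds are
#'   deterministic).
#' @param max_retries Regeneration cap for extinct percolation draws.
#' @return A [binary_mask()] with attribute `theoretical_dimension`.
#' @export
#' @examples
#' sum(make_phantom("menger_sponge", level = 1)$grid) # 20
make_phantom <- function(kind = c("solid_cube", "slab", "line", "menger_sponge",
                                  "fractal_percolation"),
                         level = 3, m = 3, retention_p = NULL, size = 64,
                         seed = NULL, max_retries = 25L) {
  kind <- match.arg(kind)
  mk <- function(grid, d) {
    msk <- binary_mask(grid)
    attr(msk, "theoretical_dimension") <- d
    msk
  }
  switch(kind,
    solid_cube = mk(array(TRUE, c(size, size, size)), 3),
    slab = mk(array(TRUE, c(size, size, 1)), 2),
    line = mk(array(TRUE, c(size, 1, 1)), 1),
    menger_sponge = mk(menger_grid(level), log(20) / log(3)),
    fractal_percolation = {
      if (is.null(retention_p) || retention_p <= 0 || retention_p > 1)
        cfd_stop("retention_p must be in (0, 1]", "argument_error")
      if (m < 2 || m != round(m))
        cfd_stop("m must be an integer >= 2", "argument_error")
      if (m^3 * retention_p <= 1)
        cfd_warn("m^3 * p <= 1: percolation is subcritical (almost-sure extinction)",
                 "subcritical_percolation")
      if (!is.null(seed)) set.seed(seed)
      g <- NULL
      for (i in seq_len(max_retries)) {
        cand <- percolation_grid(rep.int(as.integer(m), level), retention_p)
        if (sum(cand) >= 2L) { g <- cand; break }
      }
      if (is.null(g))
        cfd_stop(sprintf("percolation extinct in %d attempts (m=%d, p=%.3f, level=%d)",
                         max_retries, m, retention_p, level), "percolation_extinct")
      mk(g, 3 + log(retention_p) / log(m))
    }
  )
}

## Menger sponge on a 3^level grid: a voxel survives iff at no scale do two
## or more of its base-3 digits equal 1.
menger_grid <- function(level) {
  if (level < 1 || level != round(level))
    cfd_stop("level must be an integer >= 1", "argument_error")
  s <- 3L^level
  keep <- array(TRUE, c(s, s, s))
  idx <- 0:(s - 1L)
  for (l in seq_len(level)) {
    di <- ((idx %/% 3L^(l - 1L)) %% 3L) == 1L
    ax <- array(di, c(s, s, s))                # varies along x
    ay <- aperm(ax, c(2L, 1L, 3L))             # along y
    az <- aperm(ax, c(3L, 2L, 1L))             # along z
    keep <- keep & ((ax + ay + az) < 2L)
  }
  keep
}

## Recursive-subdivision percolation supporting a different subdivision
## factor per generation (ms = vector of factors). Per-generation retention
## may be scalar (classical) or per-generation. Grid size prod(ms).
percolation_grid <- function(ms, p) {
  if (length(p) == 1L) p <- rep(p, length(ms))
  g <- array(TRUE, c(1L, 1L, 1L))
  for (i in seq_along(ms)) {
    m <- ms[i]
    s <- dim(g)[1L] * m
    parent <- rep(seq_len(s / m), each = m)
    g <- g[parent, parent, parent] & array(runif(s^3) < p[i], c(s, s, s))
  }
  g
}
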