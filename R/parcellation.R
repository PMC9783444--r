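## Desikan-Killiany volumetric label codes grouped by lobe (left hemisphere;
## right = left + 1000). The grouping covers 29 of the 34 DK regions: the
## insula and the four cingulate regions belong to no lobe here and are
## excluded from lobar masks (they still count toward hemisphere label
## unions). A CSV copy ships in inst/extdata/dk_lobe_labels.csv so alternate
## groupings can be supplied.
DK_LOBE_LEFT <- list(
  frontal   = c(1003L, 1012L, 1014L, 1017L, 1018L, 1019L, 1020L, 1024L,
                1027L, 1028L, 1032L),
  temporal  = c(1001L, 1006L, 1007L, 1009L, 1015L, 1016L, 1030L, 1033L, 1034L),
  parietal  = c(1008L, 1022L, 1025L, 1029L, 1031L),
  occipital = c(1005L, 1011L, 1013L, 1021L)
)

#' DK label codes for a lobe and hemisphere
#'
#' Returns the volumetric Desikan-Killiany label codes making up one lobe.
#' Left-hemisphere cortical labels run 1001-1035 and right-hemisphere labels
#' are the same codes plus 1000. The insula and cingulate regions are not
#' assigned to any lobe.
#'
#' @param lobe One of `"frontal"`, `"temporal"`, `"parietal"`, `"occipital"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return Integer vector of label codes.
#' @export
#' @examples
#' labels_for_region("occipital", "left") # 1005 1011 1013 1021
labels_for_region <- function(lobe, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (length(lobe) != 1L || !lobe %in% names(DK_LOBE_LEFT))
    cfd_stop(sprintf("unknown lobe '%s'", paste(lobe, collapse = ",")),
             "argument_error")
  left <- DK_LOBE_LEFT[[lobe]]
  if (hemisphere == "left") left else left + 1000L
}

## all lobe-assigned labels for one side
hemisphere_lobe_labels <- function(hemisphere) {
  unlist(lapply(names(DK_LOBE_LEFT), labels_for_region, hemisphere = hemisphere),
         use.names = FALSE)
}

#' All cortical DK labels for one hemisphere
#'
#' The full 1001-1035 (left) or 2001-2035 (right) code range, used when a
#' hemisphere mask must be derived from a label volume because no ribbon
#' volume is available.
#'
#' @param hemisphere `"left"` or `"right"`.
#' @return Integer vector of 35 label codes.
#' @export
hemisphere_all_labels <- function(hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  base <- 1001:1035
  if (hemisphere == "left") base else base + 1000L
}

#' Create a label volume
#'
#' @param grid 3D integer array of anatomical label codes (0 = background).
#' @param voxel_size_mm Numeric length-3 voxel size, metadata only.
#' @param label_space Tag describing the coding; default assumes the DK
#'   1000/2000 convention of aparc-style volumes.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, voxel_size_mm = c(1, 1, 1),
                         label_space = "dk_aparc_1000_2000") {
  if (length(dim(grid)) != 3L)
    cfd_stop("label grid must be 3D", "geometry_error")
  storage.mode(grid) <- "integer"
  if (any(grid < 0L, na.rm = TRUE))
    cfd_stop("labels must be non-negative integers", "argument_error")
  structure(
    list(grid = grid, shape = dim(grid),
         voxel_size_mm = as.numeric(voxel_size_mm), label_space = label_space),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d labelled (%s)\n",
              paste(x$shape, collapse = "x"), sum(x$grid != 0L), x$label_space))
  invisible(x)
}

#' Binary mask of the voxels carrying any of a set of labels
#'
#' @param labels A [label_volume()].
#' @param label_set Non-empty integer vector of label codes.
#' @return A [binary_mask()] with the same geometry metadata.
#' @export
region_mask <- function(labels, label_set) {
  if (!inherits(labels, "label_volume"))
    cfd_stop("labels must be a label_volume", "argument_error")
  if (length(label_set) == 0L)
    cfd_stop("label_set is empty", "argument_error")
  g <- labels$grid %in% as.integer(label_set)
  dim(g) <- labels$shape
  if (!any(g))
    cfd_stop(sprintf("no voxel carries any of labels {%s}",
                     paste(sort(unique(as.integer(label_set))), collapse = ", ")),
             "empty_mask")
  binary_mask(g, voxel_size_mm = labels$voxel_size_mm)
}

#' Per-subject FD extraction: two hemispheres and eight lobes
#'
#' Computes the ten regional FD values for one subject: left/right hemisphere
#' FD on the supplied cortical ribbon masks (box window r = 2..30) and the
#' eight lobar FDs on masks derived from the DK label volume (r = 2..14).
#' When ribbon masks are not supplied the hemisphere masks fall back to the
#' union of all cortical labels of that side, which is recorded in the
#' result's `provenance`.
#'
#' @param ribbon_left,ribbon_right [binary_mask()] cortical ribbons, or
#'   `NULL` to derive hemispheres from `labels`.
#' @param labels A [label_volume()] with DK 1000/2000 coding.
#' @return A `subject_fd` list: `values` (named numeric, NA where a region is
#'   missing), `estimates` (named list of `fd_estimate`s), `missing`
#'   (character vector of region codes), `provenance`.
#' @export
subject_fd_table <- function(ribbon_left = NULL, ribbon_right = NULL, labels) {
  if (!inherits(labels, "label_volume"))
    cfd_stop("labels must be a label_volume", "argument_error")
  shapes <- list(labels$shape)
  for (rb in list(ribbon_left, ribbon_right))
    if (!is.null(rb)) shapes <- c(shapes, list(rb$shape))
  if (length(unique(lapply(shapes, as.integer))) != 1L)
    cfd_stop("ribbon and label volumes must share one shape", "geometry_error")

  provenance <- "hemispheres from ribbon masks"
  if (is.null(ribbon_left) || is.null(ribbon_right)) {
    provenance <- "hemispheres from union of cortical labels (no ribbon supplied)"
    ribbon_left  <- try(region_mask(labels, hemisphere_all_labels("left")), silent = TRUE)
    ribbon_right <- try(region_mask(labels, hemisphere_all_labels("right")), silent = TRUE)
  }

  vals <- setNames(rep(NA_real_, length(FD_REGIONS)), FD_REGIONS)
  ests <- setNames(vector("list", length(FD_REGIONS)), FD_REGIONS)
  one <- function(mask_or_try, class) {
    if (inherits(mask_or_try, "try-error")) return(NULL)
    tryCatch(region_fd(mask_or_try, class),
             corticalfd_empty_mask = function(e) NULL,
             corticalfd_degenerate_curve = function(e) NULL)
  }
  ests$lh <- one(ribbon_left, "hemisphere")
  ests$rh <- one(ribbon_right, "hemisphere")
  lobe_of <- c(f = "frontal", t = "temporal", p = "parietal", o = "occipital")
  for (code in c("lf", "rf", "lt", "rt", "lp", "rp", "lo", "ro")) {
    side <- if (substr(code, 1, 1) == "l") "left" else "right"
    lb <- labels_for_region(lobe_of[[substr(code, 2, 2)]], side)
    msk <- tryCatch(region_mask(labels, lb),
                    corticalfd_empty_mask = function(e) NULL)
    ests[[code]] <- if (is.null(msk)) NULL else one(msk, "lobe")
  }
  for (code in FD_REGIONS)
    if (!is.null(ests[[code]])) vals[[code]] <- ests[[code]]$fd
  structure(
    list(values = vals, estimates = ests,
         missing = FD_REGIONS[is.na(vals)], provenance = provenance),
    class = "subject_fd"
  )
}

#' @export
print.subject_fd <- function(x, ...) {
  cat("<subject_fd>\n")
  print(round(x$values, 4))
  if (length(x$missing)) cat("missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
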