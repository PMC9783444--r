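#' Read a 3D volume (NIfTI or FreeSurfer MGH/MGZ)
#'
#' Loads `.nii`/`.nii.gz` through RNifti and `.mgh`/`.mgz` through a built-in
#' reader for the FreeSurfer MGH format (big-endian; MGZ is the gzip-wrapped
#' variant). Only 3D (or trivially 3D, single-frame) volumes are accepted.
#'
#' @param path Path to the volume.
#' @param as `"labels"` for a [label_volume()], `"mask"` for a
#'   [binary_mask()] (nonzero = foreground), or `"auto"` (default): integer
#'   data with values outside \{0, 1\} become labels, anything else a mask.
#' @return A [label_volume()] or [binary_mask()].
#' @export
read_volume <- function(path, as = c("auto", "labels", "mask")) {
  as <- match.arg(as)
  if (!file.exists(path))
    cfd_stop(sprintf("no such file: %s", path), "io_error")
  ext <- tolower(path)
  if (grepl("\\.(mgh|mgz)$", ext)) {
    v <- read_mgh(path)
    arr <- v$data; vox <- v$voxel_size
  } else if (grepl("\\.nii(\\.gz)?$", ext)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    vox <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(arr))))]
  } else {
    cfd_stop(sprintf("unrecognised volume format: %s (want .nii[.gz], .mgh, .mgz)",
                     path), "format_error")
  }
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) { dim(arr) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3L)
    cfd_stop(sprintf("%s: expected a 3D volume but dim field is (%s)",
                     path, paste(d, collapse = ", ")), "format_error")
  if (length(vox) < 3L || any(!is.finite(vox)) || any(vox <= 0)) vox <- c(1, 1, 1)
  is_int <- all(arr == round(arr), na.rm = TRUE)
  if (as == "labels" || (as == "auto" && is_int && any(arr > 1))) {
    label_volume(array(as.integer(round(arr)), d), voxel_size_mm = vox)
  } else {
    binary_mask(arr != 0, voxel_size_mm = vox)
  }
}

#' Write a volume as NIfTI or MGH/MGZ
#'
#' @param volume A [label_volume()] or [binary_mask()].
#' @param path Output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mgh`, `.mgz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "binary_mask")) {
    arr <- array(as.integer(volume$grid), volume$shape)
  } else if (inherits(volume, "label_volume")) {
    arr <- volume$grid
  } else cfd_stop("volume must be a binary_mask or label_volume", "argument_error")
  ext <- tolower(path)
  if (grepl("\\.(mgh|mgz)$", ext)) {
    write_mgh(arr, path, voxel_size = volume$voxel_size_mm)
  } else if (grepl("\\.nii(\\.gz)?$", ext)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- volume$voxel_size_mm
    RNifti::writeNifti(img, path)
  } else cfd_stop(sprintf("unrecognised output format: %s", path), "format_error")
  invisible(path)
}

## --- minimal MGH/MGZ codec -------------------------------------------------
## MGH layout (big-endian): int32 version, width, height, depth, nframes,
## type (0 uchar, 1 int32, 3 float32, 4 int16), int32 dof, int16 goodRASFlag,
## then (if goodRASFlag > 0) 3x float32 spacing, 9x float32 direction cosines,
## 3x float32 centre; header padded to 284 bytes, data follows.
MGH_HEADER_BYTES <- 284L

read_mgh <- function(path) {
  con <- gzfile(path, "rb") # transparently handles both plain mgh and gzipped mgz
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 7L, size = 4L, endian = "big")
  names(ints) <- c("version", "width", "height", "depth", "nframes", "type", "dof")
  if (is.na(ints["version"]) || ints["version"] != 1L)
    cfd_stop(sprintf("%s: MGH version field is %s, expected 1", path,
                     ints["version"]), "format_error")
  if (ints["nframes"] > 1L)
    cfd_stop(sprintf("%s: nframes field is %d; only 3D single-frame volumes supported",
                     path, ints["nframes"]), "format_error")
  good_ras <- readBin(con, "integer", n = 1L, size = 2L, endian = "big")
  vox <- c(1, 1, 1)
  if (!is.na(good_ras) && good_ras > 0L)
    vox <- readBin(con, "double", n = 3L, size = 4L, endian = "big")
  ## skip to the data section
  consumed <- 7L * 4L + 2L + if (!is.na(good_ras) && good_ras > 0L) 60L else 0L
  readBin(con, "raw", n = MGH_HEADER_BYTES - consumed +
            if (!is.na(good_ras) && good_ras > 0L) 48L else 0L) # Mdc/centre + pad
  nvox <- prod(ints[c("width", "height", "depth")])
  data <- switch(as.character(ints["type"]),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L,
                             signed = FALSE, endian = "big")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 4L, endian = "big")),
    "3" = readBin(con, "double", n = nvox, size = 4L, endian = "big"),
    "4" = as.numeric(readBin(con, "integer", n = nvox, size = 2L, endian = "big")),
    cfd_stop(sprintf("%s: unsupported MGH data type field %d", path, ints["type"]),
             "format_error")
  )
  if (length(data) != nvox)
    cfd_stop(sprintf("%s: truncated data section", path), "format_error")
  list(data = array(data, unname(ints[c("width", "height", "depth")])),
       voxel_size = vox)
}

write_mgh <- function(arr, path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(arr)) == 3L)
  con <- if (grepl("\\.mgz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(1L, dim(arr), 1L, 1L, 0L)), con, size = 4L, endian = "big")
  writeBin(1L, con, size = 2L, endian = "big") # goodRASFlag
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "big")
  mdc <- c(-1, 0, 0, 0, 0, -1, 0, 1, 0) # conformed LIA orientation
  writeBin(as.numeric(mdc), con, size = 4L, endian = "big")
  writeBin(numeric(3L), con, size = 4L, endian = "big")
  pad <- MGH_HEADER_BYTES - (7L * 4L + 2L + 60L)
  writeBin(raw(pad), con)
  writeBin(as.integer(arr), con, size = 4L, endian = "big")
  invisible(path)
}
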