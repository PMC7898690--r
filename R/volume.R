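#' 3D scalar volume with units and an acquisition time stamp
#'
#' A lightweight container for co-registered volumes: a 3D numeric array
#' plus voxel size (mm), a units tag (`"s"` for T1, `"mM"` for
#' concentration, `"1/min"` for leakage rate, `""` for dimensionless
#' fractions and masks), and an optional time stamp (minutes after
#' injection start, the map's k-space-center time).
#'
#' @param voxels 3D numeric or logical array.
#' @param voxel_size Length-3 positive voxel dimensions (mm).
#' @param units Units tag string.
#' @param timestamp Optional acquisition time (min).
#' @return An object of class `volume_image` (the array, with attributes).
#' @export
volume_image <- function(voxels, voxel_size = c(1, 1, 1), units = "",
                         timestamp = NULL) {
  if (is.logical(voxels)) voxels <- array(as.numeric(voxels), dim = dim(voxels))
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop("`voxels` must be a 3D array.", call. = FALSE)
  }
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive lengths (mm).", call. = FALSE)
  }
  if (!is.character(units) || length(units) != 1) {
    stop("`units` must be a single string.", call. = FALSE)
  }
  structure(voxels, voxel_size = as.numeric(voxel_size), units = units,
            timestamp = timestamp, class = c("volume_image", "array"))
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x)
  ts <- attr(x, "timestamp")
  cat(sprintf("<volume_image> %dx%dx%d voxels, %s mm, units '%s'%s\n",
              d[1], d[2], d[3],
              paste(format(attr(x, "voxel_size")), collapse = "x"),
              attr(x, "units"),
              if (is.null(ts)) "" else sprintf(", t = %g min", ts)))
  invisible(x)
}

same_grid <- function(...) {
  dims <- lapply(list(...), dim)
  all(vapply(dims, function(d) identical(d[1:3], dims[[1]][1:3]), logical(1)))
}

mask_indices <- function(mask) {
  if (is.null(mask)) stop("mask is missing.", call. = FALSE)
  idx <- which(as.logical(mask) & !is.na(mask))
  if (length(idx) == 0) stop("mask is empty.", call. = FALSE)
  idx
}

#' Write a volume to NIfTI-1
#'
#' Voxel data and voxel sizes go in the NIfTI header; units and time
#' stamps are metadata for the JSON/YAML sidecars, never encoded in
#' header intent fields.
#'
#' @param vol A [volume_image()] or plain 3D/4D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size override (mm); taken from the volume
#'   attribute when present.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = NULL) {
  vs <- voxel_size %||% attr(vol, "voxel_size") %||% c(1, 1, 1)
  arr <- unclass(vol)
  attributes(arr) <- list(dim = dim(vol))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param units Units tag to attach.
#' @param timestamp Optional time stamp (min) to attach.
#' @return A [volume_image()] for 3D files; a plain 4D array with a
#'   `voxel_size` attribute for 4D files.
#' @export
read_volume <- function(path, units = "", timestamp = NULL) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3) {
    volume_image(arr, voxel_size = vs, units = units, timestamp = timestamp)
  } else {
    attr(arr, "voxel_size") <- vs
    arr
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
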