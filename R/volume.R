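#' 3D scalar volume with voxel spacing
#'
#' A minimal container for the observed image: a 3D numeric array of
#' intensities plus the physical voxel size in mm per axis. All segmentation
#' functions accept either a `volume_grid` or a plain array together with a
#' `spacing_mm` argument.
#'
#' @param intensities 3D numeric array, all values finite.
#' @param spacing_mm numeric length-3, strictly positive voxel size in mm.
#' @return An object of class `volume_grid`.
#' @examples
#' v <- volume_grid(array(0, c(8, 8, 8)), spacing_mm = c(0.86, 0.86, 1))
#' dim(v$intensities)
#' @export
volume_grid <- function(intensities, spacing_mm = c(0.86, 0.86, 1)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 strictly positive numbers", call. = FALSE)
  }
  structure(list(intensities = intensities, spacing_mm = spacing_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$intensities), collapse = " x "),
      " voxels, spacing ", paste(x$spacing_mm, collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

as_volume_grid <- function(image, spacing_mm = c(0.86, 0.86, 1)) {
  if (inherits(image, "volume_grid")) image else volume_grid(image, spacing_mm)
}

#' Read / write volumes and masks as NIfTI
#'
#' Thin wrappers around RNifti that carry the voxel spacing in the header.
#' `write_mask()` stores a logical array as 0/1 integers; `read_mask()`
#' returns it as a logical array.
#'
#' @param x a `volume_grid` (or plain array for masks).
#' @param path file path, typically ending in `.nii.gz`.
#' @param spacing_mm voxel spacing written to the header for plain arrays.
#' @return `read_volume()` a `volume_grid`; `read_mask()` a logical array;
#'   the writers return `path` invisibly.
#' @export
write_volume <- function(x, path, spacing_mm = c(0.86, 0.86, 1)) {
  if (inherits(x, "volume_grid")) {
    arr <- x$intensities
    spacing_mm <- x$spacing_mm
  } else {
    arr <- x
  }
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- spacing_mm[seq_along(dim(arr))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim(img)),
              spacing_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path, spacing_mm = c(0.86, 0.86, 1)) {
  write_volume(array(as.integer(x), dim(x)), path, spacing_mm)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  arr <- v$intensities > 0.5
  attr(arr, "spacing_mm") <- v$spacing_mm
  arr
}
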