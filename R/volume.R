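#' SPECT volume and liver VOI containers
#'
#' `spect_volume()` wraps a 3D array of non-negative voxel activity values
#' (counts per voxel) together with its voxel spacing in mm. `liver_voi()`
#' wraps a 3D logical mask selecting the liver voxels on the same grid.
#' Both validate their invariants on construction.
#'
#' @param values 3D numeric array of activity values; all finite and >= 0.
#' @param spacing numeric(3), voxel edge lengths in mm.
#' @return An object of class `spect_volume` (a list with elements `values`
#'   and `spacing`).
#' @examples
#' v <- spect_volume(array(5, c(4, 4, 4)))
#' dim(v)
#' @export
spect_volume <- function(values, spacing = c(1, 1, 1)) {
  values <- as_array3d(values, "values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths (mm)")
  if (any(!is.finite(values)))
    stop("volume contains non-finite values")
  if (any(values < 0))
    stop("volume contains negative values; see load_volume() for clamping")
  structure(list(values = values, spacing = spacing),
            class = "spect_volume")
}

#' @param mask 3D array; nonzero/TRUE voxels select the liver.
#' @rdname spect_volume
#' @export
liver_voi <- function(mask) {
  mask <- as_array3d(mask, "mask")
  m <- array(mask != 0 & !is.na(mask), dim = dim(mask))
  if (!any(m))
    stop("empty VOI: the mask selects no voxels")
  structure(list(mask = m), class = "liver_voi")
}

as_array3d <- function(x, what) {
  if (inherits(x, "spect_volume")) x <- x$values
  if (inherits(x, "liver_voi")) x <- x$mask
  x <- unclass(x)
  attributes(x) <- attributes(x)["dim"]
  if (is.null(dim(x)) || length(dim(x)) != 3)
    stop(sprintf("`%s` must be a 3D array", what))
  if (any(dim(x) < 1))
    stop(sprintf("`%s` has a zero-length dimension", what))
  storage.mode(x) <- if (what == "mask") "logical" else "double"
  x
}

# Coercion used at every module boundary: plain arrays are accepted.
as_spect_volume <- function(x) {
  if (inherits(x, "spect_volume")) x else spect_volume(x)
}

as_liver_voi <- function(x, shape = NULL) {
  v <- if (inherits(x, "liver_voi")) x else liver_voi(x)
  if (!is.null(shape) && !identical(dim(v$mask), as.integer(shape)))
    stop(sprintf("VOI grid %s does not match volume grid %s",
                 paste(dim(v$mask), collapse = "x"),
                 paste(shape, collapse = "x")))
  v
}

#' @export
dim.spect_volume <- function(x) dim(x$values)

#' @export
dim.liver_voi <- function(x) dim(x$mask)

#' @export
print.spect_volume <- function(x, ...) {
  cat(sprintf("SPECT volume: %s voxels, spacing %s mm\n",
              paste(dim(x$values), collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  value range [%g, %g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.liver_voi <- function(x, ...) {
  cat(sprintf("Liver VOI: %d of %d voxels selected\n",
              sum(x$mask), length(x$mask)))
  invisible(x)
}
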