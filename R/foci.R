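#' Label and count disjoint uptake foci above a threshold
#'
#' A voxel is foreground iff it lies inside the VOI and its value is `>=
#' threshold` (inclusive, so the maximum voxel survives a threshold at
#' Cmax). Connected components of the foreground are labelled under the
#' chosen 3D connectivity; components smaller than `min_size` voxels are
#' dropped to background. The number of surviving components is the number
#' of uptake foci (NUF). Labels are assigned in deterministic scan order:
#' component ids increase with the (column-major) linear index of each
#' component's first voxel. Voxels outside the VOI never join a component,
#' even when above threshold — the VOI is a hard boundary.
#'
#' @param volume a [spect_volume()] or 3D numeric array.
#' @param voi a [liver_voi()] or 3D mask on the same grid.
#' @param threshold threshold value, counts per voxel, `>= 0`.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full 3D
#'   neighbourhood, the default: it best matches the visual merging of
#'   diagonal noise clusters).
#' @param min_size minimum component size in voxels (default 1; use 2 to
#'   require two-voxel foci).
#' @return `label_foci()`: a `foci_labeling` object with `labels` (3D
#'   integer array, 0 = background), `count` (the NUF), and the parameters
#'   used. `count_foci()`: the NUF alone.
#' @examples
#' vol <- array(0, c(3, 3, 3)); vol[1, 1, 1] <- vol[3, 3, 1] <- 10
#' count_foci(vol, array(TRUE, c(3, 3, 3)), threshold = 5)
#' @export
label_foci <- function(volume, voi, threshold, connectivity = 26,
                       min_size = 1) {
  volume <- as_spect_volume(volume)
  voi <- as_liver_voi(voi, shape = dim(volume))
  check_foci_params(threshold, connectivity, min_size)
  res <- .cc_label(as.vector(volume$values), as.vector(voi$mask),
                   dim(volume), threshold, as.integer(connectivity),
                   as.integer(min_size))
  labels <- array(res$labels, dim = dim(volume))
  structure(list(labels = labels, count = res$count, threshold = threshold,
                 connectivity = as.integer(connectivity),
                 min_size = as.integer(min_size)),
            class = "foci_labeling")
}

#' @rdname label_foci
#' @export
count_foci <- function(volume, voi, threshold, connectivity = 26,
                       min_size = 1) {
  label_foci(volume, voi, threshold, connectivity, min_size)$count
}

check_foci_params <- function(threshold, connectivity, min_size) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold < 0)
    stop("`threshold` must be a single finite value >= 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be one of 6, 18, 26")
  if (min_size < 1 || min_size != round(min_size))
    stop("`min_size` must be a positive integer")
  invisible(TRUE)
}

#' @export
print.foci_labeling <- function(x, ...) {
  cat(sprintf(
    "Foci labelling: %d focus(es) at threshold %g (connectivity %d, min size %d)\n",
    x$count, x$threshold, x$connectivity, x$min_size))
  invisible(x)
}
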