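#' Threshold index
#'
#' The threshold index maps a voxel threshold `c_thr` to
#' `ThI = (c_max - c_thr) / c_max`, where `c_max` is the maximum voxel
#' value inside the VOI: 0 at a threshold equal to the maximum, approaching
#' 1 at threshold zero.
#'
#' @param c_max maximum VOI voxel value, counts per voxel, `> 0`.
#' @param c_thr threshold, counts per voxel, in `[0, c_max]`.
#' @return ThI, dimensionless in `[0, 1]`.
#' @examples
#' threshold_index(200, 150)  # 0.25
#' @export
threshold_index <- function(c_max, c_thr) {
  if (any(c_max <= 0)) stop("`c_max` must be positive")
  if (any(c_thr < 0) || any(c_thr > c_max))
    stop("`c_thr` must lie in [0, c_max]")
  (c_max - c_thr) / c_max
}

#' Compute the nNUFTI curve for one liver
#'
#' Sweeps the voxel threshold over `grid_size` equally spaced levels
#' `c_thr(k) = k * c_max / grid_size` for `k = grid_size, ..., 1` (threshold
#' 0 excluded), counts the uptake foci at each level with [count_foci()],
#' and normalizes the counts by their maximum over the sweep (nNUF). The
#' rows are ordered by strictly increasing ThI. For a tumour-free liver the
#' curve is bell-shaped: the focus count first rises as more noise blobs
#' clear the falling threshold, then falls as foci merge; hot lesions
#' compress the curve towards higher ThI.
#'
#' @inheritParams label_foci
#' @param grid_size number of threshold levels G (default 256). A fixed
#'   grid makes curves comparable across livers.
#' @return An object of class `nnufti`: a list with `rows` (data frame with
#'   columns `threshold`, `thi`, `nuf`, `nnuf`), `c_max`, `mean_conc` (mean
#'   VOI activity concentration, counts/voxel), `grid_size`,
#'   `connectivity`, `min_size`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(16, 16, 12),
#'                                     semi_axes_mm = c(28, 24, 18),
#'                                     seed = 1))
#' cv <- nnufti(ph$volume, ph$voi, grid_size = 32)
#' cv
#' @export
nnufti <- function(volume, voi, grid_size = 256, connectivity = 26,
                   min_size = 1) {
  volume <- as_spect_volume(volume)
  voi <- as_liver_voi(voi, shape = dim(volume))
  if (grid_size < 2 || grid_size != round(grid_size))
    stop("`grid_size` must be an integer >= 2")
  check_foci_params(0, connectivity, min_size)
  vals <- volume$values[voi$mask]
  c_max <- max(vals)
  if (c_max <= 0) stop("maximum VOI voxel value must be > 0")
  grid_size <- as.integer(grid_size)
  k <- grid_size:1
  thresholds <- k * c_max / grid_size
  nuf <- .nuf_sweep(as.vector(volume$values), as.vector(voi$mask),
                    dim(volume), thresholds, as.integer(connectivity),
                    as.integer(min_size))
  rows <- data.frame(threshold = thresholds,
                     thi = threshold_index(c_max, thresholds),
                     nuf = nuf,
                     nnuf = nuf / max(nuf))
  new_nnufti_curve(rows, c_max = c_max, mean_conc = mean(vals),
                   grid_size = grid_size,
                   connectivity = as.integer(connectivity),
                   min_size = as.integer(min_size))
}

new_nnufti_curve <- function(rows, c_max, mean_conc, grid_size,
                             connectivity, min_size) {
  rownames(rows) <- NULL
  structure(list(rows = rows, c_max = c_max, mean_conc = mean_conc,
                 grid_size = grid_size, connectivity = connectivity,
                 min_size = min_size),
            class = "nnufti")
}

#' Mean activity concentration in the VOI
#'
#' Arithmetic mean of the voxel values inside the VOI, in counts per voxel.
#' The threshold index at a fixed nNUF level depends on this quantity
#' (noisier, lower-count livers reach a given normalized focus count at a
#' different ThI), which is why ThI is corrected to a reference
#' concentration downstream (see [normalize_thi()]).
#'
#' @inheritParams label_foci
#' @return mean concentration, counts per voxel.
#' @export
mean_concentration <- function(volume, voi) {
  volume <- as_spect_volume(volume)
  voi <- as_liver_voi(voi, shape = dim(volume))
  mean(volume$values[voi$mask])
}

#' Threshold index at a given nNUF level on one curve branch
#'
#' Locates the global maximum of nNUF (the first such row when tied, so the
#' right-branch scan is deterministic), then finds where the curve crosses
#' `level` on the requested side of the maximum: for `side = "right"`, the
#' first above-to-below crossing after the maximum; for `side = "left"`,
#' the last below-to-above crossing before it. The ThI of the crossing is
#' linearly interpolated between the bracketing grid rows, which reduces
#' the dependence of the result on `grid_size`.
#'
#' @param curve an [nnufti()] object.
#' @param level nNUF level in (0, 1); 0.25 is the calibrated default used
#'   for tumour detection.
#' @param side `"right"` (default) or `"left"` branch of the curve.
#' @return interpolated ThI of the crossing.
#' @examples
#' rows <- data.frame(threshold = c(8, 6, 4, 2),
#'                    thi = c(0.2, 0.4, 0.6, 0.8),
#'                    nuf = c(1, 10, 4, 1),
#'                    nnuf = c(0.1, 1, 0.4, 0.1))
#' cv <- structure(list(rows = rows, c_max = 10, mean_conc = 5,
#'                      grid_size = 4L, connectivity = 26L, min_size = 1L),
#'                 class = "nnufti")
#' thi_at_nnuf(cv, 0.25, "right")  # 0.7
#' @export
thi_at_nnuf <- function(curve, level = 0.25, side = c("right", "left")) {
  stopifnot(inherits(curve, "nnufti"))
  side <- match.arg(side)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("`level` must lie strictly between 0 and 1")
  thi <- curve$rows$thi
  nnuf <- curve$rows$nnuf
  peak <- which.max(nnuf)  # first max when tied
  n <- length(nnuf)
  if (side == "right") {
    if (peak < n) {
      for (i in peak:(n - 1)) {
        if (nnuf[i] >= level && nnuf[i + 1] < level) {
          frac <- (nnuf[i] - level) / (nnuf[i] - nnuf[i + 1])
          return(thi[i] + frac * (thi[i + 1] - thi[i]))
        }
      }
    }
  } else {
    if (peak > 1) {
      for (i in (peak - 1):1) {
        if (nnuf[i] < level && nnuf[i + 1] >= level) {
          frac <- (level - nnuf[i]) / (nnuf[i + 1] - nnuf[i])
          return(thi[i] + frac * (thi[i + 1] - thi[i]))
        }
      }
    }
  }
  reach <- if (side == "right") min(nnuf[peak:n]) else min(nnuf[1:peak])
  stop(sprintf(
    "no nNUF = %g crossing on the %s branch (minimum nNUF reached: %g)",
    level, side, reach), call. = FALSE)
}

#' @export
print.nnufti <- function(x, ...) {
  cat(sprintf("nNUFTI curve: %d threshold levels, connectivity %d, min size %d\n",
              nrow(x$rows), x$connectivity, x$min_size))
  cat(sprintf("  Cmax %.4g counts/voxel, mean concentration %.4g counts/voxel\n",
              x$c_max, x$mean_conc))
  cat(sprintf("  max NUF %d at ThI %.4g\n",
              max(x$rows$nuf), x$rows$thi[which.max(x$rows$nnuf)]))
  invisible(x)
}

#' @export
summary.nnufti <- function(object, level = 0.25, ...) {
  right <- tryCatch(thi_at_nnuf(object, level, "right"), error = function(e) NA_real_)
  left <- tryCatch(thi_at_nnuf(object, level, "left"), error = function(e) NA_real_)
  out <- list(c_max = object$c_max, mean_conc = object$mean_conc,
              grid_size = object$grid_size, max_nuf = max(object$rows$nuf),
              peak_thi = object$rows$thi[which.max(object$rows$nnuf)],
              level = level, thi_right = right, thi_left = left)
  class(out) <- "summary.nnufti"
  out
}

#' @export
print.summary.nnufti <- function(x, ...) {
  cat("nNUFTI curve summary\n")
  cat(sprintf("  Cmax:                 %.6g counts/voxel\n", x$c_max))
  cat(sprintf("  mean concentration:   %.6g counts/voxel\n", x$mean_conc))
  cat(sprintf("  threshold levels:     %d\n", x$grid_size))
  cat(sprintf("  max NUF:              %d (at ThI %.4g)\n", x$max_nuf, x$peak_thi))
  cat(sprintf("  ThI at nNUF = %.3g:   right %.4g, left %.4g\n",
              x$level, x$thi_right, x$thi_left))
  invisible(x)
}

#' @export
as.data.frame.nnufti <- function(x, ...) x$rows

#' @param y unused.
#' @rdname nnufti
#' @export
plot.nnufti <- function(x, y, ...) {
  graphics::plot(x$rows$thi, x$rows$nnuf, type = "l",
                 xlab = "threshold index (ThI)",
                 ylab = "normalized number of uptake foci (nNUF)", ...)
  invisible(x)
}
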