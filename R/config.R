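#' Pipeline run configuration
#'
#' Collects every tunable of the analysis pipeline with its calibrated
#' default: connectivity 26, minimum focus size 1 voxel, 256 threshold
#' levels, nNUF level 0.25 read on the right curve branch, reference mean
#' concentration 60 counts/voxel, decision-band edges 0.64 and 0.70. The
#' command-line tools serialize the active configuration (JSON) alongside
#' every output so results are self-describing.
#'
#' @param connectivity,min_size,grid_size see [nnufti()].
#' @param nnuf_level,side see [thi_at_nnuf()].
#' @param m_ref see [fit_concentration_model()].
#' @param band_edges see [assign_band()].
#' @param seed RNG seed for phantom generation.
#' @param verbose print progress messages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(connectivity = 26, min_size = 1, grid_size = 256,
                       nnuf_level = 0.25, side = "right", m_ref = 60,
                       band_edges = c(0.64, 0.70), seed = 1,
                       verbose = FALSE) {
  check_foci_params(0, connectivity, min_size)
  side <- match.arg(side, c("right", "left"))
  if (nnuf_level <= 0 || nnuf_level >= 1)
    stop("`nnuf_level` must lie strictly between 0 and 1")
  structure(list(connectivity = as.integer(connectivity),
                 min_size = as.integer(min_size),
                 grid_size = as.integer(grid_size),
                 nnuf_level = nnuf_level, side = side, m_ref = m_ref,
                 band_edges = as.numeric(band_edges),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @param config,path `write_config()` stores the configuration as JSON.
#' @rdname run_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-12s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
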