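#' Read and write volumes and masks (NIfTI-1)
#'
#' `load_volume()` reads a 3D scalar NIfTI-1 image into a [spect_volume()].
#' Strictly negative voxels — float noise that iterative reconstruction can
#' leave in an otherwise non-negative volume — are clamped to 0, with a
#' warning reporting how many were affected. `load_mask()` reads a mask on
#' the same grid; any nonzero voxel is treated as inside the VOI.
#' `save_volume()` writes a volume (or a plain 3D array) back to NIfTI-1.
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return `load_volume()`: a [spect_volume()]; `load_mask()`: a
#'   [liver_voi()].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' save_volume(array(5, c(4, 4, 4)), f)
#' v <- load_volume(f)
#' range(v$values)
#' @export
load_volume <- function(path) {
  img <- read_nifti3d(path)
  values <- as.array(img)
  attributes(values) <- list(dim = dim(values))
  neg <- values < 0
  if (any(neg)) {
    warning(sprintf("clamped %d negative voxel(s) to 0 in '%s'",
                    sum(neg), path))
    values[neg] <- 0
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  spect_volume(values, spacing)
}

#' @param shape expected grid dimensions (e.g. `dim(volume)`), or `NULL` to
#'   skip the check.
#' @rdname load_volume
#' @export
load_mask <- function(path, shape = NULL) {
  img <- read_nifti3d(path)
  values <- as.array(img)
  attributes(values) <- list(dim = dim(values))
  if (!is.null(shape) && !identical(dim(values), as.integer(shape)))
    stop(sprintf("mask grid %s does not match expected grid %s",
                 paste(dim(values), collapse = "x"),
                 paste(shape, collapse = "x")))
  liver_voi(values != 0)
}

#' @param volume a [spect_volume()] or 3D array.
#' @rdname load_volume
#' @export
save_volume <- function(volume, path) {
  volume <- as_spect_volume(volume)
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param mask a [liver_voi()] or 3D array; written as 0/1 integers. Unlike
#'   a VOI, a mask written here may be empty (e.g. a lesion truth mask of a
#'   tumour-free phantom).
#' @rdname load_volume
#' @export
save_mask <- function(mask, path) {
  m <- as_array3d(mask, "mask")
  img <- RNifti::asNifti(array(as.integer(m != 0), dim = dim(m)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti3d <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  # tolerate trailing singleton dimensions (3D image stored as 4D)
  if (length(d) > 3 && all(d[-(1:3)] == 1)) {
    img2 <- as.array(img)
    dim(img2) <- d[1:3]
    attr(img2, "pixdim") <- RNifti::pixdim(img)[1:3]
    return(structure(img2, class = "plain3d"))
  }
  if (length(d) != 3)
    stop(sprintf("'%s' is not a 3D scalar image (dims: %s)",
                 path, paste(d, collapse = "x")))
  img
}

#' Curve and cohort CSV persistence
#'
#' Curves are written as plain CSV with columns `threshold,thi,nuf,nnuf`
#' preceded by `#`-prefixed metadata lines carrying `c_max`, `mean_conc`,
#' `grid_size`, `connectivity` and `min_size`, so results stay diffable and
#' language-neutral. `read_curve()` restores an object equal to the one
#' written. Cohort tables use columns
#' `patient_id,group,thi,mean_conc,nthi,ppv,band`.
#'
#' @param curve an [nnufti()] curve object.
#' @param path output (or input) CSV path.
#' @return `read_curve()` returns an `nnufti` object; `read_cohort()` a
#'   data frame; the writers return `path` invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "nnufti"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(c_max = curve$c_max, mean_conc = curve$mean_conc,
            grid_size = curve$grid_size, connectivity = curve$connectivity,
            min_size = curve$min_size)
  writeLines(sprintf("# %s = %s", names(meta),
                     vapply(meta, format_num, "")), con)
  writeLines("threshold,thi,nuf,nnuf", con)
  writeLines(sprintf("%s,%s,%d,%s",
                     vapply(curve$rows$threshold, format_num, ""),
                     vapply(curve$rows$thi, format_num, ""),
                     curve$rows$nuf,
                     vapply(curve$rows$nnuf, format_num, "")), con)
  invisible(path)
}

format_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "\\s*=\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"))
  need <- c("threshold", "thi", "nuf", "nnuf")
  if (!all(need %in% names(df)))
    stop(sprintf("curve CSV missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  need_meta <- c("c_max", "mean_conc", "grid_size", "connectivity", "min_size")
  if (!all(need_meta %in% names(meta)))
    stop(sprintf("curve CSV missing metadata: %s",
                 paste(setdiff(need_meta, names(meta)), collapse = ", ")))
  new_nnufti_curve(rows = df[, need],
                   c_max = meta$c_max, mean_conc = meta$mean_conc,
                   grid_size = as.integer(meta$grid_size),
                   connectivity = as.integer(meta$connectivity),
                   min_size = as.integer(meta$min_size))
}

#' @param cohort data frame with columns
#'   `patient_id,group,thi,mean_conc,nthi,ppv,band` (missing statistics may
#'   be `NA`).
#' @rdname write_curve
#' @export
write_cohort <- function(cohort, path) {
  need <- c("patient_id", "group", "thi", "mean_conc", "nthi", "ppv", "band")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop(sprintf("cohort table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  write.csv(cohort[, need], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "thi", "mean_conc", "nthi", "ppv", "band")
  if (!all(need %in% names(df)))
    stop(sprintf("cohort CSV missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df
}
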