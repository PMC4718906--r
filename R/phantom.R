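#' Digital liver phantom specification
#'
#' Describes a seeded synthetic SPECT liver volume: an ellipsoidal liver
#' VOI on a regular grid, a mean background activity concentration
#' `lambda_bg` (counts/voxel) modulated by a smooth linear gain field
#' (radiotracer uptake is unevenly distributed through the liver, typically
#' higher towards the right lobe), optional hot spherical lesions at a
#' given tumour-to-normal concentration ratio (TNC), independent Poisson
#' counting noise per voxel, and an isotropic Gaussian point-spread blur.
#' Identical specs (including the seed) generate identical volumes.
#'
#' All positions and lengths are in mm; the centre of voxel `(i, j, k)` is
#' at `((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz)`.
#'
#' @param shape grid dimensions (default 64 x 64 x 48).
#' @param voxel_mm voxel edge lengths in mm (default 4.5 isotropic).
#' @param centre ellipsoid centre in mm (default: grid centre).
#' @param semi_axes_mm ellipsoid semi-axes in mm (default 100, 80, 60).
#' @param lambda_bg mean background concentration, counts/voxel (default
#'   60, the reference concentration of the downstream correction).
#' @param nonuniformity gain-field amplitude `a` in `[0, 1)` (default 0.2);
#'   the gain runs linearly from `1 - a` to `1 + a` across the first axis
#'   of the ellipsoid.
#' @param psf_sigma_mm isotropic Gaussian PSF sigma in mm (default 2,
#'   sub-voxel at the default spacing); 0 disables blurring. The default is
#'   deliberately small: volumes from unfiltered iterative reconstruction
#'   keep near voxel-scale noise granularity, and it is that granularity
#'   the focus counting works on. Larger values emulate post-filtering.
#' @param lesions list of [lesion()] objects, all inside the ellipsoid.
#' @param seed RNG seed for the Poisson draw.
#' @return an object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(seed = 7)
#' spec
#' @export
phantom_spec <- function(shape = c(64, 64, 48), voxel_mm = c(4.5, 4.5, 4.5),
                         centre = NULL, semi_axes_mm = c(100, 80, 60),
                         lambda_bg = 60, nonuniformity = 0.2,
                         psf_sigma_mm = 2, lesions = list(), seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) stop("`shape` must be 3 positive dims")
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (any(voxel_mm <= 0)) stop("`voxel_mm` must be positive")
  if (is.null(centre)) centre <- shape * voxel_mm / 2
  if (length(semi_axes_mm) != 3 || any(semi_axes_mm <= 0))
    stop("`semi_axes_mm` must be 3 positive lengths")
  if (lambda_bg <= 0) stop("`lambda_bg` must be positive")
  if (nonuniformity < 0 || nonuniformity >= 1)
    stop("`nonuniformity` must lie in [0, 1)")
  if (psf_sigma_mm < 0) stop("`psf_sigma_mm` must be >= 0")
  lesions <- lapply(lesions, function(l) {
    if (!inherits(l, "phantom_lesion")) l <- do.call(lesion, as.list(l))
    d <- semi_axes_mm - l$radius_mm
    if (any(d <= 0) || sum(((l$centre - centre) / d)^2) > 1)
      stop("lesion does not lie inside the VOI ellipsoid")
    l
  })
  structure(list(shape = shape, voxel_mm = as.numeric(voxel_mm),
                 centre = as.numeric(centre),
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 lambda_bg = lambda_bg, nonuniformity = nonuniformity,
                 psf_sigma_mm = psf_sigma_mm, lesions = lesions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @param radius_mm lesion radius in mm; `tnc` tumour-to-normal
#'   concentration ratio, `>= 1`.
#' @rdname phantom_spec
#' @export
lesion <- function(centre, radius_mm, tnc) {
  if (length(centre) != 3) stop("lesion `centre` must be 3 mm coordinates")
  if (radius_mm <= 0) stop("`radius_mm` must be positive")
  if (tnc < 1) stop("`tnc` must be >= 1")
  structure(list(centre = as.numeric(centre), radius_mm = radius_mm,
                 tnc = tnc),
            class = "phantom_lesion")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Liver phantom spec: %s grid, %s mm voxels, seed %d\n",
              paste(x$shape, collapse = " x "),
              paste(format(x$voxel_mm), collapse = " x "), x$seed))
  cat(sprintf("  lambda_bg %g counts/voxel, nonuniformity %g, PSF sigma %g mm\n",
              x$lambda_bg, x$nonuniformity, x$psf_sigma_mm))
  cat(sprintf("  %d lesion(s)\n", length(x$lesions)))
  invisible(x)
}

# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a phantom volume
#'
#' Realizes a [phantom_spec()]: the intensity field is
#' `lambda(x) = lambda_bg * g(x) * (1 + (tnc - 1) * lesion(x))` inside the
#' VOI and 0 outside; an independent Poisson count is drawn per voxel; the
#' counts are convolved with the Gaussian PSF. Inside the VOI the
#' convolution is renormalized by the blurred VOI indicator, so the mean
#' VOI concentration stays calibrated to `lambda_bg` instead of being
#' dragged down by spill-out at the liver boundary. Deterministic given
#' the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([spect_volume()]), `voi` ([liver_voi()]),
#'   `truth` (3D logical lesion mask) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  ax <- axis_mm(spec, 1); ay <- axis_mm(spec, 2); az <- axis_mm(spec, 3)
  ex <- ((ax - spec$centre[1]) / spec$semi_axes_mm[1])^2
  ey <- ((ay - spec$centre[2]) / spec$semi_axes_mm[2])^2
  ez <- ((az - spec$centre[3]) / spec$semi_axes_mm[3])^2
  voi <- outer(outer(ex, ey, "+"), ez, "+") <= 1

  gain_x <- 1 + spec$nonuniformity *
    (ax - spec$centre[1]) / spec$semi_axes_mm[1]
  lambda <- array(spec$lambda_bg * gain_x, dim = shape)  # first dim fastest

  truth <- array(FALSE, dim = shape)
  if (length(spec$lesions)) {
    factor <- array(1, dim = shape)
    for (l in spec$lesions) {
      d2 <- outer(outer((ax - l$centre[1])^2, (ay - l$centre[2])^2, "+"),
                  (az - l$centre[3])^2, "+")
      inside <- d2 <= l$radius_mm^2
      factor[inside] <- pmax(factor[inside], l$tnc)
      truth <- truth | inside
    }
    lambda <- lambda * factor
  }
  lambda[!voi] <- 0

  counts <- with_seed(spec$seed,
                      array(rpois(length(lambda), lambda), dim = shape))

  values <- counts
  if (spec$psf_sigma_mm > 0) {
    sigma_vox <- spec$psf_sigma_mm / spec$voxel_mm
    bc <- array(.gauss_blur3d(as.double(counts), shape, sigma_vox),
                dim = shape)
    bm <- array(.gauss_blur3d(as.double(voi), shape, sigma_vox),
                dim = shape)
    values <- bc
    values[voi] <- bc[voi] / bm[voi]
  }
  values[values < 0] <- 0

  list(volume = spect_volume(values, spec$voxel_mm),
       voi = liver_voi(voi), truth = truth, spec = spec)
}

axis_mm <- function(spec, i) {
  (seq_len(spec$shape[i]) - 0.5) * spec$voxel_mm[i]
}

#' Generate a labelled phantom cohort
#'
#' Generates `n_neg` tumour-free and `n_pos` lesioned phantoms from a
#' common base spec. Per-member Poisson seeds, lesion configurations for
#' the positives, and member-level heterogeneity (mean concentration and
#' liver size, emulating the patient-to-patient spread in uptake,
#' measurement time and camera sensitivity that motivates the downstream
#' concentration correction) are all derived deterministically from
#' `seed`, so a cohort is reproducible as a whole.
#'
#' @param n_neg,n_pos member counts (>= 0).
#' @param base_spec a [phantom_spec()]; its `lesions` are ignored.
#' @param lesion_sampler function of a `phantom_spec` returning a list of
#'   [lesion()]s (uses the current RNG stream). The default,
#'   `sample_lesions()`, draws 1-3 spherical lesions of radius 8-20 mm at
#'   TNC 1.5-3.5 uniformly inside the ellipsoid — a mix of minimal and
#'   substantial tumour burden at the low contrast ratios that make
#'   detection hard.
#' @param seed master seed for the cohort.
#' @param lambda_range per-member mean background concentration range,
#'   counts/voxel (uniform draw; `NULL` keeps `base_spec$lambda_bg` fixed).
#' @param size_range per-member multiplicative liver size range (`NULL`
#'   keeps the base semi-axes fixed).
#' @return list of members, each a list `spec`, `volume`, `voi`, `truth`,
#'   `label` (`"neg"` or `"pos"`).
#' @export
generate_cohort <- function(n_neg, n_pos, base_spec = phantom_spec(),
                            lesion_sampler = sample_lesions, seed = 1,
                            lambda_range = c(40, 90),
                            size_range = c(0.9, 1.1)) {
  stopifnot(inherits(base_spec, "phantom_spec"), n_neg >= 0, n_pos >= 0)
  n <- n_neg + n_pos
  draws <- with_seed(seed, list(
    seeds = matrix(sample.int(2^31 - 2, 2 * n), ncol = 2),
    lambda = if (is.null(lambda_range)) rep(base_spec$lambda_bg, n)
             else runif(n, lambda_range[1], lambda_range[2]),
    size = if (is.null(size_range)) rep(1, n)
           else runif(n, size_range[1], size_range[2])))
  labels <- rep(c("neg", "pos"), c(n_neg, n_pos))
  lapply(seq_len(n), function(i) {
    spec <- phantom_spec(shape = base_spec$shape,
                         voxel_mm = base_spec$voxel_mm,
                         centre = base_spec$centre,
                         semi_axes_mm = base_spec$semi_axes_mm * draws$size[i],
                         lambda_bg = draws$lambda[i],
                         nonuniformity = base_spec$nonuniformity,
                         psf_sigma_mm = base_spec$psf_sigma_mm,
                         seed = draws$seeds[i, 1])
    if (labels[i] == "pos") {
      les <- with_seed(draws$seeds[i, 2], lesion_sampler(spec))
      if (!length(les)) stop("lesion_sampler returned no lesions for a positive member")
      spec <- phantom_spec(shape = spec$shape, voxel_mm = spec$voxel_mm,
                           centre = spec$centre,
                           semi_axes_mm = spec$semi_axes_mm,
                           lambda_bg = spec$lambda_bg,
                           nonuniformity = spec$nonuniformity,
                           psf_sigma_mm = spec$psf_sigma_mm,
                           lesions = les, seed = draws$seeds[i, 1])
    }
    ph <- generate_phantom(spec)
    ph$label <- labels[i]
    ph
  })
}

#' @param spec sampler argument: the member's [phantom_spec()].
#' @rdname generate_cohort
#' @export
sample_lesions <- function(spec) {
  n <- sample(1:3, 1)
  lapply(seq_len(n), function(i) {
    r <- runif(1, 8, 20)
    tnc <- runif(1, 1.5, 3.5)
    repeat {
      u <- runif(3, -1, 1)
      if (sum(u^2) <= 1) break
    }
    d <- spec$semi_axes_mm - r
    if (any(d <= 0)) stop("lesion radius exceeds an ellipsoid semi-axis")
    lesion(spec$centre + u * d, radius_mm = r, tnc = tnc)
  })
}
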