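#' Parametric structures for the synthetic phantom
#'
#' Two shape families stand in for the myelinating anatomy: `shape_ellipsoid()`
#' for nuclei-like blobs (VLN/STN) and `shape_slab()` for curved sheet-like
#' tracts (capsule-like). Coordinates are physical mm; voxel `i` along an axis
#' with spacing `s` is centred at `(i - 0.5) * s`.
#'
#' Each shape exposes an analytic inside test through a scalar "level"
#' `g(x) <= 1`, and a normalized radial coordinate in `[0, 1]` used by the
#' cohort generator's optional within-structure onset gradient.
#'
#' @param center numeric length-3, centre in mm.
#' @param radii numeric length-3, semi-axes in mm (ellipsoid) or
#'   `c(rx, ry)` lateral semi-extent in mm (slab).
#' @param thickness slab thickness in mm along the z axis.
#' @param curvature quadratic bending of the slab mid-surface
#'   (mm displacement per mm^2 of lateral distance); 0 gives a flat slab.
#' @param label character name of the structure.
#' @return A `phantom_shape` object.
#' @export
shape_ellipsoid <- function(center, radii, label = "ellipsoid") {
  stopifnot(length(center) == 3L, length(radii) == 3L, all(radii > 0))
  structure(list(type = "ellipsoid", center = as.numeric(center),
                 radii = as.numeric(radii), label = label),
            class = "phantom_shape")
}

#' @rdname shape_ellipsoid
#' @export
shape_slab <- function(center, radii, thickness, curvature = 0,
                       label = "slab") {
  stopifnot(length(center) == 3L, length(radii) == 2L, all(radii > 0),
            thickness > 0)
  structure(list(type = "slab", center = as.numeric(center),
                 radii = as.numeric(radii), thickness = thickness,
                 curvature = curvature, label = label),
            class = "phantom_shape")
}

# Occupancy of a shape evaluated at point coordinates (vectors X, Y, Z in mm).
shape_inside <- function(shape, X, Y, Z) {
  c0 <- shape$center
  if (shape$type == "ellipsoid") {
    r <- shape$radii
    ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
      ((Z - c0[3]) / r[3])^2 <= 1
  } else {
    r <- shape$radii
    lat2 <- ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2
    mid <- c0[3] + shape$curvature * ((X - c0[1])^2 + (Y - c0[2])^2)
    lat2 <= 1 & abs(Z - mid) <= shape$thickness / 2
  }
}

# Normalized radial coordinate (0 centre, 1 boundary) at voxel centres.
shape_radius <- function(shape, X, Y, Z) {
  c0 <- shape$center
  if (shape$type == "ellipsoid") {
    r <- shape$radii
    sqrt(((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
           ((Z - c0[3]) / r[3])^2)
  } else {
    r <- shape$radii
    sqrt(((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2)
  }
}

#' Specification of a synthetic T2-like phantom
#'
#' Describes a volume in which myelin-like signal (MLS) structures are
#' hypointense against background tissue, with partial-volume (PV) voxels at
#' structure boundaries formed as intensity mixtures and additive Gaussian
#' noise on top. The PV definition is geometric: the MLS fraction of a voxel
#' is its supersampled occupancy by the analytic shapes.
#'
#' @param grid_shape integer length-3 voxel counts, all >= 8.
#' @param spacing_mm voxel size in mm, default `c(0.86, 0.86, 1)`.
#' @param mu_mls,mu_bkg pure-tissue mean intensities; `mu_mls < mu_bkg`
#'   (MLS is dark on T2-weighted contrast).
#' @param sigma noise standard deviation (same units as the means); default
#'   5% of the MLS/BKG contrast.
#' @param structures list of [shape_ellipsoid()] / [shape_slab()] objects.
#' @param supersampling_factor integer >= 2; each voxel is split into
#'   `factor^3` subvoxels to compute boundary fractions.
#' @param seed integer seed; required, no global RNG state is used.
#' @param noise `"gaussian"` (default, matches the segmenter's model) or
#'   `"rician"` for a magnitude-image robustness variant.
#' @param roi_margin integer: voxels stripped from every face to form the ROI.
#' @return A `phantom_spec` object.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 20),
                         spacing_mm = c(0.86, 0.86, 1),
                         mu_mls = 100, mu_bkg = 200,
                         sigma = 0.05 * (mu_bkg - mu_mls),
                         structures = default_structures(grid_shape, spacing_mm),
                         supersampling_factor = 4L,
                         seed = 1L,
                         noise = c("gaussian", "rician"),
                         roi_margin = 0L) {
  noise <- match.arg(noise)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stop("`grid_shape` must be 3 integers, all >= 8", call. = FALSE)
  }
  if (!(mu_mls < mu_bkg)) {
    stop("`mu_mls` must be below `mu_bkg`: MLS is hypointense on T2",
         call. = FALSE)
  }
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  supersampling_factor <- as.integer(supersampling_factor)
  if (supersampling_factor < 2L) {
    stop("`supersampling_factor` must be an integer >= 2", call. = FALSE)
  }
  if (!length(structures) || !all(vapply(structures, inherits, TRUE,
                                         "phantom_shape"))) {
    stop("`structures` must be a non-empty list of phantom shapes",
         call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 mu_mls = mu_mls, mu_bkg = mu_bkg, sigma = sigma,
                 structures = structures,
                 supersampling_factor = supersampling_factor,
                 seed = as.integer(seed), noise = noise,
                 roi_margin = as.integer(roi_margin)),
            class = "phantom_spec")
}

#' Default deep-brain-like structure set
#'
#' Two ellipsoidal nuclei and one curved slab, loosely emulating the
#' ventrolateral nuclei, subthalamic nuclei and a capsule tract. Sized so
#' that majority-MLS voxels occupy about 6% of the grid, matching the
#' MLS proportion the deep-brain initialization percentile encodes.
#'
#' @param grid_shape,spacing_mm as in [phantom_spec()].
#' @return list of `phantom_shape` objects.
#' @export
default_structures <- function(grid_shape = c(40, 40, 20),
                               spacing_mm = c(0.86, 0.86, 1)) {
  ext <- grid_shape * spacing_mm   # physical extent in mm
  list(
    shape_ellipsoid(center = ext * c(0.32, 0.56, 0.50),
                    radii = ext * c(0.15, 0.18, 0.24), label = "VLN"),
    shape_ellipsoid(center = ext * c(0.70, 0.62, 0.45),
                    radii = ext * c(0.135, 0.135, 0.21), label = "STN"),
    shape_slab(center = ext * c(0.52, 0.22, 0.55),
               radii = ext[1:2] * c(0.33, 0.12),
               thickness = 4.8 * spacing_mm[3], curvature = 0.01,
               label = "PLIC")
  )
}

# Voxel-centre coordinate vectors (mm) for a grid.
voxel_centers <- function(grid_shape, spacing_mm) {
  lapply(1:3, function(a) (seq_len(grid_shape[a]) - 0.5) * spacing_mm[a])
}

# Per-voxel occupancy fraction of one shape by supersampled subvoxel centres.
# Returns a 3D array in [0, 1]; errors if the shape covers nothing.
shape_fraction <- function(shape, grid_shape, spacing_mm, s) {
  n <- grid_shape
  sub <- lapply(1:3, function(a) {
    idx <- seq_len(n[a] * s)
    ((idx - 1) %/% s + ((idx - 1) %% s + 0.5) / s) * spacing_mm[a]
  })
  X <- rep(sub[[1]], times = n[2] * s * n[3] * s)
  Y <- rep(rep(sub[[2]], each = n[1] * s), times = n[3] * s)
  Z <- rep(sub[[3]], each = n[1] * s * n[2] * s)
  occ <- shape_inside(shape, X, Y, Z)
  if (!any(occ)) {
    stop(sprintf("structure '%s' lies fully outside the grid", shape$label),
         call. = FALSE)
  }
  occ6 <- array(occ, c(s, n[1], s, n[2], s, n[3]))
  occp <- aperm(occ6, c(2, 4, 6, 1, 3, 5))
  array(rowSums(array(occp, c(prod(n), s^3))), n) / s^3
}

#' Generate a synthetic phantom volume with partial-volume ground truth
#'
#' Builds the noiseless mixture image `f * mu_mls + (1 - f) * mu_bkg`, where
#' `f` is the supersampled occupancy fraction of the union of the spec's
#' structures, then adds seeded noise. Ground-truth labels are MLS where
#' `f = 1`, BKG where `f = 0` and PV strictly in between.
#'
#' @param spec a [phantom_spec()].
#' @return A `mls_phantom` object: `image` (a [volume_grid()]), `roi`
#'   (logical array), `truth_labels` (integer array, 1 = MLS, 2 = PV,
#'   3 = BKG), `truth_fraction` (array in \[0, 1\]), `structure_fractions`
#'   (named list of per-structure fraction arrays) and the `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 10), seed = 7))
#' table(ph$truth_labels)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape
  s <- spec$supersampling_factor
  fracs <- lapply(spec$structures, shape_fraction, grid_shape = n,
                  spacing_mm = spec$spacing_mm, s = s)
  names(fracs) <- vapply(spec$structures, `[[`, "", "label")
  f <- Reduce(pmax, fracs)   # union of shapes (shapes rarely overlap)
  labels <- array(BKG, n)
  labels[f > 0 & f < 1] <- PV
  labels[f == 1] <- MLS
  clean <- f * spec$mu_mls + (1 - f) * spec$mu_bkg
  img <- with_seed(spec$seed, {
    if (spec$sigma == 0) {
      clean
    } else if (spec$noise == "gaussian") {
      clean + rnorm(length(clean), 0, spec$sigma)
    } else {
      sqrt((clean + rnorm(length(clean), 0, spec$sigma))^2 +
             rnorm(length(clean), 0, spec$sigma)^2)
    }
  })
  img <- array(img, n)
  roi <- array(TRUE, n)
  m <- spec$roi_margin
  if (m > 0) {
    roi[c(seq_len(m), n[1] - seq_len(m) + 1L), , ] <- FALSE
    roi[, c(seq_len(m), n[2] - seq_len(m) + 1L), ] <- FALSE
    roi[, , c(seq_len(m), n[3] - seq_len(m) + 1L)] <- FALSE
  }
  structure(list(image = volume_grid(img, spec$spacing_mm), roi = roi,
                 truth_labels = labels, truth_fraction = f,
                 structure_fractions = fracs, spec = spec),
            class = "mls_phantom")
}

#' @export
print.mls_phantom <- function(x, ...) {
  n <- x$spec$grid_shape
  cat("<mls_phantom> ", paste(n, collapse = " x "), " voxels; ",
      sum(x$truth_labels == MLS), " MLS, ", sum(x$truth_labels == PV),
      " PV voxels; sigma = ", x$spec$sigma, "\n", sep = "")
  invisible(x)
}

#' Ground-truth binary MLS mask of a phantom
#'
#' The majority-occupancy mask `truth_fraction > 0.5`, the reference used in
#' Dice evaluation of segmenters.
#'
#' @param phantom a `mls_phantom`.
#' @return logical array.
#' @export
truth_mask <- function(phantom) {
  stopifnot(inherits(phantom, "mls_phantom"))
  phantom$truth_fraction > 0.5
}

#' Write a phantom to a directory as NIfTI volumes
#'
#' Writes `image.nii.gz`, `roi.nii.gz`, `truth_labels.nii.gz` and
#' `truth_fraction.nii.gz` with spacing in the headers.
#'
#' @param phantom a `mls_phantom`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$spec$spacing_mm
  write_volume(phantom$image, file.path(dir, "image.nii.gz"))
  write_mask(phantom$roi, file.path(dir, "roi.nii.gz"), sp)
  write_volume(array(as.numeric(phantom$truth_labels),
                     dim(phantom$truth_labels)),
               file.path(dir, "truth_labels.nii.gz"), sp)
  write_volume(phantom$truth_fraction,
               file.path(dir, "truth_fraction.nii.gz"), sp)
  invisible(dir)
}
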