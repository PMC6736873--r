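#' Specification of a synthetic longitudinal cohort
#'
#' Describes a cohort of subjects scanned at different gestational ages (GA),
#' each contributing a binary MLS segmentation on a common reference grid.
#' Every structure of the reference phantom myelinates along a logistic curve
#' `P(on at t) = c / (1 + exp(-k (t - t0)))`.
#'
#' A subject's segmentation is drawn with one latent uniform variable per
#' subject and structure: a voxel is labelled iff its logistic probability
#' exceeds the draw. Marginally every voxel follows its logistic curve; with
#' a spatially constant onset the whole structure switches coherently
#' (structure-level Bernoulli). An optional `gradient_weeks` per structure
#' spreads the onset radially (centre first), emulating a myelination wave
#' and giving the cohort continuous age information.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param ga_range_weeks `c(low, high)` within \[20, 50\] weeks.
#' @param structure_onsets a data frame (or [tibble::tibble]) with columns
#'   `label`, `t0` (midpoint, weeks), `k` (rate per week), `c` (asymptote in
#'   (0, 1\]) and optionally `gradient_weeks` (onset spread, default 0).
#' @param label_noise_rate probability in \[0, 0.5) of flipping each ROI
#'   voxel's label.
#' @param seed integer seed.
#' @param ga_sampling `"even"` (default; evenly spaced ages, like a cohort
#'   scanned on a fixed schedule) or `"uniform"` (random ages).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects, ga_range_weeks = c(29, 44),
                        structure_onsets, label_noise_rate = 0, seed = 1L,
                        ga_sampling = c("even", "uniform")) {
  ga_sampling <- match.arg(ga_sampling)
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (length(ga_range_weeks) != 2L || ga_range_weeks[1] > ga_range_weeks[2] ||
      ga_range_weeks[1] < 20 || ga_range_weeks[2] > 50) {
    stop("`ga_range_weeks` must be an increasing pair within [20, 50]",
         call. = FALSE)
  }
  if (label_noise_rate < 0 || label_noise_rate >= 0.5) {
    stop("`label_noise_rate` must be in [0, 0.5)", call. = FALSE)
  }
  so <- as_tibble(structure_onsets)
  need <- c("label", "t0", "k", "c")
  if (!all(need %in% names(so))) {
    stop("`structure_onsets` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"gradient_weeks" %in% names(so)) so$gradient_weeks <- 0
  if (any(so$c <= 0 | so$c > 1)) stop("asymptotes `c` must be in (0, 1]",
                                      call. = FALSE)
  if (any(so$k < 0)) stop("rates `k` must be >= 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 ga_range_weeks = as.numeric(ga_range_weeks),
                 structure_onsets = so,
                 label_noise_rate = label_noise_rate,
                 seed = as.integer(seed), ga_sampling = ga_sampling),
            class = "cohort_spec")
}

# Voxelwise onset map t0_v for one structure: t0 plus a radial gradient
# (centre myelinates first), restricted to the structure's truth mask. The
# gradient is parameterized by the volume quantile r^3 rather than the
# radius itself, so onsets are spread uniformly over voxels and the
# myelinated volume grows linearly across the onset window.
structure_onset_map <- function(shape, row, grid_shape, spacing_mm, mask) {
  ctr <- voxel_centers(grid_shape, spacing_mm)
  X <- rep(ctr[[1]], times = grid_shape[2] * grid_shape[3])
  Y <- rep(rep(ctr[[2]], each = grid_shape[1]), times = grid_shape[3])
  Z <- rep(ctr[[3]], each = grid_shape[1] * grid_shape[2])
  r <- array(shape_radius(shape, X, Y, Z), grid_shape)
  q <- pmin(r, 1)^3
  t0v <- row$t0 - row$gradient_weeks / 2 + row$gradient_weeks * q
  t0v[!mask] <- NA_real_
  t0v
}

#' Generate a longitudinal cohort of aligned binary segmentations
#'
#' Draws subject ages from the cohort spec, then for each subject draws its
#' binary MLS segmentation on the reference phantom's grid as described in
#' [cohort_spec()]. Deterministic for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param reference a [phantom_spec()] defining the common grid and the
#'   structures; structures are matched to `structure_onsets` by `label`.
#' @return An `mls_cohort`: a [tibble::tibble] with columns `subject_id`,
#'   `ga_weeks` and `seg` (list-column of logical arrays), carrying the grid
#'   shape, spacing, GA range and per-structure truth masks as attributes.
#' @examples
#' ref <- phantom_spec(grid_shape = c(12, 12, 8), seed = 1)
#' on <- tibble::tibble(label = c("VLN", "STN", "PLIC"),
#'                      t0 = c(28, 30, 40), k = c(3, 3, 3), c = 1)
#' coh <- generate_cohort(cohort_spec(6, c(29, 44), on, seed = 2), ref)
#' coh
#' @export
generate_cohort <- function(spec, reference) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(reference, "phantom_spec"))
  n <- reference$grid_shape
  labels <- vapply(reference$structures, `[[`, "", "label")
  so <- spec$structure_onsets
  miss <- setdiff(so$label, labels)
  if (length(miss)) {
    stop("onsets given for unknown structure(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  # structure truth masks (majority occupancy) on the reference grid
  fracs <- lapply(reference$structures, shape_fraction, grid_shape = n,
                  spacing_mm = reference$spacing_mm,
                  s = reference$supersampling_factor)
  names(fracs) <- labels
  masks <- lapply(fracs, function(f) f > 0.5)
  onset_maps <- lapply(seq_len(nrow(so)), function(j) {
    shape <- reference$structures[[match(so$label[j], labels)]]
    structure_onset_map(shape, so[j, ], n, reference$spacing_mm,
                        masks[[so$label[j]]])
  })
  lo <- spec$ga_range_weeks[1]; hi <- spec$ga_range_weeks[2]
  out <- with_seed(spec$seed, {
    ga <- if (spec$ga_sampling == "even") {
      seq(lo, hi, length.out = spec$n_subjects)
    } else {
      sort(runif(spec$n_subjects, lo, hi))
    }
    segs <- lapply(seq_len(spec$n_subjects), function(s) {
      seg <- array(FALSE, n)
      for (j in seq_len(nrow(so))) {
        p <- so$c[j] * plogis(so$k[j] * (ga[s] - onset_maps[[j]]))
        u <- runif(1)
        on <- !is.na(p) & p > u
        seg <- seg | on
      }
      if (spec$label_noise_rate > 0) {
        flip <- array(runif(prod(n)) < spec$label_noise_rate, n)
        seg <- xor(seg, flip)
      }
      seg
    })
    list(ga = ga, segs = segs)
  })
  res <- tibble(subject_id = sprintf("S%03d", seq_len(spec$n_subjects)),
                ga_weeks = out$ga, seg = out$segs)
  structure(res,
            class = c("mls_cohort", class(res)),
            grid_shape = n, spacing_mm = reference$spacing_mm,
            ga_range_weeks = spec$ga_range_weeks,
            structure_masks = masks, cohort_spec = spec)
}

#' Write / read a cohort as CSV plus one NIfTI per subject
#'
#' `write_cohort()` writes `cohort.csv` with columns `subject_id`,
#' `ga_weeks`, `path` and a `.nii.gz` segmentation per subject;
#' `read_cohort()` reads it back into an `mls_cohort` tibble.
#'
#' @param cohort an `mls_cohort`.
#' @param dir output directory.
#' @param csv_path path to a `cohort.csv` written by `write_cohort()`.
#' @return `write_cohort()` the CSV path invisibly; `read_cohort()` an
#'   `mls_cohort` tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- attr(cohort, "spacing_mm") %||% c(0.86, 0.86, 1)
  paths <- vapply(seq_len(nrow(cohort)), function(i) {
    p <- file.path(dir, paste0(cohort$subject_id[i], ".nii.gz"))
    write_mask(cohort$seg[[i]], p, sp)
    p
  }, "")
  csv <- file.path(dir, "cohort.csv")
  write.csv(data.frame(subject_id = cohort$subject_id,
                       ga_weeks = cohort$ga_weeks, path = paths),
            csv, row.names = FALSE)
  invisible(csv)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(csv_path) {
  tab <- read.csv(csv_path, stringsAsFactors = FALSE)
  segs <- lapply(tab$path, read_mask)
  sp <- attr(segs[[1]], "spacing_mm")
  res <- tibble(subject_id = as.character(tab$subject_id),
                ga_weeks = tab$ga_weeks,
                seg = lapply(segs, function(s) { attributes(s) <- list(dim = dim(s)); s }))
  structure(res, class = c("mls_cohort", class(res)),
            grid_shape = dim(segs[[1]]), spacing_mm = sp,
            ga_range_weeks = range(tab$ga_weeks))
}
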