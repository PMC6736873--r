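#' Maximum-vote hard segmentation of a posterior map
#'
#' Per-voxel argmax over the class posteriors. Ties are broken by the fixed
#' class precedence MLS > PV > BKG, which together with the fixed class order
#' makes the rule bit-reproducible.
#'
#' @param posteriors 4D posterior array (classes last), or an `mls_em` fit.
#' @param roi optional logical array; voxels outside get `NA`.
#' @return integer array of class labels (1 = MLS, 2 = PV, 3 = BKG for the
#'   three-class model; 1 = MLS, 2 = BKG for the two-class baseline), with a
#'   `classes` attribute.
#' @export
max_vote <- function(posteriors, roi = NULL) {
  classes <- CLASS_NAMES
  if (inherits(posteriors, "mls_em")) {
    roi <- roi %||% posteriors$roi
    classes <- posteriors$classes
    posteriors <- posteriors$posteriors
  }
  dm <- dim(posteriors)
  K <- dm[4]
  pm <- matrix(posteriors, ncol = K)
  lab <- max.col(pm, ties.method = "first")   # first = MLS > PV > BKG
  lab <- array(as.integer(lab), dm[1:3])
  if (!is.null(roi)) lab[!roi] <- NA_integer_
  attr(lab, "classes") <- classes[seq_len(K)]
  lab
}

#' MLS fraction of a partial-volume voxel
#'
#' Linear unmixing of an intensity between the two pure-tissue means:
#' `f = (mu_bkg - y) / (mu_bkg - mu_mls)`, clamped to \[0, 1\]. `f = 1` at
#' the MLS mean, `0` at the BKG mean, `0.5` at the midpoint.
#'
#' @param y observed intensity (vectorized).
#' @param mu_mls,mu_bkg pure-tissue means with `mu_bkg > mu_mls`.
#' @return MLS fraction(s) in \[0, 1\].
#' @export
pv_fraction <- function(y, mu_mls, mu_bkg) {
  if (!(mu_bkg > mu_mls)) {
    stop("degenerate contrast: `mu_bkg` must exceed `mu_mls`", call. = FALSE)
  }
  pmin(pmax((mu_bkg - y) / (mu_bkg - mu_mls), 0), 1)
}

#' Final binary MLS mask from a fitted segmentation
#'
#' Applies the maximum-vote rule, then reclassifies PV voxels by their MLS
#' fraction: a PV voxel joins the MLS mask iff its fraction is strictly
#' above 0.5. The two-class baseline has no PV class and returns the voted
#' MLS mask directly.
#'
#' @param fit an `mls_em` object (or a 4D posterior array, in which case
#'   `image`, `state` and `roi` must be given).
#' @param image,state,roi components when `fit` is a plain array.
#' @return list of class `mls_segmentation`: `mask` (logical array),
#'   `provenance` (integer array: 0 none, 1 voted MLS, 2 reclassified PV)
#'   and `counts`, a [tibble::tibble] of voxel counts per rule.
#' @export
finalize_mls <- function(fit, image = NULL, state = NULL, roi = NULL) {
  if (inherits(fit, "mls_em")) {
    image <- fit$image; state <- fit$state; roi <- fit$roi
    posteriors <- fit$posteriors
    two_class <- length(fit$classes) == 2L
  } else {
    posteriors <- fit
    two_class <- dim(posteriors)[4] == 2L
    if (is.null(image) || is.null(state) || is.null(roi)) {
      stop("`image`, `state` and `roi` are required with a plain posterior ",
           "array", call. = FALSE)
    }
  }
  vg <- as_volume_grid(image)
  vote <- max_vote(posteriors, roi)
  voted_mls <- !is.na(vote) & vote == MLS
  if (two_class) {
    reclass <- array(FALSE, dim(roi))
  } else {
    f <- pv_fraction(vg$intensities, state$mu_mls, state$mu_bkg)
    reclass <- !is.na(vote) & vote == PV & f > 0.5
  }
  mask <- voted_mls | reclass
  prov <- array(0L, dim(roi))
  prov[voted_mls] <- 1L
  prov[reclass] <- 2L
  counts <- tibble(rule = c("voted_mls", "reclassified_pv", "total"),
                   n_voxels = c(sum(voted_mls), sum(reclass), sum(mask)))
  structure(list(mask = mask, provenance = prov, counts = counts),
            class = "mls_segmentation")
}

#' @export
print.mls_segmentation <- function(x, ...) {
  cat("<mls_segmentation> ", sum(x$mask), " MLS voxels (",
      x$counts$n_voxels[1], " voted, ", x$counts$n_voxels[2],
      " reclassified PV)\n", sep = "")
  invisible(x)
}

#' Write a final segmentation as NIfTI plus a CSV rule summary
#'
#' @param seg an `mls_segmentation`.
#' @param dir output directory.
#' @param spacing_mm voxel spacing for the headers.
#' @return `dir`, invisibly.
#' @export
write_segmentation <- function(seg, dir, spacing_mm = c(0.86, 0.86, 1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mask(seg$mask, file.path(dir, "mls_mask.nii.gz"), spacing_mm)
  write.csv(seg$counts, file.path(dir, "rule_counts.csv"), row.names = FALSE)
  invisible(dir)
}
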