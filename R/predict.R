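#' Predict gestational age by SSD matching against the atlas
#'
#' Evaluates the atlas probability map on a candidate-age grid and returns
#' the age minimizing the sum of squared differences to the subject's binary
#' segmentation, `SSD(t) = sum_v (seg_v - p_v(t))^2`. Ties go to the
#' youngest candidate age.
#'
#' @param segmentation logical (or 0/1) array on the atlas grid.
#' @param atlas a `growth_atlas`.
#' @param grid_step candidate grid step in weeks (default 0.1).
#' @param roi optional logical array restricting the compared voxels.
#' @return An `age_prediction`: list with `predicted_ga` and `ssd_curve`, a
#'   [tibble::tibble] of `ga_weeks` and `ssd`.
#' @export
predict_ga <- function(segmentation, atlas, grid_step = 0.1, roi = NULL) {
  stopifnot(inherits(atlas, "growth_atlas"))
  if (!identical(dim(segmentation), as.integer(atlas$grid_shape)) &&
      !identical(dim(segmentation), atlas$grid_shape)) {
    stop("segmentation grid does not match the atlas grid", call. = FALSE)
  }
  keep <- if (is.null(roi)) TRUE else as.logical(roi)
  s <- as.numeric(segmentation)
  if (!is.null(roi)) s <- s[keep]
  rng <- atlas$ga_range_weeks
  grid <- seq(rng[1], rng[2], by = grid_step)
  ssd <- vapply(grid, function(t) {
    p <- as.numeric(query_atlas(atlas, t))
    if (!is.null(roi)) p <- p[keep]
    sum((s - p)^2)
  }, numeric(1))
  structure(list(predicted_ga = grid[which.min(ssd)],   # first min = youngest
                 ssd_curve = tibble(ga_weeks = grid, ssd = ssd)),
            class = "age_prediction")
}

#' @export
print.age_prediction <- function(x, ...) {
  cat("<age_prediction> predicted GA ", x$predicted_ga, " weeks\n", sep = "")
  invisible(x)
}

#' Leave-one-out gestational-age prediction over a cohort
#'
#' For each subject, rebuilds the growth atlas from the remaining subjects,
#' predicts the held-out subject's age by [predict_ga()], and reports the
#' root-mean-squared error against the nominal ages.
#'
#' @param cohort an `mls_cohort` with at least 3 subjects.
#' @param grid_step candidate grid step in weeks.
#' @param roi optional logical array restricting both fitting and matching.
#' @param ... passed to [fit_voxel_logistic()].
#' @return A `ga_loo` object: [tibble::tibble] with `subject_id`,
#'   `nominal_ga`, `predicted_ga` and `error`, carrying `rmse_weeks` as an
#'   attribute (see [glance()]).
#' @export
loo_predict <- function(cohort, grid_step = 0.1, roi = NULL, ...) {
  n <- nrow(cohort)
  if (n < 3L) stop("leave-one-out needs at least 3 subjects", call. = FALSE)
  preds <- vapply(seq_len(n), function(i) {
    atl <- build_atlas(cohort[-i, ], roi = roi, ...)
    atl$ga_range_weeks <- attr(cohort, "ga_range_weeks") %||%
      range(cohort$ga_weeks)
    predict_ga(cohort$seg[[i]], atl, grid_step, roi)$predicted_ga
  }, numeric(1))
  res <- tibble(subject_id = cohort$subject_id, nominal_ga = cohort$ga_weeks,
                predicted_ga = preds, error = preds - cohort$ga_weeks)
  rmse <- sqrt(mean(res$error^2))
  structure(res, class = c("ga_loo", class(res)), rmse_weeks = rmse,
            grid_step = grid_step)
}

#' Volume of a binary mask in millilitres
#'
#' Exact voxel-count computation: `count * voxel volume / 1000`.
#'
#' @param mask logical (or 0/1) array.
#' @param spacing_mm voxel spacing in mm.
#' @return volume in mL.
#' @examples
#' mls_volume(array(TRUE, c(10, 10, 10)), c(0.86, 0.86, 1))
#' @export
mls_volume <- function(mask, spacing_mm = c(0.86, 0.86, 1)) {
  sum(as.logical(mask)) * prod(spacing_mm) / 1000
}

#' MLS volume fraction within a region of interest
#'
#' `|MLS ∩ ROI| / |ROI|`, an exact count ratio.
#'
#' @param mls_mask,roi_mask logical arrays on the same grid.
#' @return scalar in \[0, 1\].
#' @export
volume_fraction <- function(mls_mask, roi_mask) {
  assert_same_grid(mls_mask, roi_mask, "masks")
  n_roi <- sum(as.logical(roi_mask))
  if (n_roi == 0) stop("ROI mask is empty", call. = FALSE)
  sum(as.logical(mls_mask) & as.logical(roi_mask)) / n_roi
}

#' Fit a volumetric growth trend
#'
#' Exponential trend `y = a * exp(b * x)` fitted by nonlinear least squares
#' on the original scale (Levenberg-Marquardt, seeded from a log-linear
#' regression), or an ordinary linear fit `y = a + b * x`. The coefficient
#' of determination is computed on the original scale,
#' `R^2 = 1 - SS_res / SS_tot`; for constant `y` (zero `SS_tot`) the
#' convention `R^2 = 0` is used.
#'
#' @param x ages (weeks); at least 3 distinct values.
#' @param y volumes (or volume fractions), same length, finite.
#' @param model `"exponential"` (default) or `"linear"`.
#' @return A `trend_fit`: list with `a`, `b`, `r2`, `model`, `fitted` and
#'   the input `data` as a [tibble::tibble]. See [tidy()] / [glance()].
#' @examples
#' x <- 29:44
#' fit_trend(x, 2 * exp(0.1 * x))
#' @export
fit_trend <- function(x, y, model = c("exponential", "linear")) {
  model <- match.arg(model)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  if (length(unique(x)) < 3L) {
    stop("at least 3 distinct `x` values are required", call. = FALSE)
  }
  if (model == "exponential") {
    ylog <- log(pmax(y, 1e-12))
    lin <- lm(ylog ~ x)
    start <- list(a = exp(unname(coef(lin)[1])), b = unname(coef(lin)[2]))
    fit <- minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    a <- unname(coef(fit)["a"]); b <- unname(coef(fit)["b"])
    yhat <- a * exp(b * x)
  } else {
    fit <- lm(y ~ x)
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
    yhat <- a + b * x
  }
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(a = a, b = b, r2 = r2, model = model, fitted = yhat,
                 data = tibble(x = x, y = y)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  form <- if (x$model == "exponential") "y = a exp(b x)" else "y = a + b x"
  cat(sprintf("<trend_fit> %s: a = %.4g, b = %.4g, R^2 = %.3f\n",
              form, x$a, x$b, x$r2))
  invisible(x)
}

#' Volumetric summary of a cohort of segmentations
#'
#' Computes the MLS volume (mL) and, when an ROI is supplied, the volume
#' fraction for every subject of a cohort — the per-subject quantities the
#' growth-trend analysis consumes.
#'
#' @param cohort an `mls_cohort`.
#' @param roi optional logical array shared by all subjects.
#' @return [tibble::tibble] with `subject_id`, `ga_weeks`, `volume_ml` and
#'   (with an ROI) `volume_fraction`.
#' @export
cohort_volumes <- function(cohort, roi = NULL) {
  sp <- attr(cohort, "spacing_mm") %||% c(0.86, 0.86, 1)
  out <- tibble(
    subject_id = cohort$subject_id,
    ga_weeks = cohort$ga_weeks,
    volume_ml = vapply(cohort$seg, mls_volume, numeric(1), spacing_mm = sp))
  if (!is.null(roi)) {
    out$volume_fraction <- vapply(cohort$seg, volume_fraction, numeric(1),
                                  roi_mask = roi)
  }
  out
}
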