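#' Fit a logistic growth curve to one voxel's label history
#'
#' Maximizes the Bernoulli likelihood of
#' `P(label = 1 | t) = c / (1 + exp(-k (t - t0)))` by bounded quasi-Newton
#' optimization (`k` in \[0, `k_max`\], `t0` within the observed age range
#' ± `t0_margin` weeks, `c` in (0, 1\]) from three deterministic starting
#' points. Degenerate inputs short-circuit: all-zero labels give status
#' `"constant-0"`, all-one `"constant-1"`, and fewer than `min_obs`
#' observations (or fewer than two distinct ages) give `"failed"` with the
#' empirical label frequency as the constant probability.
#'
#' @param ga numeric vector of gestational ages (weeks).
#' @param labels 0/1 (or logical) vector, same length.
#' @param k_max upper bound on the rate (per week).
#' @param t0_margin extension of the `t0` search range beyond the data.
#' @param min_obs minimum observations for a `"fitted"` status.
#' @return list with `t0`, `k`, `c`, `status` (`"fitted"`, `"constant-0"`,
#'   `"constant-1"` or `"failed"`) and `p_const`, the constant probability
#'   used when no curve is fitted.
#' @examples
#' set.seed(1)
#' ga <- runif(200, 29, 44)
#' y <- rbinom(200, 1, plogis(2 * (ga - 40)))
#' fit_voxel_logistic(ga, y)[c("t0", "k", "status")]
#' @export
fit_voxel_logistic <- function(ga, labels, k_max = 20, t0_margin = 5,
                               min_obs = 8L) {
  labels <- as.numeric(labels)
  if (length(ga) != length(labels)) {
    stop("`ga` and `labels` must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("`labels` must be binary (0/1)", call. = FALSE)
  }
  if (all(labels == 0)) {
    return(list(t0 = NA_real_, k = NA_real_, c = NA_real_,
                status = "constant-0", p_const = 0))
  }
  if (all(labels == 1)) {
    return(list(t0 = NA_real_, k = NA_real_, c = NA_real_,
                status = "constant-1", p_const = 1))
  }
  if (length(labels) < min_obs || length(unique(ga)) < 2L) {
    return(list(t0 = NA_real_, k = NA_real_, c = NA_real_,
                status = "failed", p_const = mean(labels)))
  }
  rng <- range(ga)
  lower <- c(t0 = rng[1] - t0_margin, k = 0, c = 1e-6)
  upper <- c(t0 = rng[2] + t0_margin, k = k_max, c = 1)
  nll <- function(par) {
    p <- par[3] * plogis(par[2] * (ga - par[1]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(labels * log(p) + (1 - labels) * log(1 - p))
  }
  starts <- list(
    c(t0 = unname(quantile(ga, 0.25)), k = 0.5, c = 1),
    c(t0 = unname(quantile(ga, 0.50)), k = 2,   c = 1),
    c(t0 = unname(quantile(ga, 0.75)), k = 8,
      c = max(mean(labels), 0.5)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(list(t0 = NA_real_, k = NA_real_, c = NA_real_,
                status = "failed", p_const = mean(labels)))
  }
  list(t0 = unname(best$par[1]), k = unname(best$par[2]),
       c = unname(best$par[3]), status = "fitted", p_const = mean(labels))
}

# Fit all voxels of a label matrix (voxels x subjects), deduplicating
# identical label sequences (spatially coherent cohorts repeat few
# patterns). Voxels that are never or always labelled bypass the keying.
fit_label_matrix <- function(L, ga, ...) {
  rs <- rowSums(L)
  fits <- vector("list", nrow(L))
  const0 <- list(t0 = NA_real_, k = NA_real_, c = NA_real_,
                 status = "constant-0", p_const = 0)
  const1 <- list(t0 = NA_real_, k = NA_real_, c = NA_real_,
                 status = "constant-1", p_const = 1)
  fits[rs == 0] <- list(const0)
  fits[rs == ncol(L)] <- list(const1)
  mid <- which(rs > 0 & rs < ncol(L))
  if (length(mid)) {
    key <- apply(L[mid, , drop = FALSE], 1, paste, collapse = "")
    uniq <- !duplicated(key)
    ufit <- lapply(mid[uniq], function(i) fit_voxel_logistic(ga, L[i, ], ...))
    fits[mid] <- ufit[match(key, key[uniq])]
  }
  fits
}

#' Build the voxelwise spatio-temporal growth atlas
#'
#' Fits [fit_voxel_logistic()] at every voxel of the reference grid from the
#' cohort's aligned binary segmentations. Voxels with identical label
#' histories share one fit.
#'
#' @param cohort an `mls_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param roi optional logical array restricting the fitted voxels.
#' @param ... passed to [fit_voxel_logistic()].
#' @return A `growth_atlas`: arrays `t0`, `k`, `c`, `p_const` and a
#'   character array `status` on the reference grid, plus `ga_range_weeks`,
#'   `grid_shape` and `spacing_mm`.
#' @export
build_atlas <- function(cohort, roi = NULL, ...) {
  n <- attr(cohort, "grid_shape") %||% dim(cohort$seg[[1]])
  ga <- cohort$ga_weeks
  L <- vapply(cohort$seg, function(s) as.logical(s), logical(prod(n)))
  idx <- if (is.null(roi)) seq_len(prod(n)) else which(as.logical(roi))
  fits <- fit_label_matrix(L[idx, , drop = FALSE] * 1, ga, ...)
  grab <- function(fld, fill) {
    a <- array(fill, n)
    a[idx] <- vapply(fits, function(f) f[[fld]],
                     if (is.character(fill)) "" else numeric(1))
    a
  }
  structure(list(t0 = grab("t0", NA_real_), k = grab("k", NA_real_),
                 c = grab("c", NA_real_), p_const = grab("p_const", 0),
                 status = grab("status", "outside"),
                 ga_range_weeks = attr(cohort, "ga_range_weeks") %||% range(ga),
                 grid_shape = n,
                 spacing_mm = attr(cohort, "spacing_mm") %||% c(0.86, 0.86, 1)),
            class = "growth_atlas")
}

#' @export
print.growth_atlas <- function(x, ...) {
  tab <- table(x$status)
  cat("<growth_atlas> ", paste(x$grid_shape, collapse = " x "),
      " voxels over GA ", x$ga_range_weeks[1], "-", x$ga_range_weeks[2],
      " weeks\n  status: ",
      paste(sprintf("%s = %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Query the atlas probability map at a gestational age
#'
#' Evaluates every voxel's logistic curve at `ga_weeks`; constant voxels
#' return their constant and failed voxels their empirical frequency.
#' Queries outside the fitted age range are answered but flagged with a
#' warning (extrapolation).
#'
#' @param atlas a `growth_atlas`.
#' @param ga_weeks scalar gestational age in weeks.
#' @return numeric array of probabilities in \[0, 1\] on the atlas grid.
#' @export
query_atlas <- function(atlas, ga_weeks) {
  stopifnot(inherits(atlas, "growth_atlas"), length(ga_weeks) == 1L)
  rng <- atlas$ga_range_weeks
  if (ga_weeks < rng[1] || ga_weeks > rng[2]) {
    warning(sprintf("ga = %g weeks is outside the fitted range [%g, %g]: ",
                    ga_weeks, rng[1], rng[2]), "extrapolating")
  }
  p <- atlas$p_const
  f <- atlas$status == "fitted"
  p[f] <- atlas$c[f] * plogis(atlas$k[f] * (ga_weeks - atlas$t0[f]))
  p[atlas$status == "constant-0"] <- 0
  p[atlas$status == "constant-1"] <- 1
  p
}

#' Myelination milestone of a structure
#'
#' The earliest gestational age (on a 0.1-week grid over the atlas range) at
#' which the median voxelwise probability inside `structure_mask` strictly
#' exceeds `threshold`. A structure already above threshold at the start of
#' the range is reported left-censored (`"<= range start"`); one that never
#' crosses is `"not reached"`.
#'
#' @param atlas a `growth_atlas`.
#' @param structure_mask non-empty logical array on the atlas grid.
#' @param threshold probability threshold, default 0.5.
#' @param step scan step in weeks.
#' @return A one-row [tibble::tibble] with `status` (`"reached"`,
#'   `"le_range_start"`, `"not_reached"`), `ga_weeks` (NA when not reached)
#'   and `label` (e.g. `"39.8 weeks"`, `"<=29 weeks"`, `"not reached"`).
#' @export
milestone <- function(atlas, structure_mask, threshold = 0.5, step = 0.1) {
  stopifnot(inherits(atlas, "growth_atlas"))
  if (!any(structure_mask)) stop("`structure_mask` is empty", call. = FALSE)
  rng <- atlas$ga_range_weeks
  grid <- seq(rng[1], rng[2], by = step)
  med <- vapply(grid, function(t) {
    median(query_atlas(atlas, t)[structure_mask])
  }, numeric(1))
  if (med[1] > threshold) {
    return(tibble(status = "le_range_start", ga_weeks = rng[1],
                  label = sprintf("<=%g weeks", rng[1])))
  }
  hit <- which(med > threshold)
  if (!length(hit)) {
    return(tibble(status = "not_reached", ga_weeks = NA_real_,
                  label = "not reached"))
  }
  tibble(status = "reached", ga_weeks = grid[hit[1]],
         label = sprintf("%.1f weeks", grid[hit[1]]))
}

#' Write / read a growth atlas
#'
#' The atlas is stored as four NIfTI volumes (`t0`, `k`, `c`, `p_const`),
#' an integer status volume and a JSON metadata sidecar.
#'
#' @param atlas a `growth_atlas`.
#' @param dir directory.
#' @return `write_atlas()` returns `dir` invisibly; `read_atlas()` a
#'   `growth_atlas`.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- atlas$spacing_mm
  lv <- c("outside", "constant-0", "constant-1", "failed", "fitted")
  for (f in c("t0", "k", "c", "p_const")) {
    a <- atlas[[f]]
    a[is.na(a)] <- -1
    write_volume(a, file.path(dir, paste0(f, ".nii.gz")), sp)
  }
  write_volume(array(match(atlas$status, lv) - 1, atlas$grid_shape),
               file.path(dir, "status.nii.gz"), sp)
  jsonlite::write_json(list(ga_range_weeks = atlas$ga_range_weeks,
                            grid_shape = atlas$grid_shape,
                            spacing_mm = sp, status_levels = lv),
                       file.path(dir, "atlas.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  rd <- function(f) read_volume(file.path(dir, paste0(f, ".nii.gz")))$intensities
  num <- lapply(c(t0 = "t0", k = "k", c = "c", p_const = "p_const"), rd)
  num[c("t0", "k", "c")] <- lapply(num[c("t0", "k", "c")], function(a) {
    a[a == -1] <- NA_real_; a
  })
  st <- array(meta$status_levels[round(rd("status")) + 1],
              meta$grid_shape)
  structure(c(num, list(status = st,
                        ga_range_weeks = meta$ga_range_weeks,
                        grid_shape = meta$grid_shape,
                        spacing_mm = meta$spacing_mm)),
            class = "growth_atlas")
}
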